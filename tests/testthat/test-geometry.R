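test_that("single-sphere occupied fraction matches the closed form", {
  r <- 0.5
  m <- make_fixture("single_sphere", arena_half_width = 1, radius = r,
                    centre = c(0, 0, 0))
  beta_exact <- 4 / 3 * pi * r^3 / 8
  expect_equal(m$beta_achieved, beta_exact, tolerance = 1e-12)

  # binomial sampling oracle: beta_hat within 3 SE of the closed form
  n <- 1e5
  beta_hat <- 1 - estimate_porosity(m, n_points = n, seed = 42)
  se <- sqrt(beta_exact * (1 - beta_exact) / n)
  expect_lt(abs(beta_hat - beta_exact), 3 * se)

  # unbiasedness: the mean over 30 seeds is within 3 SE of its own mean
  hats <- vapply(1:30, function(s)
    1 - estimate_porosity(m, n_points = 2e4, seed = s), numeric(1))
  se_mean <- sqrt(beta_exact * (1 - beta_exact) / 2e4) / sqrt(30)
  expect_lt(abs(mean(hats) - beta_exact), 3 * se_mean)
})

test_that("porosity estimator handles trivial media and is stable in n", {
  empty <- make_fixture("empty")
  expect_identical(estimate_porosity(empty, 10), 1)

  lat <- make_fixture("lattice", arena_half_width = 0.5, radius = 0.04,
                      pitch = 0.2)
  beta_exact <- 4 / 3 * pi * 0.04^3 / 0.2^3
  expect_equal(lat$beta_achieved, beta_exact, tolerance = 1e-12)
  beta_hat <- 1 - estimate_porosity(lat, 1e5, seed = 7)
  expect_lt(abs(beta_hat - beta_exact),
            3 * sqrt(beta_exact * (1 - beta_exact) / 1e5))

  m <- small_medium(0.8, seed = 3)
  b5 <- 1 - estimate_porosity(m, 1e5, seed = 11)
  b6 <- 1 - estimate_porosity(m, 1e6, seed = 12)
  expect_lt(abs(b5 - b6) / b6, 0.01)
})

test_that("generation converges to target beta, monotonically, deterministically", {
  targets <- c(0.3, 0.5, 0.8, 0.9, 0.95)
  media <- lapply(seq_along(targets), function(i)
    small_medium(targets[i], seed = 100 + i))
  achieved <- vapply(media, function(m) m$beta_achieved, numeric(1))
  expect_true(all(abs(achieved - targets) / targets <= 0.05))
  expect_true(all(diff(achieved) > 0))

  m1 <- small_medium(0.5, seed = 9)
  m2 <- small_medium(0.5, seed = 9)
  expect_identical(m1$spheres, m2$spheres)
  m3 <- small_medium(0.5, seed = 10)
  expect_false(identical(m1$spheres, m3$spheres))

  expect_error(generate_medium(0), "between 0 and 1")
  expect_error(generate_medium(1.2), "between 0 and 1")
})

test_that("the origin and the cleft cylinder stay free of sphere material", {
  cl <- cleft()
  m <- small_medium(0.8, seed = 5, cleft = cl)
  s <- m$spheres
  expect_true(all(sqrt(s$x^2 + s$y^2 + s$z^2) > s$radius))

  m <- insert_cleft(m, cl)
  R <- cl$diameter / 2
  H <- cl$height / 2
  s <- m$spheres
  dr <- pmax(sqrt(s$x^2 + s$y^2) - R, 0)
  dz <- pmax(abs(s$z) - H, 0)
  expect_true(all(dr^2 + dz^2 >= s$radius^2))

  expect_error(cleft(diameter = 0), "positive")
  expect_error(cleft(height = -1), "positive")
  expect_error(insert_cleft(small_medium(0.3, half = 0.1),
                            cleft(diameter = 0.5)),
               "fit inside")
})

test_that("grid-backed nearest-surface query equals the brute-force scan", {
  m <- small_medium(0.5, seed = 21, half = 0.3)
  expect_lt(nrow(m$spheres), 1000)
  set.seed(77)
  pts <- matrix(runif(3 * 200, -0.3, 0.3), ncol = 3)
  for (i in seq_len(nrow(pts))) {
    got <- nearest_surface_query(m, pts[i, ])
    want <- brute_nearest_sphere(m, pts[i, ])
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
    expect_identical(got$id, want$id)
    expect_identical(got$interior, want$distance < 0)
  }

  one <- make_fixture("single_sphere", radius = 0.5, centre = c(1, 0, 0))
  q <- nearest_surface_query(one, c(0, 0, 0))
  expect_equal(q$distance, 0.5, tolerance = 1e-12)
  expect_identical(q$surface, "sphere")
  inside <- nearest_surface_query(one, c(1, 0, 0.1))
  expect_lt(inside$distance, 0)
  expect_true(inside$interior)

  # cleft discs are reported with negative ids
  mc <- insert_cleft(make_fixture("empty"), cleft())
  q <- nearest_surface_query(mc, c(0, 0, 0))
  expect_identical(q$surface, "disc")
  expect_equal(q$distance, 0.010, tolerance = 1e-12)
})

test_that("medium serialization round-trips losslessly", {
  m <- small_medium(0.5, seed = 31, cleft = cleft())
  m <- insert_cleft(m, cleft())
  path <- file.path(tempdir(), "medium.csv")
  write_medium(m, path)
  m2 <- read_medium(path)
  expect_identical(m2$spheres$x, m$spheres$x)
  expect_identical(m2$spheres$radius, m$spheres$radius)
  expect_identical(m2$arena_half_width, m$arena_half_width)
  expect_identical(m2$beta_achieved, m$beta_achieved)
  expect_identical(m2$seed, m$seed)
  expect_equal(m2$cleft$diameter, 0.320)

  xyz <- file.path(tempdir(), "medium.xyz")
  write_medium_xyz(m, xyz)
  expect_identical(readLines(xyz)[1], as.character(nrow(m$spheres)))
})
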