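test_that("scatter histograms conserve mass and localise a point source", {
  ens <- particle_ensemble(500)  # everything at the origin, t = 0
  prof <- histogram_scatter(ens, fit = FALSE)
  expect_identical(sum(prof$counts), 500L)
  expect_identical(sum(prof$counts > 0), 1L)

  m <- make_fixture("empty")
  run <- quick_run(m, t_total = 0.1, n_particles = 1000, seed = 5)
  prof <- histogram_scatter(run$checkpoints[[1]])
  expect_identical(sum(prof$counts), 1000L)

  # free-diffusion marginal agrees with the Normal(0, sqrt(2 D t)) law
  xs <- run$checkpoints[[1]]$positions[, 1]
  ks <- suppressWarnings(
    stats::ks.test(xs, "pnorm", 0, sqrt(2 * 0.65 * 0.1)))
  expect_gt(ks$p.value, 0.01)

  esc <- forced_ensemble(matrix(0, 4, 3), c(0L, 2L, 2L, 2L))
  expect_identical(sum(histogram_scatter(esc, fit = FALSE)$counts), 1L)
  expect_error(histogram_scatter(forced_ensemble(matrix(0, 1, 3), 2L)),
               "no particles")
})

test_that("Gaussian fit recovers known dispersions and flags degenerate data", {
  set.seed(10)
  ens <- forced_ensemble(cbind(stats::rnorm(4000, 0, 0.3),
                               stats::rnorm(4000, 0, 0.3),
                               stats::rnorm(4000, 0, 0.3)),
                         integer(4000))
  s <- fit_gaussian_sigma(histogram_scatter(ens, fit = FALSE))
  expect_true(attr(s, "fit_ok"))
  expect_equal(as.numeric(s), 0.3, tolerance = 0.03)

  # all mass in a single bin: fallback, flagged
  point <- particle_ensemble(100)
  s0 <- fit_gaussian_sigma(histogram_scatter(point, fit = FALSE))
  expect_false(attr(s0, "fit_ok"))

  expect_error(fit_gaussian_sigma(
    structure(list(axis = "x", bin_edges = c(-1, 0, 1), counts = c(0L, 0L),
                   time = 0, sigma = NA_real_, fit_ok = FALSE),
              class = "scatter_profile")),
    "empty")
})

test_that("free-diffusion sigma grows with time and tracks sqrt(2 D t)", {
  m <- make_fixture("empty")
  sig <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_particles = 400, t_total = 0.1,
                             checkpoint_times = c(0.05, 0.1), seed = 200 + s)
    run <- run_simulation(cfg, m)
    vapply(run$checkpoints, function(e) histogram_scatter(e)$sigma,
           numeric(1))
  })
  expect_gt(mean(sig[2, ]), mean(sig[1, ]))
  for (i in 1:2) {
    t_i <- c(0.05, 0.1)[i]
    se <- sd(sig[i, ]) / sqrt(ncol(sig))
    expect_lt(abs(mean(sig[i, ]) - sqrt(2 * 0.65 * t_i)), 3 * se)
  }
})

test_that("capture statistics report both distance metrics correctly", {
  pos <- matrix(rep(c(0.05, 0, 0), each = 10), nrow = 10)
  ens <- forced_ensemble(pos, rep(1L, 10))
  cs <- capture_statistics(ens)
  expect_true(cs$any_bound)
  expect_equal(cs$median, 0.05, tolerance = 1e-12)
  expect_identical(cs$fraction_within(0.1), 1)
  expect_identical(cs$fraction_within(0.01), 0)

  # fraction_within is monotone and reaches the bound fraction
  half_bound <- forced_ensemble(rbind(pos, matrix(0.2, 10, 3)),
                                rep(c(1L, 0L), each = 10))
  cs2 <- capture_statistics(half_bound)
  radii <- c(0.01, 0.05, 0.1, 1, 10)
  fw <- cs2$fraction_within(radii)
  expect_true(all(diff(fw) >= 0))
  expect_equal(fw[length(fw)], cs2$bound_fraction)

  # cleft-edge metric: capture 50 nm beyond the 160 nm cleft rim
  cl <- cleft()
  edge <- forced_ensemble(matrix(rep(c(0.21, 0, 0), each = 4), nrow = 4),
                          rep(1L, 4))
  cse <- capture_statistics(edge, cl = cl)
  expect_equal(cse$median_from_cleft, 0.05, tolerance = 1e-12)
  expect_equal(cse$median, 0.21, tolerance = 1e-12)

  # no bound particles: explicit empty stats
  none <- capture_statistics(forced_ensemble(matrix(0, 5, 3), integer(5)))
  expect_false(none$any_bound)
  expect_identical(none$median, NA_real_)
  expect_length(none$distances, 0)
})

test_that("effective-D measurement validates its inputs", {
  expect_error(measure_effective_D(data.frame(time = 0.1, msd_free = 0.39)),
               "at least 2")
  tc <- data.frame(time = c(0.1, 0.2, 0.3),
                   msd_free = 6 * 0.5 * c(0.1, 0.2, 0.3))
  expect_equal(measure_effective_D(tc), 0.5, tolerance = 1e-12)
  # zero-displacement limit
  tc0 <- data.frame(time = c(0.1, 0.2), msd_free = c(0, 0))
  expect_equal(measure_effective_D(tc0), 0, tolerance = 1e-12)
})

test_that("run summaries collect sigma, binding and capture per checkpoint", {
  cl <- cleft()
  m <- insert_cleft(small_medium(0.8, seed = 81, cleft = cl), cl)
  cfg <- simulation_config(n_particles = 400, t_total = 0.05,
                           checkpoint_times = c(0.02, 0.05), p_bind = 0.3,
                           seed = 82)
  run <- run_simulation(cfg, m)
  tab <- summarize_run(run)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("sigma", "bound_fraction", "median_capture_nm",
                    "median_beyond_cleft_nm", "within_100nm", "alpha",
                    "p_bind") %in% names(tab)))
  expect_true(all(diff(tab$bound_fraction) >= 0))
  expect_identical(tab$p_bind, rep(0.3, 2))
})
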