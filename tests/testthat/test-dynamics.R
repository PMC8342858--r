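test_that("time-step choice follows the Einstein relation and its cap", {
  m <- make_fixture("single_sphere", radius = 0.010, centre = c(0.5, 0, 0))
  cfg <- simulation_config(D = 0.65)
  # 2 * sqrt(2 D dt) = 0.5 * 0.020 um  =>  dt = (0.005)^2 / (2 * 0.65)
  expect_equal(choose_timestep(cfg, m), 0.005^2 / (2 * 0.65),
               tolerance = 1e-12)

  # doubling D halves the admissible dt
  expect_equal(choose_timestep(simulation_config(D = 1.3), m),
               choose_timestep(cfg, m) / 2, tolerance = 1e-12)

  # cap at 1e-4 ms when nothing constrains the step
  expect_identical(choose_timestep(cfg, make_fixture("empty")), 1e-4)
  expect_identical(choose_timestep(simulation_config(D = 0), m), 1e-4)

  # the cleft height constrains the step too
  mc <- insert_cleft(make_fixture("empty"), cleft())
  expect_equal(choose_timestep(cfg, mc), 0.005^2 / (2 * 0.65),
               tolerance = 1e-12)
})

test_that("per-axis step variance matches the stepping rule", {
  m <- make_fixture("empty")
  n <- 5e5
  dt <- 1e-4
  for (rule in c("calibrated", "literal")) {
    cfg <- simulation_config(n_particles = n, dt = dt, step_rule = rule,
                             seed = 3)
    set.seed(cfg$seed)
    ens <- step_ensemble(particle_ensemble(n), cfg, m)
    v <- apply(ens$positions, 2, var)
    expected <- if (rule == "calibrated") 2 * 0.65 * dt else
      (4 / 3) * 2 * 0.65 * dt
    expect_true(all(abs(v - expected) / expected < 0.01),
                label = sprintf("%s rule variance", rule))
  }

  # zero diffusivity: no displacement at all
  cfg0 <- simulation_config(D = 0, dt = dt, n_particles = 100, seed = 1)
  set.seed(1)
  ens0 <- step_ensemble(particle_ensemble(100), cfg0, m, n_steps = 10)
  expect_true(all(ens0$positions == 0))
})

test_that("free diffusion reproduces the closed-form dispersion and D", {
  m <- make_fixture("empty")
  cfg <- simulation_config(n_particles = 2000, t_total = 0.1,
                           checkpoint_times = 0.1, seed = 8)
  run <- run_simulation(cfg, m)
  sig <- histogram_scatter(run$checkpoints[[1]])$sigma
  expect_equal(sig, sqrt(2 * 0.65 * 0.1), tolerance = 0.05)
  expect_equal(measure_effective_D(run), 0.65, tolerance = 0.05)

  lit <- run_simulation(simulation_config(n_particles = 2000, t_total = 0.1,
                                          checkpoint_times = 0.1, seed = 8,
                                          step_rule = "literal"), m)
  expect_equal(measure_effective_D(lit), 4 / 3 * 0.65, tolerance = 0.05)

  # t_total = 0: ensemble unchanged at the origin
  r0 <- run_simulation(simulation_config(n_particles = 50, t_total = 0,
                                         checkpoint_times = numeric(0)), m)
  expect_true(all(r0$final$positions == 0))
  expect_identical(r0$final$status, integer(50))
})

test_that("particles are conserved, stay outside spheres, and bind permanently", {
  m <- small_medium(0.8, seed = 41)
  run <- quick_run(m, t_total = 0.05, n_particles = 500, p_bind = 0.3,
                   seed = 42)
  ens <- run$final
  expect_identical(length(ens$status), 500L)
  expect_true(all(ens$status %in% 0:1))

  # bound particles carry a bind time; free ones do not
  expect_true(all(!is.na(ens$bind_time[ens$status == 1L])))
  expect_true(all(is.na(ens$bind_time[ens$status == 0L])))
  expect_true(any(ens$status == 1L))

  # no free particle rests inside a sphere beyond numerical tolerance
  free <- ens$positions[ens$status == 0L, , drop = FALSE]
  for (i in seq_len(min(nrow(free), 200))) {
    q <- nearest_surface_query(m, free[i, ])
    expect_gt(q$distance, -1e-6)
  }

  # binding permanence: further stepping never moves or re-times bound
  cfg <- run$config
  bound_before <- ens$positions[ens$status == 1L, , drop = FALSE]
  times_before <- ens$bind_time[ens$status == 1L]
  ens2 <- step_ensemble(ens, cfg, m, n_steps = 200)
  expect_identical(ens2$positions[ens$status == 1L, , drop = FALSE],
                   bound_before)
  expect_identical(ens2$bind_time[ens$status == 1L], times_before)
})

test_that("catchment capture lands exactly on the sphere surface", {
  m <- make_fixture("single_sphere", arena_half_width = 0.5, radius = 0.1,
                    centre = c(0.15, 0, 0))
  cfg <- simulation_config(n_particles = 200, t_total = 0.5,
                           checkpoint_times = 0.5, p_bind = 1, seed = 6)
  run <- run_simulation(cfg, m)
  ens <- run$final
  expect_true(any(ens$status == 1L))
  bp <- bind_positions(ens)
  r_err <- abs(sqrt((bp[, 1] - 0.15)^2 + bp[, 2]^2 + bp[, 3]^2) - 0.1)
  expect_true(all(r_err < 1e-9))
  bt <- ens$bind_time[ens$status == 1L]
  expect_true(all(bt > 0 & bt <= ens$time + 1e-12))

  # single-move resolution: a candidate inside the catchment shell with
  # p_bind = 1 binds and is projected onto the surface
  cfg1 <- simulation_config(p_bind = 1, dt = 1e-5)
  res <- resolve_surface_interaction(c(0, 0, 0), c(0.0485, 0, 0),
                                     cfg1,
                                     make_fixture("single_sphere",
                                                  arena_half_width = 0.5,
                                                  radius = 0.05,
                                                  centre = c(0.1, 0, 0)))
  expect_true(res$became_bound)
  expect_equal(res$new_position, c(0.05, 0, 0), tolerance = 1e-12)
})

test_that("cleft discs reflect but never capture", {
  # spheres surround the cleft, so every capture must lie outside it
  cl <- cleft()
  m <- insert_cleft(small_medium(0.8, seed = 51, cleft = cl), cl)
  run <- quick_run(m, t_total = 0.05, n_particles = 300, p_bind = 1,
                   seed = 52)
  ens <- run$final
  expect_true(any(ens$status == 1L))
  bp <- bind_positions(ens)
  rho <- sqrt(bp[, 1]^2 + bp[, 2]^2)
  inside_cleft <- rho < cl$diameter / 2 - 1e-9 &
    abs(bp[, 3]) < cl$height / 2 - 1e-9
  expect_false(any(inside_cleft))

  # a particle wandering within the cleft interior of an otherwise empty
  # arena can never bind, even with p_bind = 1
  m0 <- insert_cleft(make_fixture("empty"), cl)
  run0 <- quick_run(m0, t_total = 0.01, n_particles = 100, p_bind = 1,
                    seed = 53)
  expect_true(all(run0$final$status != 1L))
})

test_that("runs are bit-for-bit reproducible from the seed", {
  m <- small_medium(0.5, seed = 61)
  r1 <- quick_run(m, seed = 62)
  r2 <- quick_run(m, seed = 62)
  expect_identical(r1$final$positions, r2$final$positions)
  expect_identical(r1$final$status, r2$final$status)
  expect_identical(r1$timecourse, r2$timecourse)
  r3 <- quick_run(m, seed = 63)
  expect_false(identical(r1$final$positions, r3$final$positions))
})

test_that("final bound fraction is non-decreasing in p_bind", {
  m <- small_medium(0.5, seed = 71)
  frac <- vapply(c(0, 0.13, 0.3, 1), function(p) {
    mean(vapply(1:3, function(s)
      mean(quick_run(m, t_total = 0.02, n_particles = 300, p_bind = p,
                     seed = 80 + s)$final$status == 1L), numeric(1)))
  }, numeric(1))
  expect_identical(frac[1], 0)
  expect_true(all(diff(frac) >= 0))
})

test_that("denser packing narrows the free scatter monotonically", {
  sig <- vapply(c(0.3, 0.5, 0.8), function(beta) {
    m <- small_medium(beta, seed = 95)
    run <- quick_run(m, t_total = 0.05, n_particles = 1000, seed = 96)
    histogram_scatter(run$final, half_width = 0.75)$sigma
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("escaped particles are tracked in absorb-count mode", {
  m <- make_fixture("empty", arena_half_width = 0.2)
  cfg <- simulation_config(n_particles = 300, t_total = 0.2,
                           checkpoint_times = 0.2,
                           boundary_mode = "absorb-count", seed = 91)
  run <- run_simulation(cfg, m)
  st <- run$final$status
  expect_true(any(st == 2L))
  expect_identical(sum(st == 0L) + sum(st == 1L) + sum(st == 2L), 300L)
  tc <- run$timecourse
  expect_true(all(diff(tc$escaped_fraction) >= 0))
})
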