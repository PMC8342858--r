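#' Simulation configuration
#'
#' Collects the physical and numerical parameters of one run. When `dt` is
#' `NULL` it is chosen at run time by [choose_timestep()] against the
#' medium actually simulated.
#'
#' @param D Free diffusion coefficient in um^2/ms (default 0.65, glutamate
#'   in interstitial fluid).
#' @param dt Time step in ms, or `NULL` to pick the largest tunnelling-safe
#'   value (always capped at 1e-4 ms).
#' @param n_particles Number of particles released at the origin
#'   (default 2000, one vesicle's worth of glutamate).
#' @param t_total Simulated time in ms (default 1; binding immobilises
#'   nearly everything well before that in brain-like media).
#' @param checkpoint_times Times (ms) at which the full ensemble is
#'   snapshotted (default `c(0.1, 1)`).
#' @param p_bind Capture probability per surface encounter, in \[0, 1\]:
#'   0.3 mimics cerebellar astroglial coverage, 0.13 hippocampal CA1,
#'   1 makes every membrane a transporter surface, 0 disables binding.
#' @param catchment Half-thickness of the capture shell around sphere
#'   surfaces, um (default 0.003, i.e. +-3 nm, comparable to the
#'   elementary displacement).
#' @param boundary_mode `"reflect"` (default) folds particles back at the
#'   arena faces; `"absorb-count"` removes them and counts them as escaped.
#' @param step_rule `"calibrated"` (default) scales the per-axis uniform
#'   displacement by sqrt(3) so its variance is exactly 2*D*dt and the
#'   measured diffusion coefficient matches the nominal `D`; `"literal"`
#'   uses scale 2, whose effective diffusion coefficient is (4/3)*D.
#' @param binding_mode `"per-encounter"` (default) draws an independent
#'   Bernoulli(p_bind) at every surface encounter; `"per-sphere"` labels a
#'   fraction `p_bind` of spheres as astroglial at run start, and only
#'   those capture (with probability 1).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param safety_factor Fraction of the smallest obstacle feature the
#'   maximum elementary displacement may span (default 0.5).
#' @param max_retries Redraw attempts before a blocked particle rests for
#'   one step (default 10).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(D = 0.65,
                              dt = NULL,
                              n_particles = 2000L,
                              t_total = 1,
                              checkpoint_times = c(0.1, 1),
                              p_bind = 0,
                              catchment = 0.003,
                              boundary_mode = c("reflect", "absorb-count"),
                              step_rule = c("calibrated", "literal"),
                              binding_mode = c("per-encounter", "per-sphere"),
                              seed = 1L,
                              safety_factor = 0.5,
                              max_retries = 10L) {
  boundary_mode <- match.arg(boundary_mode)
  step_rule <- match.arg(step_rule)
  binding_mode <- match.arg(binding_mode)
  stopifnot(is.numeric(D), length(D) == 1, D >= 0,
            is.numeric(t_total), t_total >= 0,
            is.numeric(catchment), catchment > 0,
            is.numeric(safety_factor), safety_factor > 0,
            max_retries >= 0)
  if (!is.null(dt)) stopifnot(is.numeric(dt), dt > 0)
  if (!is.numeric(p_bind) || length(p_bind) != 1 || is.na(p_bind) ||
      p_bind < 0 || p_bind > 1)
    stop("p_bind must be a probability in [0, 1]")
  if (n_particles < 1) stop("n_particles must be at least 1")
  if (length(checkpoint_times) &&
      any(checkpoint_times < 0 | checkpoint_times > t_total))
    stop("checkpoint_times must lie within [0, t_total]")
  structure(list(D = D, dt = dt, n_particles = as.integer(n_particles),
                 t_total = t_total,
                 checkpoint_times = sort(unique(checkpoint_times)),
                 p_bind = p_bind, catchment = catchment,
                 boundary_mode = boundary_mode, step_rule = step_rule,
                 binding_mode = binding_mode,
                 seed = as.integer(seed),
                 safety_factor = safety_factor,
                 max_retries = as.integer(max_retries)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  D = %.3g um^2/ms, dt = %s ms, %d particles, t = %.3g ms\n",
              x$D, if (is.null(x$dt)) "auto" else format(x$dt), x$n_particles,
              x$t_total))
  cat(sprintf("  p_bind = %.3g (%s), catchment = +-%g nm, %s boundary, %s steps\n",
              x$p_bind, x$binding_mode, 1000 * x$catchment, x$boundary_mode,
              x$step_rule))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

step_scale <- function(config) {
  if (config$step_rule == "calibrated") sqrt(3) else 2
}

#' Choose a tunnelling-safe time step
#'
#' Returns the largest `dt <= 1e-4` ms such that the maximum elementary
#' per-axis displacement, `2 * Delta1D` with `Delta1D = sqrt(2 * D * dt)`,
#' does not exceed `safety_factor` times the smallest obstacle feature
#' (the smallest sphere diameter or the cleft height, whichever is
#' smaller). This prevents particles from tunnelling through the smallest
#' obstacles in a single step. Deterministic.
#'
#' @param config A [simulation_config()].
#' @param medium A `"sphere_medium"` (may be empty).
#' @return Time step in ms.
#' @export
#' @examples
#' m <- make_fixture("single_sphere", radius = 0.01, centre = c(0.5, 0, 0))
#' choose_timestep(simulation_config(), m)
choose_timestep <- function(config, medium) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(medium, "sphere_medium"))
  cap <- 1e-4
  features <- numeric(0)
  if (nrow(medium$spheres) > 0)
    features <- c(features, 2 * min(medium$spheres$radius))
  if (!is.null(medium$cleft)) features <- c(features, medium$cleft$height)
  if (length(features) == 0 || config$D == 0) return(cap)
  f <- min(features) * config$safety_factor
  min(cap, (f / 2)^2 / (2 * config$D))
}

#' Particle ensemble state
#'
#' @param n Number of particles.
#' @param position Common initial position (default the origin, the
#'   release site at the centre of the cleft).
#' @param time Ensemble clock in ms.
#' @return An object of class `"particle_ensemble"` with fields
#'   `positions` (n x 3 matrix, um; bound particles sit at their capture
#'   point), `status` (integer: 0 free, 1 bound, 2 escaped), `bind_time`
#'   (ms, `NA` for unbound) and `time`.
#' @export
particle_ensemble <- function(n, position = c(0, 0, 0), time = 0) {
  stopifnot(n >= 1, length(position) == 3)
  structure(list(positions = matrix(rep(as.numeric(position), each = n),
                                    nrow = n),
                 status = integer(n),
                 bind_time = rep(NA_real_, n),
                 time = time),
            class = "particle_ensemble")
}

ensemble_from_cpp <- function(snap) {
  bt <- snap$bind_time
  bt[snap$status != 1L] <- NA_real_
  structure(list(positions = snap$positions,
                 status = snap$status,
                 bind_time = bt,
                 time = snap$time),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<particle_ensemble> %d particles at t = %.4g ms: %d free, %d bound, %d escaped\n",
              n, x$time, sum(x$status == 0L), sum(x$status == 1L),
              sum(x$status == 2L)))
  invisible(x)
}

#' Extract bound-particle capture positions
#' @param ensemble A `"particle_ensemble"`.
#' @return Matrix of capture positions (um), one row per bound particle.
#' @export
bind_positions <- function(ensemble) {
  ensemble$positions[ensemble$status == 1L, , drop = FALSE]
}

sphere_bindable_flags <- function(config, medium) {
  if (config$binding_mode != "per-sphere") return(integer(0))
  n <- nrow(medium$spheres)
  # astroglial identity assigned once per run from the run's RNG stream
  as.integer(runif(n) < config$p_bind)
}

#' Advance an ensemble by Brownian time steps
#'
#' Each free particle receives an independent candidate displacement
#' `(s * dx * Delta1D, s * dy * Delta1D, s * dz * Delta1D)` with each
#' component an independent uniform draw from (-1, 1),
#' `Delta1D = sqrt(2 * D * dt)`, and `s` the step-rule scale (sqrt(3)
#' calibrated, 2 literal). The candidate is then resolved against the
#' obstacles (see [resolve_surface_interaction()]); bound particles never
#' move. The RNG state is whatever is current, so seed once per run.
#'
#' @param ensemble A `"particle_ensemble"`.
#' @param config A [simulation_config()] with a concrete `dt`.
#' @param medium A `"sphere_medium"`.
#' @param n_steps Number of time steps to take (default 1).
#' @return The advanced ensemble.
#' @export
step_ensemble <- function(ensemble, config, medium, n_steps = 1L) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(config, "simulation_config"),
            inherits(medium, "sphere_medium"))
  if (config$binding_mode == "per-sphere")
    stop("per-sphere binding labels spheres once per run; use run_simulation()")
  dt <- config$dt %||% choose_timestep(config, medium)
  res <- cpp_run_sim(sphere_matrix(medium), medium$arena_half_width,
                     cleft_vec(medium$cleft),
                     ensemble$positions, ensemble$status,
                     ifelse(is.na(ensemble$bind_time), -1,
                            ensemble$bind_time),
                     ensemble$time, config$D, dt, as.integer(n_steps),
                     config$p_bind, config$catchment, step_scale(config),
                     if (config$boundary_mode == "reflect") 0L else 1L,
                     integer(0), 0L, config$max_retries,
                     sphere_bindable_flags(config, medium))
  out <- ensemble_from_cpp(res)
  # capture times recorded before this call must survive unchanged
  keep <- !is.na(ensemble$bind_time)
  out$bind_time[keep] <- ensemble$bind_time[keep]
  out
}

#' Resolve one proposed particle move against the obstacles
#'
#' Applies the surface-interaction rule to a single candidate endpoint:
#' if it falls within the +-catchment shell of a sphere surface, a
#' Bernoulli draw with probability `p_bind` decides permanent capture (the
#' particle is projected onto the surface). Without capture the collision
#' is elastic: any move whose endpoint penetrates an obstacle or whose
#' path crosses a cleft disc is rejected and the displacement redrawn, up
#' to `max_retries` times, after which the particle rests for the step;
#' an endpoint in the outer (extracellular) half of the shell is a valid
#' free position and is kept. Cleft discs always reflect and never
#' capture. Exposed mainly for testing single interactions; full runs use
#' [run_simulation()].
#'
#' @param old_position,candidate_position Numeric 3-vectors, um.
#' @param config A [simulation_config()] with concrete `dt` (or `dt` is
#'   chosen from the medium).
#' @param medium A `"sphere_medium"`.
#' @return List with `new_position`, `became_bound`, `escaped`, `rested`.
#' @export
resolve_surface_interaction <- function(old_position, candidate_position,
                                        config, medium) {
  stopifnot(length(old_position) == 3, length(candidate_position) == 3,
            inherits(config, "simulation_config"),
            inherits(medium, "sphere_medium"))
  dt <- config$dt %||% choose_timestep(config, medium)
  cpp_resolve_move(sphere_matrix(medium), medium$arena_half_width,
                   cleft_vec(medium$cleft),
                   as.numeric(old_position), as.numeric(candidate_position),
                   config$p_bind, config$catchment, sqrt(2 * config$D * dt),
                   step_scale(config),
                   if (config$boundary_mode == "reflect") 0L else 1L,
                   config$max_retries)
}

#' Run a full release-and-diffusion simulation
#'
#' Releases `n_particles` instantaneously at the origin at t = 0, iterates
#' the Brownian stepping rule to `t_total`, snapshots the full ensemble at
#' every checkpoint time, and records a regularly sampled time course of
#' the bound fraction and of the mean squared displacement of the free
#' particles (from which [measure_effective_D()] verifies the effective
#' diffusion coefficient). Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param medium A `"sphere_medium"`.
#' @param n_timecourse_samples Approximate number of time-course rows
#'   (default 200).
#' @return An object of class `"run_summary"`: `config` (with the concrete
#'   `dt` filled in), `checkpoints` (named list of ensembles, names are
#'   times in ms), `timecourse` (data frame: `time`, `bound_fraction`,
#'   `escaped_fraction`, `msd_free`, `n_free`), `final` ensemble, and
#'   `medium_info`.
#' @export
#' @examples
#' m <- make_fixture("empty", arena_half_width = 1.5)
#' cfg <- simulation_config(n_particles = 200, t_total = 0.05,
#'                          checkpoint_times = 0.05, seed = 7)
#' run <- run_simulation(cfg, m)
#' run$timecourse[nrow(run$timecourse), ]
run_simulation <- function(config, medium, n_timecourse_samples = 200) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(medium, "sphere_medium"))
  dt <- config$dt %||% choose_timestep(config, medium)
  config$dt <- dt
  set.seed(config$seed)
  bindable <- sphere_bindable_flags(config, medium)

  init <- particle_ensemble(config$n_particles)
  if (config$t_total == 0) {
    return(structure(list(config = config,
                          checkpoints = stats::setNames(list(init), "0"),
                          timecourse = data.frame(time = 0, bound_fraction = 0,
                                                  escaped_fraction = 0,
                                                  msd_free = 0,
                                                  n_free = config$n_particles),
                          final = init,
                          medium_info = medium_info(medium)),
                     class = "run_summary"))
  }
  n_steps <- as.integer(ceiling(config$t_total / dt - 1e-9))
  cp_steps <- pmin(as.integer(round(config$checkpoint_times / dt)), n_steps)
  sample_every <- max(1L, n_steps %/% as.integer(n_timecourse_samples))

  res <- cpp_run_sim(sphere_matrix(medium), medium$arena_half_width,
                     cleft_vec(medium$cleft),
                     init$positions, init$status,
                     rep(-1, config$n_particles), 0,
                     config$D, dt, n_steps, config$p_bind, config$catchment,
                     step_scale(config),
                     if (config$boundary_mode == "reflect") 0L else 1L,
                     cp_steps, sample_every, config$max_retries, bindable)
  cps <- lapply(res$checkpoints, ensemble_from_cpp)
  names(cps) <- vapply(config$checkpoint_times, format, character(1),
                       trim = TRUE)
  structure(list(config = config,
                 checkpoints = cps,
                 timecourse = res$timecourse,
                 final = ensemble_from_cpp(res),
                 medium_info = medium_info(medium)),
            class = "run_summary")
}

medium_info <- function(medium) {
  list(n_spheres = nrow(medium$spheres),
       arena_half_width = medium$arena_half_width,
       beta_target = medium$beta_target,
       beta_achieved = medium$beta_achieved,
       alpha = 1 - medium$beta_achieved,
       cleft = !is.null(medium$cleft),
       cleft_diameter = if (is.null(medium$cleft)) NA_real_ else
         medium$cleft$diameter,
       cleft_height = if (is.null(medium$cleft)) NA_real_ else
         medium$cleft$height,
       seed = medium$seed)
}

#' @export
print.run_summary <- function(x, ...) {
  tc <- x$timecourse
  last <- tc[nrow(tc), ]
  cat("<run_summary>\n")
  cat(sprintf("  %d particles, t = %.4g ms, dt = %.3g ms, p_bind = %.3g\n",
              x$config$n_particles, x$final$time, x$config$dt,
              x$config$p_bind))
  cat(sprintf("  medium: %d spheres, alpha = %.3g%s\n",
              x$medium_info$n_spheres, x$medium_info$alpha,
              if (x$medium_info$cleft) ", cleft" else ""))
  cat(sprintf("  final bound fraction %.3f, escaped %.3f\n",
              last$bound_fraction, last$escaped_fraction))
  invisible(x)
}

#' Characteristic centre-to-boundary diffusion time
#'
#' The mean first-order time scale `r^2 / (6 D)` for a particle to diffuse
#' a distance `r` in three dimensions; with the default arena (r = 1.5 um)
#' and D = 0.65 um^2/ms this is about 0.58 ms, below the 1 ms simulated
#' window, which is why runs are limited to 1 ms.
#'
#' @param r Distance in um (default 1.5, centre to arena face).
#' @param D Diffusion coefficient in um^2/ms (default 0.65).
#' @return Time in ms.
#' @export
characteristic_diffusion_time <- function(r = 1.5, D = 0.65) {
  stopifnot(r > 0, D > 0)
  r^2 / (6 * D)
}
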