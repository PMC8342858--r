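# Shared helpers: small media and short runs keep the unit tests quick;
# the full-scale study conditions live in test-acceptance.R.

small_medium <- function(beta, seed = 1L, half = 0.75, ...) {
  generate_medium(beta, arena_half_width = half, seed = seed, ...)
}

quick_run <- function(medium, t_total = 0.05, n_particles = 500, p_bind = 0,
                      seed = 1L, ...) {
  cfg <- simulation_config(n_particles = n_particles, t_total = t_total,
                           checkpoint_times = t_total, p_bind = p_bind,
                           seed = seed, ...)
  run_simulation(cfg, medium)
}

# Brute-force signed distance to the nearest sphere surface, the oracle
# for the grid-backed nearest_surface_query.
brute_nearest_sphere <- function(medium, point) {
  s <- medium$spheres
  if (nrow(s) == 0) return(list(distance = Inf, id = 0L))
  d <- sqrt((s$x - point[1])^2 + (s$y - point[2])^2 +
            (s$z - point[3])^2) - s$radius
  j <- which.min(abs(d))
  list(distance = d[j], id = j)
}

# Assemble a particle ensemble in a given state (capture-stats fixtures).
forced_ensemble <- function(positions, status, bind_time = NULL,
                            time = 1) {
  ens <- particle_ensemble(nrow(positions), time = time)
  ens$positions <- positions
  ens$status <- as.integer(status)
  ens$bind_time <- bind_time %||% ifelse(status == 1L, time / 2, NA_real_)
  ens$time <- time
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
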