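#' Scenario presets
#'
#' The nine standard simulated neuropil conditions, named after the
#' figure panels they generate:
#' free diffusion in open (`fig1a`) and brain-like (`fig1b`) media, fully
#' absorbing surfaces in an open medium (`fig1c`), cerebellar (binding
#' probability 0.3) and hippocampal CA1 (0.13) astroglial coverage with a
#' synaptic cleft at normal (`fig2a`, `fig2b`), shrunken (`fig2c`,
#' `fig2d`: alpha 0.1 or 0.05) and expanded (`fig3a`, `fig3b`: alpha 0.5)
#' extracellular space.
#'
#' @return A data frame with one row per preset: `name`, `alpha` (default
#'   porosity), `alpha_options` (comma-separated allowed porosities),
#'   `p_bind`, `cleft`, `figure`.
#' @export
scenario_presets <- function() {
  data.frame(
    name = c("fig1a", "fig1b", "fig1c", "fig2a", "fig2b", "fig2c",
             "fig2d", "fig3a", "fig3b"),
    alpha = c(0.7, 0.2, 0.7, 0.2, 0.2, 0.1, 0.1, 0.5, 0.5),
    alpha_options = c("0.7", "0.2", "0.7", "0.2", "0.2", "0.1,0.05",
                      "0.1,0.05", "0.5", "0.5"),
    p_bind = c(0, 0, 1, 0.3, 0.13, 0.3, 0.13, 0.3, 0.13),
    cleft = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    figure = c("1A", "1B", "1C", "2A", "2B", "2C", "2D", "3A", "3B"),
    stringsAsFactors = FALSE)
}

#' Build a fully specified scenario
#'
#' Expands a preset name into a seeded `(config, medium)` pair with the
#' standard defaults: 2000 particles released at the origin of a 3 um
#' cube, D = 0.65 um^2/ms, 1 ms of simulated time, checkpoints at 0.1 and
#' 1 ms, sphere diameters uniform over 20-100 nm, and (where the preset
#' says so) a 320 x 20 nm transporter-free cleft at the origin. The medium
#' is generated with seed `seed`; the dynamics seed is derived from it, so
#' a single integer reproduces the whole realisation.
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param seed Integer seed for this Monte Carlo realisation.
#' @param alpha Porosity override, allowed only among the preset's
#'   `alpha_options` (used by the shrunken-space presets to pick 0.1 vs
#'   0.05).
#' @param ... Overrides forwarded to [simulation_config()]
#'   (e.g. `n_particles`, `t_total`).
#' @return List with elements `config` and `medium`.
#' @export
#' @examples
#' sc <- scenario_presets()
#' sc[sc$name == "fig2a", ]
build_scenario <- function(name, seed = 1L, alpha = NULL, ...) {
  presets <- scenario_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown scenario '%s'; valid presets: %s", name,
                 paste(presets$name, collapse = ", ")))
  allowed <- as.numeric(strsplit(row$alpha_options, ",")[[1]])
  if (is.null(alpha)) alpha <- row$alpha
  if (!alpha %in% allowed)
    stop(sprintf("scenario '%s' allows alpha in {%s}", name,
                 row$alpha_options))
  seed <- as.integer(seed)
  cl <- if (row$cleft) cleft() else NULL
  medium <- generate_medium(beta_target = 1 - alpha, seed = seed,
                            cleft = cl)
  if (row$cleft) medium <- insert_cleft(medium, cl)
  config <- simulation_config(p_bind = row$p_bind,
                              seed = (seed + 1000003L) %% 2147483647L,
                              ...)
  list(config = config, medium = medium)
}

#' Deterministic toy media with closed-form porosity
#'
#' Fixture geometries for oracle-based testing: an `empty` arena, a
#' `single_sphere` of known radius and centre, a cubic `lattice` of
#' non-overlapping spheres, and a `flat_wall` (a very large sphere whose
#' surface is locally plane at a given x). Their `beta_achieved` fields
#' hold the exact closed-form occupied fraction, so estimator bias and
#' collision behaviour can be checked against known answers.
#'
#' @param kind One of `"empty"`, `"single_sphere"`, `"lattice"`,
#'   `"flat_wall"`.
#' @param arena_half_width Arena half-width, um (default 1.5).
#' @param radius Sphere radius, um (single_sphere: default 0.5; lattice:
#'   default 0.04).
#' @param centre Sphere centre (single_sphere; default origin-offset
#'   `c(0.5, 0, 0)`).
#' @param pitch Lattice pitch, um (default 0.2; must be at least
#'   `2 * radius` so spheres do not overlap and the closed form holds).
#' @param wall_x x-coordinate of the wall surface (flat_wall; default 0.5);
#'   the wall occupies x > wall_x locally.
#' @param wall_radius Radius of the wall sphere (default 100 um).
#' @return A `"sphere_medium"` with exact `beta_achieved`.
#' @export
#' @examples
#' m <- make_fixture("single_sphere", arena_half_width = 1, radius = 0.5,
#'                   centre = c(0, 0, 0))
#' m$beta_achieved  # (4/3) pi 0.5^3 / 8
make_fixture <- function(kind = c("empty", "single_sphere", "lattice",
                                  "flat_wall"),
                         arena_half_width = 1.5, radius = NULL,
                         centre = c(0.5, 0, 0), pitch = 0.2,
                         wall_x = 0.5, wall_radius = 100) {
  kind <- match.arg(kind)
  h <- arena_half_width
  V <- (2 * h)^3
  empty_df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         radius = numeric(0))
  switch(kind,
    empty = new_sphere_medium(empty_df, h, beta_target = 0,
                              beta_achieved = 0),
    single_sphere = {
      r <- radius %||% 0.5
      stopifnot(r > 0, length(centre) == 3)
      # closed form assumes the sphere lies fully inside the arena
      if (any(abs(centre) + r > h))
        warning("sphere protrudes beyond the arena; closed-form beta ignores the outside part")
      df <- data.frame(x = centre[1], y = centre[2], z = centre[3],
                       radius = r)
      new_sphere_medium(df, h, beta_target = 4 / 3 * pi * r^3 / V,
                        beta_achieved = 4 / 3 * pi * r^3 / V)
    },
    lattice = {
      r <- radius %||% 0.04
      stopifnot(pitch >= 2 * r)
      g <- seq(-h + pitch / 2, h - pitch / 2, by = pitch)
      df <- expand.grid(x = g, y = g, z = g)
      df$radius <- r
      beta <- 4 / 3 * pi * r^3 / pitch^3
      new_sphere_medium(df, h, beta_target = beta, beta_achieved = beta)
    },
    flat_wall = {
      R <- wall_radius
      df <- data.frame(x = wall_x + R, y = 0, z = 0, radius = R)
      new_sphere_medium(df, h, beta_target = NA_real_,
                        beta_achieved = NA_real_)
    })
}
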