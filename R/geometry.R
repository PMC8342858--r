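#' Synaptic cleft geometry
#'
#' Describes the transporter-free synaptic cleft: an open cylinder centred
#' on the arena origin (the release site), bounded axially by two reflecting
#' discs representing the pre- and postsynaptic membranes. The discs never
#' capture particles; the lateral rim is open, so molecules leave the cleft
#' sideways. Default dimensions (320 nm wide, 20 nm high) follow typical
#' hippocampal CA3-CA1 synapse measurements.
#'
#' @param diameter Cleft diameter in um (default 0.320).
#' @param height Cleft height (membrane-to-membrane) in um (default 0.020).
#' @return An object of class `"cleft"` with fields `diameter`, `height`,
#'   `centre` (origin) and `axis` (+z).
#' @export
#' @examples
#' cl <- cleft()
#' cl$diameter
cleft <- function(diameter = 0.320, height = 0.020) {
  stopifnot(is.numeric(diameter), length(diameter) == 1,
            is.numeric(height), length(height) == 1)
  if (!is.finite(diameter) || diameter <= 0)
    stop("cleft diameter must be a positive length (um)")
  if (!is.finite(height) || height <= 0)
    stop("cleft height must be a positive length (um)")
  structure(list(diameter = diameter, height = height,
                 centre = c(0, 0, 0), axis = c(0, 0, 1)),
            class = "cleft")
}

cleft_vec <- function(cl) {
  if (is.null(cl)) numeric(0) else c(cl$diameter / 2, cl$height / 2)
}

new_sphere_medium <- function(spheres, arena_half_width, beta_target = NA_real_,
                              beta_achieved = NA_real_, seed = NA_integer_,
                              cleft = NULL) {
  stopifnot(is.data.frame(spheres),
            all(c("x", "y", "z", "radius") %in% names(spheres)))
  structure(list(spheres = spheres,
                 arena_half_width = arena_half_width,
                 beta_target = beta_target,
                 beta_achieved = beta_achieved,
                 seed = seed,
                 cleft = cleft),
            class = "sphere_medium")
}

sphere_matrix <- function(medium) {
  as.matrix(medium$spheres[, c("x", "y", "z", "radius"), drop = FALSE])
}

#' @export
print.sphere_medium <- function(x, ...) {
  cat("<sphere_medium>\n")
  cat(sprintf("  arena: %.3g um cube, %d spheres\n",
              2 * x$arena_half_width, nrow(x$spheres)))
  cat(sprintf("  beta: target %.4g, achieved %.4g (porosity alpha = %.4g)\n",
              x$beta_target, x$beta_achieved, 1 - x$beta_achieved))
  if (!is.null(x$cleft))
    cat(sprintf("  cleft: %.0f x %.0f nm, reflecting discs at the origin\n",
                1000 * x$cleft$diameter, 1000 * x$cleft$height))
  invisible(x)
}

#' Generate an overlapping-sphere medium at a target occupied volume fraction
#'
#' Fills the arena cube with randomly sized, overlapping spheres until the
#' occupied volume fraction beta (= 1 - porosity alpha) reaches the target
#' within a relative tolerance. Sphere centres are uniform over the cube;
#' diameters are uniform over `diameter_range`. The origin (the release
#' site) is kept free of sphere material, as is the cleft cylinder when a
#' cleft is supplied. The initial sphere count comes from the Poisson
#' coverage relation beta = 1 - exp(-n * vbar / V); each refill pass
#' regenerates the medium with a count adjusted proportionally to the
#' remaining relative error, and convergence is checked with a fresh
#' Monte Carlo porosity estimate.
#'
#' @param beta_target Target occupied volume fraction, in (0, 1).
#' @param diameter_range Sphere diameter interval in um
#'   (default `c(0.020, 0.100)`, i.e. 20-100 nm).
#' @param arena_half_width Half-width of the arena cube in um (default 1.5,
#'   a 3 um cube).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param cleft Optional [cleft()]; candidate spheres intersecting the cleft
#'   cylinder are rejected during generation.
#' @param n_test_points Test points per porosity estimate (default 1e5).
#' @param rel_tol Relative tolerance on beta (default 0.05).
#' @param max_iter Maximum refill passes before giving up (default 50).
#' @return A `"sphere_medium"` with `beta_achieved` measured by the
#'   estimator (not the closed form).
#' @seealso [estimate_porosity()], [insert_cleft()], [make_fixture()]
#' @export
#' @examples
#' m <- generate_medium(0.3, arena_half_width = 0.5, seed = 1)
#' m$beta_achieved
generate_medium <- function(beta_target,
                            diameter_range = c(0.020, 0.100),
                            arena_half_width = 1.5,
                            seed = 1L,
                            cleft = NULL,
                            n_test_points = 1e5,
                            rel_tol = 0.05,
                            max_iter = 50L) {
  if (!is.numeric(beta_target) || length(beta_target) != 1 ||
      !is.finite(beta_target) || beta_target <= 0 || beta_target >= 1)
    stop("beta_target must lie strictly between 0 and 1")
  stopifnot(length(diameter_range) == 2, all(diameter_range > 0),
            diameter_range[1] <= diameter_range[2],
            diameter_range[2] < 2 * arena_half_width,
            arena_half_width > 0, n_test_points >= 1)
  if (!is.null(cleft) && !inherits(cleft, "cleft"))
    stop("cleft must be built with cleft()")

  rmin <- diameter_range[1] / 2
  rmax <- diameter_range[2] / 2
  # E[r^3] for r ~ U(rmin, rmax); mean sphere volume vbar = 4/3 pi E[r^3]
  er3 <- if (rmax > rmin) (rmax^4 - rmin^4) / (4 * (rmax - rmin)) else rmin^3
  vbar <- 4 / 3 * pi * er3
  V <- (2 * arena_half_width)^3
  n <- max(1L, as.integer(round(-log(1 - beta_target) * V / vbar)))

  set.seed(as.integer(seed))
  cl <- cleft_vec(cleft)
  for (iter in seq_len(max_iter)) {
    sph <- cpp_sample_spheres(n, arena_half_width, rmin, rmax, TRUE, cl)
    beta_hat <- cpp_estimate_beta(sph, arena_half_width,
                                  as.integer(n_test_points))
    if (abs(beta_hat - beta_target) / beta_target <= rel_tol) {
      spheres <- as.data.frame(sph)
      names(spheres) <- c("x", "y", "z", "radius")
      return(new_sphere_medium(spheres, arena_half_width,
                               beta_target = beta_target,
                               beta_achieved = beta_hat,
                               seed = as.integer(seed),
                               cleft = cleft))
    }
    n <- max(1L, as.integer(round(
      n * (1 + (beta_target - beta_hat) / beta_target))))
  }
  stop(sprintf(
    "sphere filling did not converge in %d passes: achieved beta = %.4f, target = %.4f",
    max_iter, beta_hat, beta_target))
}

#' Estimate medium porosity by uniform test points
#'
#' Scatters `n_points` test points uniformly through the arena cube and
#' returns the porosity estimate `alpha_hat`, the fraction of points that
#' fall outside every sphere. The occupied volume fraction is
#' `beta_hat = 1 - alpha_hat`. Cleft discs have zero volume and do not
#' affect the estimate.
#'
#' @param medium A `"sphere_medium"`.
#' @param n_points Number of test points (default 1e5; 1e6 changes the
#'   estimate by well under 1 percent relative).
#' @param seed Optional integer seed for the test-point stream.
#' @return The porosity estimate `alpha_hat` (scalar in \[0, 1\]).
#' @export
estimate_porosity <- function(medium, n_points = 1e5, seed = NULL) {
  stopifnot(inherits(medium, "sphere_medium"), n_points >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nrow(medium$spheres) == 0) return(1)
  1 - cpp_estimate_beta(sphere_matrix(medium), medium$arena_half_width,
                        as.integer(n_points))
}

#' Insert a transporter-free synaptic cleft into a medium
#'
#' Removes any sphere intersecting the cleft cylinder and attaches the
#' cleft to the medium. During simulation the two cleft discs (pre- and
#' postsynaptic membranes) reflect particles elastically and never capture
#' them; the lateral exits stay open.
#'
#' @param medium A `"sphere_medium"`.
#' @param cl A [cleft()] lying fully inside the arena.
#' @return The medium with the cleft attached and intersecting spheres
#'   removed.
#' @export
insert_cleft <- function(medium, cl = cleft()) {
  stopifnot(inherits(medium, "sphere_medium"))
  if (!inherits(cl, "cleft")) stop("cl must be built with cleft()")
  h <- medium$arena_half_width
  if (cl$diameter / 2 > h || cl$height / 2 > h)
    stop("cleft does not fit inside the arena")
  s <- medium$spheres
  if (nrow(s) > 0) {
    R <- cl$diameter / 2
    H <- cl$height / 2
    rho <- sqrt(s$x^2 + s$y^2)
    dr <- pmax(rho - R, 0)
    dz <- pmax(abs(s$z) - H, 0)
    keep <- dr^2 + dz^2 >= s$radius^2
    medium$spheres <- s[keep, , drop = FALSE]
    rownames(medium$spheres) <- NULL
  }
  medium$cleft <- cl
  medium
}

#' Signed distance to the nearest obstacle surface
#'
#' Returns, for a query point, the signed distance to the nearest obstacle
#' surface (sphere or cleft disc) together with the surface identity.
#' Sphere distances are negative when the point lies inside the sphere;
#' disc distances are always non-negative. Backed by the uniform-grid
#' spatial index with an exact expanding-shell search, so results agree
#' with a brute-force scan over all spheres.
#'
#' @param medium A `"sphere_medium"`.
#' @param point Numeric 3-vector, um, inside the arena.
#' @return A list with `distance` (um, signed), `surface` (`"sphere"`,
#'   `"disc"` or `"none"`), `id` (1-based sphere row, or -1/-2 for the
#'   +z/-z disc) and `interior` (`TRUE` when inside a sphere).
#' @export
nearest_surface_query <- function(medium, point) {
  stopifnot(inherits(medium, "sphere_medium"),
            is.numeric(point), length(point) == 3)
  res <- cpp_nearest_surface(sphere_matrix(medium), medium$arena_half_width,
                             cleft_vec(medium$cleft),
                             matrix(point, nrow = 1))
  id <- res$id[1]
  list(distance = res$distance[1],
       surface = if (id > 0) "sphere" else if (id < 0) "disc" else "none",
       id = id,
       interior = is.finite(res$distance[1]) && res$distance[1] < 0)
}

#' Write / read a medium as CSV plus a JSON sidecar
#'
#' The sphere table is written as CSV (`x, y, z, radius`, one sphere per
#' row, 17 significant digits so the round trip is lossless at full double
#' precision); arena size, seed, beta values and cleft dimensions go into
#' `<path>.json`.
#'
#' @param medium A `"sphere_medium"`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_medium()` returns `path` invisibly; `read_medium()`
#'   returns the reconstructed `"sphere_medium"`.
#' @export
write_medium <- function(medium, path) {
  stopifnot(inherits(medium, "sphere_medium"))
  s <- medium$spheres
  lines <- c("x,y,z,radius",
             sprintf("%.17g,%.17g,%.17g,%.17g", s$x, s$y, s$z, s$radius))
  writeLines(lines, path)
  meta <- list(arena_half_width = medium$arena_half_width,
               beta_target = medium$beta_target,
               beta_achieved = medium$beta_achieved,
               seed = medium$seed,
               cleft = if (is.null(medium$cleft)) NULL else
                 list(diameter = medium$cleft$diameter,
                      height = medium$cleft$height))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_medium
#' @param path CSV file path written by `write_medium()`.
#' @export
read_medium <- function(path) {
  s <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cl <- if (is.null(meta$cleft)) NULL else
    cleft(diameter = meta$cleft$diameter, height = meta$cleft$height)
  new_sphere_medium(s, meta$arena_half_width,
                    beta_target = meta$beta_target %||% NA_real_,
                    beta_achieved = meta$beta_achieved %||% NA_real_,
                    seed = meta$seed %||% NA_integer_,
                    cleft = cl)
}

#' Export sphere centres in XYZ format for 3D viewers
#'
#' Each sphere becomes one record `S x y z radius` after the standard
#' two-line XYZ header.
#'
#' @param medium A `"sphere_medium"`.
#' @param path Output file path.
#' @export
write_medium_xyz <- function(medium, path) {
  s <- medium$spheres
  lines <- c(as.character(nrow(s)),
             sprintf("overlapping-sphere medium, arena %.6g um cube",
                     2 * medium$arena_half_width),
             sprintf("S %.9g %.9g %.9g %.9g", s$x, s$y, s$z, s$radius))
  writeLines(lines, path)
  invisible(path)
}
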