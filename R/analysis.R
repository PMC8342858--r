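#' Spatial scatter histogram of a particle ensemble
#'
#' Bins the particle coordinates along one axis over the arena extent.
#' Free and bound particles are counted together (bound particles at their
#' capture position), so the histogram mirrors what a saturating optical
#' glutamate sensor would report; escaped particles (absorb-count mode)
#' are dropped. Default is 60 bins across the 3 um arena, i.e. 50 nm bins.
#'
#' @param ensemble A `"particle_ensemble"`.
#' @param axis One of `"x"`, `"y"`, `"z"` (default `"x"`).
#' @param n_bins Number of equal-width bins (default 60).
#' @param half_width Arena half-width in um (default 1.5).
#' @param fit If `TRUE` (default), fit the Gaussian immediately and store
#'   `sigma`/`fit_ok` in the profile.
#' @return An object of class `"scatter_profile"`: `axis`, `bin_edges`,
#'   `counts`, `time`, `sigma` (um, `NA` until fitted), `fit_ok`.
#' @export
histogram_scatter <- function(ensemble, axis = c("x", "y", "z"), n_bins = 60,
                              half_width = 1.5, fit = TRUE) {
  stopifnot(inherits(ensemble, "particle_ensemble"), n_bins >= 1)
  axis <- match.arg(axis)
  keep <- ensemble$status != 2L
  if (!any(keep)) stop("ensemble has no particles to histogram")
  v <- ensemble$positions[keep, match(axis, c("x", "y", "z"))]
  edges <- seq(-half_width, half_width, length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  prof <- structure(list(axis = axis, bin_edges = edges, counts = counts,
                         time = ensemble$time, sigma = NA_real_,
                         fit_ok = FALSE),
                    class = "scatter_profile")
  if (fit) {
    s <- fit_gaussian_sigma(prof)
    prof$sigma <- as.numeric(s)
    prof$fit_ok <- attr(s, "fit_ok")
  }
  prof
}

#' @export
print.scatter_profile <- function(x, ...) {
  cat(sprintf("<scatter_profile> %s-axis, t = %.4g ms, %d particles in %d bins",
              x$axis, x$time, sum(x$counts), length(x$counts)))
  if (!is.na(x$sigma))
    cat(sprintf(", sigma = %.4g um%s", x$sigma,
                if (x$fit_ok) "" else " (fallback)"))
  cat("\n")
  invisible(x)
}

profile_centres <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Best-fit Gaussian dispersion of a scatter profile
#'
#' Fits a centred, amplitude-free Gaussian `A * exp(-x^2 / (2 sigma^2))`
#' to the bin counts by unweighted least squares and returns the
#' dispersion sigma (the standard deviation of the fitted distribution).
#' The fit is robust to the skew that obstacle aggregates produce in dense
#' media: quality is reported through the `fit_ok` attribute, not
#' enforced. If the optimiser fails or the profile is degenerate (mass in
#' a single bin), sigma falls back to the count-weighted sample standard
#' deviation and `fit_ok` is `FALSE`.
#'
#' @param profile A `"scatter_profile"` with at least 5 non-empty bins for
#'   a proper fit.
#' @param weighted If `TRUE`, weight residuals by 1/max(count, 1)
#'   (Poisson-style); default `FALSE` (unweighted).
#' @return Sigma in um, with attributes `fit_ok` and `amplitude`.
#' @export
fit_gaussian_sigma <- function(profile, weighted = FALSE) {
  stopifnot(inherits(profile, "scatter_profile"))
  x <- profile_centres(profile)
  y <- profile$counts
  tot <- sum(y)
  if (tot == 0) stop("empty profile")
  mu <- sum(x * y) / tot
  s0 <- sqrt(max(sum((x - mu)^2 * y) / tot, 0))
  fallback <- function() structure(s0, fit_ok = FALSE, amplitude = max(y))
  if (sum(y > 0) < 5 || s0 == 0) return(fallback())
  w <- if (weighted) 1 / pmax(y, 1) else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x^2 / (2 * s^2)),
                      start = list(A = max(y), s = max(s0, 1e-3)),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  p <- coef(fit)
  s_hat <- abs(unname(p["s"]))
  if (!is.finite(s_hat) || s_hat <= 0) return(fallback())
  structure(s_hat, fit_ok = TRUE, amplitude = unname(p["A"]))
}

#' Capture-distance statistics of bound particles
#'
#' Summarises where the bound molecules were captured, under two metrics:
#' the Euclidean distance from the origin (the release site at the cleft
#' centre), and -- when a cleft is present -- the distance beyond the
#' cleft edge (distance to the cleft cylinder surface, zero for a capture
#' touching it). The second metric is the physically meaningful "distance
#' from the cleft": the transporter-free cleft spans half its diameter
#' laterally, so origin distances below that are impossible by
#' construction. Also returns the cumulative fraction of the whole
#' ensemble captured within a radius and, from a `"run_summary"`, the
#' bound-fraction time course.
#'
#' @param x A `"particle_ensemble"` or `"run_summary"` (its final
#'   ensemble is used; the run's cleft geometry is picked up
#'   automatically).
#' @param cl Optional [cleft()] for the edge metric when `x` is a bare
#'   ensemble.
#' @return An object of class `"capture_stats"`: `distances` (um from the
#'   origin, one per bound particle), `median`, `distances_from_cleft` /
#'   `median_from_cleft` (um beyond the cleft edge, `NULL`/`NA` without a
#'   cleft), `bound_fraction`, `fraction_within(r)` (origin metric,
#'   non-decreasing, reaching `bound_fraction` at infinity), `quantiles`
#'   (50/75/90/95 percent, origin metric), `any_bound`, `timecourse`.
#' @export
capture_statistics <- function(x, cl = NULL) {
  tc <- NULL
  if (inherits(x, "run_summary")) {
    tc <- x$timecourse[, c("time", "bound_fraction")]
    if (is.null(cl) && isTRUE(x$medium_info$cleft))
      cl <- cleft(diameter = x$medium_info$cleft_diameter,
                  height = x$medium_info$cleft_height)
    x <- x$final
  }
  stopifnot(inherits(x, "particle_ensemble"))
  n <- nrow(x$positions)
  bp <- bind_positions(x)
  d <- if (nrow(bp)) sqrt(rowSums(bp^2)) else numeric(0)
  dcl <- NULL
  if (!is.null(cl) && nrow(bp)) {
    rho <- sqrt(bp[, 1]^2 + bp[, 2]^2)
    dcl <- sqrt(pmax(rho - cl$diameter / 2, 0)^2 +
                pmax(abs(bp[, 3]) - cl$height / 2, 0)^2)
  }
  bound_fraction <- nrow(bp) / n
  fraction_within <- function(r) {
    vapply(r, function(ri) sum(d <= ri) / n, numeric(1))
  }
  structure(list(distances = d,
                 median = if (length(d)) median(d) else NA_real_,
                 distances_from_cleft = dcl,
                 median_from_cleft = if (length(dcl)) median(dcl)
                                     else NA_real_,
                 bound_fraction = bound_fraction,
                 fraction_within = fraction_within,
                 quantiles = if (length(d))
                   quantile(d, c(0.5, 0.75, 0.9, 0.95)) else NULL,
                 any_bound = length(d) > 0,
                 timecourse = tc),
            class = "capture_stats")
}

#' @export
print.capture_stats <- function(x, ...) {
  if (!x$any_bound) {
    cat("<capture_stats> no bound particles\n")
    return(invisible(x))
  }
  cat(sprintf("<capture_stats> %.1f%% bound; median capture distance %.0f nm from the origin",
              100 * x$bound_fraction, 1000 * x$median))
  if (!is.null(x$distances_from_cleft))
    cat(sprintf(", %.0f nm beyond the cleft edge", 1000 * x$median_from_cleft))
  cat("\n")
  invisible(x)
}

#' Effective diffusion coefficient from mean squared displacement
#'
#' Regresses the mean squared displacement of the free particles against
#' `6 t` (zero intercept) over the sampled time course and returns the
#' slope, the effective diffusion coefficient in um^2/ms. In an empty
#' arena this verifies the stepping rule: the calibrated rule recovers the
#' nominal D, the literal rule (4/3) D. In a porous medium it reports the
#' hindered, not the free, coefficient.
#'
#' @param x A `"run_summary"`, or a data frame with columns `time` and
#'   `msd_free` (and optionally `n_free`).
#' @param t_max Use only samples with `time <= t_max` (default `Inf`);
#'   restricts the fit to the pre-boundary regime if needed.
#' @return Effective D in um^2/ms.
#' @export
measure_effective_D <- function(x, t_max = Inf) {
  tc <- if (inherits(x, "run_summary")) x$timecourse else x
  stopifnot(is.data.frame(tc), all(c("time", "msd_free") %in% names(tc)))
  ok <- is.finite(tc$msd_free) & tc$time > 0 & tc$time <= t_max
  if (!is.null(tc$n_free)) ok <- ok & tc$n_free > 0
  tc <- tc[ok, ]
  if (nrow(tc) < 2)
    stop("need at least 2 time points with free particles to measure D")
  unname(coef(lm(msd_free ~ 0 + time, data = tc))[1]) / 6
}

#' Per-run summary table
#'
#' One row per checkpoint: time, fitted sigma of the x-axis scatter, bound
#' fraction, median capture distance, and the run's porosity and binding
#' probability. This is the tabular counterpart of the histogram figures.
#'
#' @param run A `"run_summary"`.
#' @param n_bins,axis Passed to [histogram_scatter()].
#' @return A data frame.
#' @export
summarize_run <- function(run, n_bins = 60, axis = "x") {
  stopifnot(inherits(run, "run_summary"))
  cl <- if (isTRUE(run$medium_info$cleft))
    cleft(diameter = run$medium_info$cleft_diameter,
          height = run$medium_info$cleft_height) else NULL
  rows <- lapply(run$checkpoints, function(ens) {
    prof <- histogram_scatter(ens, axis = axis, n_bins = n_bins,
                              half_width = run$medium_info$arena_half_width)
    cs <- capture_statistics(ens, cl = cl)
    data.frame(time = ens$time,
               sigma = prof$sigma,
               fit_ok = prof$fit_ok,
               bound_fraction = cs$bound_fraction,
               median_capture_nm = 1000 * cs$median,
               median_beyond_cleft_nm = 1000 * cs$median_from_cleft,
               within_100nm = cs$fraction_within(0.1))
  })
  out <- do.call(rbind, rows)
  out$alpha <- run$medium_info$alpha
  out$p_bind <- run$config$p_bind
  rownames(out) <- NULL
  out
}

#' Plot a scatter profile with its Gaussian overlay
#'
#' Draws the binned particle counts with the best-fit centred Gaussian,
#' in the style of the spatial-distribution panels of the simulation
#' figures. `log = "y"` shows the low-count tail on a log ordinate.
#'
#' @param x A `"scatter_profile"`.
#' @param log `""` (default) or `"y"`.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.scatter_profile <- function(x, log = "", ...) {
  centres <- profile_centres(x)
  y <- x$counts
  if (log == "y") y <- pmax(y, 0.5)
  graphics::plot(centres, y, type = "h", lwd = 3, col = "grey55", log = log,
                 xlab = sprintf("%s (um)", x$axis), ylab = "molecules",
                 main = sprintf("t = %.3g ms", x$time), ...)
  if (!is.na(x$sigma) && x$sigma > 0) {
    s <- fit_gaussian_sigma(x)
    A <- attr(s, "amplitude")
    xx <- seq(min(centres), max(centres), length.out = 400)
    yy <- A * exp(-xx^2 / (2 * x$sigma^2))
    if (log == "y") yy <- pmax(yy, 0.5)
    graphics::lines(xx, yy, col = "firebrick", lwd = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("sigma = %.0f nm", 1000 * x$sigma))
  }
  invisible(x)
}
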