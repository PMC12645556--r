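#' Curvature and radius-of-curvature profile of a spine curve
#'
#' Evaluates the Frenet curvature kappa(t) = ||gamma' x gamma''|| / ||gamma'||^3
#' and the radius of curvature r(t) = 1/kappa(t) on a uniform parameter grid,
#' together with cumulative arc length and arc-length-weighted scalar
#' summaries. Curvature below `flat_tol` is treated as exactly flat and
#' reported with an infinite radius.
#'
#' @param curve A [fit_spine_curve()] result.
#' @param grid_size Number of uniform grid points in [0, 1] (default 512).
#' @param flat_tol Curvature floor in 1/mm below which a point counts as flat.
#' @return An object of class `curvature_profile`: a list with `t_grid`,
#'   `position`, `kappa` (1/mm), `radius` (mm, `Inf` where flat),
#'   `arc_length` (cumulative, mm) and `summaries`
#'   (`max_kappa`, `mean_kappa`, `total_curvature`, `arc_length`,
#'   `t_max_kappa`).
#' @export
curvature_profile <- function(curve, grid_size = 512L, flat_tol = 1e-12) {
  if (!inherits(curve, "spine_curve")) stop_usage("not a spine_curve")
  if (grid_size < 8L) stop_usage("grid_size must be >= 8")
  tg <- seq(0, 1, length.out = grid_size)
  ev <- evaluate_curve(curve, tg)
  speed <- sqrt(rowSums(ev$d1^2))
  if (any(speed < 1e-12))
    stop_validation("degenerate tangent: ||gamma'(t)|| ~ 0 at t = %.4f",
                    tg[which(speed < 1e-12)[1]])
  cr <- cross3(ev$d1, ev$d2)
  kappa <- sqrt(rowSums(cr^2)) / speed^3
  flat <- kappa < flat_tol
  kappa[flat] <- 0
  radius <- ifelse(flat, Inf, 1 / kappa)
  dt <- tg[2] - tg[1]
  # trapezoidal cumulative arc length s(t) = integral of ||gamma'||
  ds <- dt * (speed[-1] + speed[-grid_size]) / 2
  arc <- c(0, cumsum(ds))
  total_len <- arc[grid_size]
  # integral of kappa ds by the same trapezoidal rule
  f <- kappa * speed
  total_curv <- sum(dt * (f[-1] + f[-grid_size]) / 2)
  i_max <- which.max(kappa)  # which.max returns the first (smallest-t) maximum
  structure(list(
    t_grid = tg, position = ev$position, kappa = kappa, radius = radius,
    arc_length = arc,
    summaries = list(max_kappa = kappa[i_max],
                     mean_kappa = total_curv / total_len,
                     total_curvature = total_curv,
                     arc_length = total_len,
                     t_max_kappa = tg[i_max])),
    class = "curvature_profile")
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Scalar curvature summary
#'
#' @param profile A [curvature_profile()].
#' @param kind `"max"` (peak curvature), `"mean"` (arc-length-weighted mean,
#'   total curvature divided by arc length) or `"total"` (integral of kappa
#'   with respect to arc length, in radians).
#' @return A numeric scalar.
#' @export
curvature_summary <- function(profile, kind = c("mean", "max", "total")) {
  if (!inherits(profile, "curvature_profile")) stop_usage("not a curvature_profile")
  kind <- match.arg(kind)
  switch(kind,
         max = profile$summaries$max_kappa,
         mean = profile$summaries$mean_kappa,
         total = profile$summaries$total_curvature)
}

#' Export a curvature profile as a data frame
#'
#' One row per grid point with position, curvature, radius and cumulative arc
#' length, suitable for writing to CSV.
#'
#' @param profile A [curvature_profile()].
#' @return A data frame with columns `t`, `x_mm`, `y_mm`, `z_mm`,
#'   `kappa_per_mm`, `radius_mm`, `arclen_mm`.
#' @export
curvature_profile_df <- function(profile) {
  data.frame(t = profile$t_grid,
             x_mm = profile$position[, 1], y_mm = profile$position[, 2],
             z_mm = profile$position[, 3],
             kappa_per_mm = profile$kappa, radius_mm = profile$radius,
             arclen_mm = profile$arc_length)
}

#' @export
print.curvature_profile <- function(x, ...) {
  s <- x$summaries
  cat(sprintf(paste0("curvature_profile: %d points, arc length %.2f mm, ",
                     "max kappa %.4g /mm, total curvature %.4g rad\n"),
              length(x$t_grid), s$arc_length, s$max_kappa, s$total_curvature))
  invisible(x)
}
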