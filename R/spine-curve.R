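#' Collapse vertebrae to a centroid polyline
#'
#' Reduces a landmark point cloud to one 3-D point per vertebra, the
#' arithmetic mean of that vertebra's landmarks. For ring-shaped landmark sets
#' the centroid coincides with the ring centre, so the polyline tracks the
#' anatomical centerline.
#'
#' @param cloud A [spine_point_cloud()].
#' @return A numeric matrix (vertebrae x 3), rostral to caudal, in mm.
#' @export
collapse_vertebrae <- function(cloud) {
  validate_spine_point_cloud(cloud)
  t(vapply(cloud$vertebrae, function(v) colMeans(v$landmarks), numeric(3)))
}

#' Fit a flat-ended cubic-spline centerline
#'
#' Fits a parametric cubic spline gamma(t) = (x(t), y(t), z(t)), t in [0, 1],
#' through an ordered 3-D polyline (typically vertebral centroids). The spline
#' is *natural*: its second derivative vanishes at both ends, which forces the
#' curvature to zero there — the "flat at the extremes" constraint that keeps
#' the head- and tail-ward ends of an annotated spine from contributing
#' spurious curvature. Knots are placed at normalized cumulative chord length
#' by default.
#'
#' With `smoothing > 0` the coordinates are first smoothed along the
#' parameter by a cubic smoothing spline (penalty `lambda = smoothing`), then
#' interpolated naturally, so the boundary constraint always holds exactly.
#' `smoothing = "gcv"` selects the penalty per coordinate by generalized
#' cross-validation, the recommended setting for noisy landmark data.
#'
#' @param centroids Numeric matrix (n x 3), n >= 4, no two consecutive rows
#'   identical.
#' @param smoothing Non-negative smoothing penalty (0 interpolates), or
#'   `"gcv"` for automatic selection.
#' @param parametrization `"chord"` (normalized cumulative chord length,
#'   default) or `"uniform"`.
#' @return An object of class `spine_curve` with fields `knots` (parameter
#'   values, 0 to 1), `coef` (per-coordinate interval-wise cubic coefficients),
#'   `parametrization` and `boundary = "natural"`.
#' @export
fit_spine_curve <- function(centroids, smoothing = 0,
                            parametrization = c("chord", "uniform")) {
  parametrization <- match.arg(parametrization)
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L) stop_usage("centroids must be an n x 3 matrix")
  n <- nrow(centroids)
  if (n < 4L) stop_validation("need >= 4 points to fit a spine curve, got %d", n)
  if (!all(is.finite(centroids))) stop_validation("non-finite centroid coordinate")
  seg <- sqrt(rowSums((centroids[-1, , drop = FALSE] -
                       centroids[-n, , drop = FALSE])^2))
  if (any(seg < 1e-12))
    stop_validation("degenerate parametrization: consecutive duplicate points")
  knots <- switch(parametrization,
                  chord = c(0, cumsum(seg)) / sum(seg),
                  uniform = seq(0, 1, length.out = n))
  vals <- centroids
  gcv <- identical(smoothing, "gcv")
  if (!gcv && (!is.numeric(smoothing) || length(smoothing) != 1L || smoothing < 0))
    stop_usage("smoothing must be a non-negative number or \"gcv\"")
  if (gcv || smoothing > 0) {
    vals <- apply(centroids, 2, function(y) {
      fit <- if (gcv) stats::smooth.spline(knots, y, all.knots = TRUE)
             else stats::smooth.spline(knots, y, lambda = smoothing,
                                       all.knots = TRUE)
      stats::predict(fit, knots)$y
    })
  }
  coef <- lapply(1:3, function(j) natural_spline_coef(knots, vals[, j]))
  structure(list(knots = knots, coef = coef,
                 parametrization = parametrization, boundary = "natural"),
            class = "spine_curve")
}

# Natural cubic spline through (x_i, y_i): second derivatives M solve a
# tridiagonal system with M_1 = M_n = 0; interval i gets
# S_i(u) = a + b u + c u^2 + d u^3, u = x - x_i.
natural_spline_coef <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)
  if (n > 2L) {
    m <- n - 2L
    A <- matrix(0, m, m)
    diag(A) <- 2 * (h[-n + 1L][1:m] + h[2:(m + 1L)])
    if (m > 1L) {
      A[cbind(1:(m - 1L), 2:m)] <- h[2:m]
      A[cbind(2:m, 1:(m - 1L))] <- h[2:m]
    }
    rhs <- 6 * diff(diff(y) / h)
    M[2:(n - 1L)] <- solve(A, rhs)
  }
  i <- seq_len(n - 1L)
  cbind(a = y[i],
        b = diff(y) / h - h * (2 * M[i] + M[i + 1L]) / 6,
        c = M[i] / 2,
        d = (M[i + 1L] - M[i]) / (6 * h))
}

#' Evaluate a spine curve and its derivatives
#'
#' Evaluates positions and the analytic first and second derivatives of the
#' stored piecewise cubics with respect to the curve parameter (no finite
#' differencing).
#'
#' @param curve A [fit_spine_curve()] result.
#' @param t Numeric vector of parameter values in [0, 1].
#' @return A list with matrices `position`, `d1`, `d2` (length(t) x 3).
#' @export
evaluate_curve <- function(curve, t) {
  if (!inherits(curve, "spine_curve")) stop_usage("not a spine_curve")
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0 | t > 1))
    stop_usage("curve parameter t must lie in [0, 1]")
  k <- curve$knots
  idx <- findInterval(t, k, rightmost.closed = TRUE, all.inside = TRUE)
  u <- t - k[idx]
  out <- lapply(curve$coef, function(cf) {
    a <- cf[idx, "a"]; b <- cf[idx, "b"]; cc <- cf[idx, "c"]; d <- cf[idx, "d"]
    list(p = a + u * (b + u * (cc + u * d)),
         d1 = b + u * (2 * cc + 3 * u * d),
         d2 = 2 * cc + 6 * d * u)
  })
  list(position = cbind(out[[1]]$p, out[[2]]$p, out[[3]]$p),
       d1 = cbind(out[[1]]$d1, out[[2]]$d1, out[[3]]$d1),
       d2 = cbind(out[[1]]$d2, out[[2]]$d2, out[[3]]$d2))
}

#' @export
print.spine_curve <- function(x, ...) {
  cat(sprintf("spine_curve: %d knots, %s parametrization, %s boundary\n",
              length(x$knots), x$parametrization, x$boundary))
  invisible(x)
}
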