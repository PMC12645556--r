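plane_normal <- function(plane) {
  if (is.numeric(plane)) {
    if (length(plane) != 3L || sqrt(sum(plane^2)) < 1e-12)
      stop_usage("custom plane normal must be a non-zero length-3 vector")
    return(plane / sqrt(sum(plane^2)))
  }
  # x = medio-lateral, y = dorso-ventral, z = rostro-caudal:
  # the coronal plane is x-z (normal y), the sagittal plane is y-z (normal x)
  switch(match.arg(plane, c("coronal", "sagittal")),
         coronal = c(0, 1, 0),
         sagittal = c(1, 0, 0))
}

#' Project a spine curve into an anatomical plane
#'
#' Orthogonally projects curve positions and tangents into a named plane
#' (scoliosis is read in the coronal plane, kyphosis in the sagittal plane) or
#' into the plane orthogonal to a custom normal vector. Projected tangents are
#' renormalized; grid points whose projected tangent nearly vanishes (the
#' curve runs almost orthogonal to the plane there) are dropped.
#'
#' @param curve A [fit_spine_curve()] result.
#' @param plane `"coronal"`, `"sagittal"`, or a length-3 normal vector.
#' @param grid_size Number of uniform parameter values (default 512).
#' @return A list of class `projected_curve` with `t` (retained parameters),
#'   `points` (n x 2, in-plane coordinates), `tangents` (n x 2, unit),
#'   `plane`.
#' @export
project_curve <- function(curve, plane = "coronal", grid_size = 512L) {
  nrm <- plane_normal(plane)
  # in-plane orthonormal basis (e1, e2)
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  tg <- seq(0, 1, length.out = grid_size)
  ev <- evaluate_curve(curve, tg)
  pts <- cbind(ev$position %*% e1, ev$position %*% e2)
  tans <- cbind(ev$d1 %*% e1, ev$d1 %*% e2)
  nt <- sqrt(rowSums(tans^2))
  keep <- nt >= 1e-9
  if (mean(keep) < 0.5)
    stop_validation("projection degenerate: curve nearly orthogonal to the plane")
  structure(list(t = tg[keep], points = pts[keep, , drop = FALSE],
                 tangents = tans[keep, , drop = FALSE] / nt[keep],
                 plane = if (is.numeric(plane)) "custom" else plane),
            class = "projected_curve")
}

#' Analytic Cobb angle of a projected centerline
#'
#' The automated surrogate for the clinical Cobb angle: the maximum unsigned
#' angle between any two centerline tangents in the projection plane, tangents
#' oriented rostral to caudal, angle taken in [0, 180) degrees. For a planar
#' circular arc this equals the arc's subtended angle, the quantity the
#' clinical endplate construction approximates. Ties are broken toward the
#' smallest (t_lower, t_upper) pair.
#'
#' @param projected A [project_curve()] result.
#' @return A list of class `cobb_measurement` with `plane`, `angle_deg`,
#'   `t_lower`, `t_upper`.
#' @export
cobb_angle <- function(projected) {
  if (!inherits(projected, "projected_curve")) stop_usage("not a projected_curve")
  n <- nrow(projected$tangents)
  if (n < 3L) stop_validation("need >= 3 tangent samples, got %d", n)
  theta <- atan2(projected$tangents[, 2], projected$tangents[, 1])
  # pairwise angle between oriented unit tangents: |dtheta| wrapped to [0, 180]
  d <- abs(outer(theta, theta, "-")) * 180 / pi
  d <- pmin(d, 360 - d)
  d[lower.tri(d, diag = TRUE)] <- -1  # keep i < j only (column-major upper tri)
  best <- max(d)
  # smallest (i, j) lexicographically among ties (to fp precision)
  hits <- which(d >= best - 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  structure(list(plane = projected$plane,
                 angle_deg = max(best, 0),
                 t_lower = projected$t[i], t_upper = projected$t[j]),
            class = "cobb_measurement")
}

#' Cobb angle of a landmark point cloud
#'
#' Convenience wrapper running centroid collapse, flat-ended spline fit,
#' projection and the analytic Cobb angle in one call.
#'
#' @param cloud A [spine_point_cloud()].
#' @param plane Projection plane, as in [project_curve()].
#' @param grid_size Evaluation grid (default 512).
#' @param smoothing Spline smoothing passed to [fit_spine_curve()].
#' @return A `cobb_measurement`.
#' @export
spine_cobb <- function(cloud, plane = "coronal", grid_size = 512L, smoothing = 0) {
  curve <- fit_spine_curve(collapse_vertebrae(cloud), smoothing = smoothing)
  cobb_angle(project_curve(curve, plane = plane, grid_size = grid_size))
}

#' @export
print.cobb_measurement <- function(x, ...) {
  cat(sprintf("cobb_measurement: %.2f deg in %s plane (t = %.3f .. %.3f)\n",
              x$angle_deg, x$plane, x$t_lower, x$t_upper))
  invisible(x)
}
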