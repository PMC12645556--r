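#' Synthetic spine template
#'
#' Describes an analytic spine centerline plus the landmark-sampling scheme
#' used to emulate an annotated micro-CT spine: `n_vertebrae` stations at
#' equal arc-length spacing along the centerline, each carrying a ring of
#' `landmarks_per_vertebra` points of radius `ring_radius` in the plane normal
#' to the local tangent, perturbed by isotropic Gaussian noise.
#'
#' Shapes (the long axis is z, rostral to caudal):
#' \describe{
#'   \item{`straight`}{a straight segment; zero curvature everywhere.}
#'   \item{`arc`}{a circular arc; `deformity_amplitude` is the subtended angle
#'     in degrees (its analytic Cobb angle), bending into `deformity_plane`.}
#'   \item{`sinusoid`}{lateral displacement `A sin(2 pi n_periods u)` with
#'     amplitude `deformity_amplitude` in mm.}
#'   \item{`s_curve`}{two opposed bends with tangent angle
#'     `theta(u) = a sin(2 pi u)` about the long axis, `a =
#'     deformity_amplitude` in degrees; each bend deflects the tangent by at
#'     most `a`, so the analytic Cobb angle is `2 a`.}
#' }
#'
#' @param shape One of `"straight"`, `"arc"`, `"sinusoid"`, `"s_curve"`.
#' @param n_vertebrae Number of vertebra stations (default 24, the annotated
#'   cervical-to-lumbar mouse column).
#' @param spine_length Centerline arc length in mm (default 80).
#' @param deformity_amplitude Shape-dependent amplitude (degrees for `arc` and
#'   `s_curve`, mm for `sinusoid`); >= 0.
#' @param n_periods Periods of the sinusoid shape (default 1.5).
#' @param deformity_plane `"coronal"` (lateral bending, x) or `"sagittal"`
#'   (dorso-ventral bending, y).
#' @param landmarks_per_vertebra Ring size (default 8).
#' @param ring_radius Ring radius in mm (default 0.8).
#' @param noise_sd Isotropic landmark noise SD in mm (default 0).
#' @param seed Integer seed for the landmark noise.
#' @return A list of class `spine_template`.
#' @export
spine_template <- function(shape = c("straight", "arc", "sinusoid", "s_curve"),
                           n_vertebrae = 24L, spine_length = 80,
                           deformity_amplitude = 0, n_periods = 1.5,
                           deformity_plane = c("coronal", "sagittal"),
                           landmarks_per_vertebra = 8L, ring_radius = 0.8,
                           noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  deformity_plane <- match.arg(deformity_plane)
  if (n_vertebrae < 4L) stop_validation("n_vertebrae must be >= 4")
  if (spine_length <= 0) stop_validation("spine_length must be > 0")
  if (deformity_amplitude < 0) stop_validation("deformity_amplitude must be >= 0")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (shape == "arc" && deformity_amplitude > 180)
    stop_validation("arc amplitude > 180 degrees would self-intersect")
  structure(list(shape = shape, n_vertebrae = as.integer(n_vertebrae),
                 spine_length = spine_length,
                 deformity_amplitude = deformity_amplitude,
                 n_periods = n_periods, deformity_plane = deformity_plane,
                 landmarks_per_vertebra = as.integer(landmarks_per_vertebra),
                 ring_radius = ring_radius, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spine_template")
}

# analytic centerline sampled at n equal-arc-length stations:
# positions, unit tangents, true curvature (1/mm) and true Cobb angle (deg)
centerline_truth <- function(tpl) {
  n <- tpl$n_vertebrae
  L <- tpl$spine_length
  u <- seq(0, 1, length.out = n)
  lat <- if (tpl$deformity_plane == "coronal") c(1, 0, 0) else c(0, 1, 0)
  ax <- c(0, 0, 1)
  amp <- tpl$deformity_amplitude

  if (tpl$shape == "straight" || amp == 0) {
    pos <- outer(u * L, ax)
    tan <- matrix(ax, n, 3, byrow = TRUE)
    return(list(position = pos, tangent = tan, kappa = rep(0, n), cobb_deg = 0))
  }
  if (tpl$shape == "arc") {
    phi <- amp * pi / 180
    R <- L / phi
    th <- phi * (u - 0.5)             # tangent angle about the long axis
    w <- R * (cos(th[1]) - cos(th))
    z <- R * (sin(th) - sin(th[1]))
    pos <- outer(w, lat) + outer(z, ax)
    tan <- outer(sin(th), lat) + outer(cos(th), ax)
    return(list(position = pos, tangent = tan, kappa = rep(1 / R, n),
                cobb_deg = amp))
  }
  if (tpl$shape == "s_curve") {
    a <- amp * pi / 180
    # integrate the tangent-angle profile theta(u) = a sin(2 pi u) finely,
    # then pick off the equally spaced arc-length stations
    m <- 4096L
    uf <- seq(0, 1, length.out = m + 1L)
    thf <- a * sin(2 * pi * uf)
    dw <- sin(thf); dz <- cos(thf)
    h <- L / m
    wf <- c(0, cumsum(h * (dw[-1] + dw[-(m + 1L)]) / 2))
    zf <- c(0, cumsum(h * (dz[-1] + dz[-(m + 1L)]) / 2))
    w <- stats::approx(uf, wf, xout = u)$y
    z <- stats::approx(uf, zf, xout = u)$y
    th <- a * sin(2 * pi * u)
    pos <- outer(w, lat) + outer(z, ax)
    tan <- outer(sin(th), lat) + outer(cos(th), ax)
    kap <- a * 2 * pi / L * abs(cos(2 * pi * u))  # |d theta / d s|
    return(list(position = pos, tangent = tan, kappa = kap, cobb_deg = 2 * amp))
  }
  # sinusoid: lateral A sin(2 pi k v) against axial v * Lz; stations are
  # re-sampled to equal arc length numerically
  k <- tpl$n_periods
  A <- amp
  m <- 4096L
  vf <- seq(0, 1, length.out = m + 1L)
  wf <- A * sin(2 * pi * k * vf)
  dw <- A * 2 * pi * k * cos(2 * pi * k * vf)
  # choose the axial extent so total arc length equals spine_length
  arc_unit <- function(Lz) {
    sp <- sqrt(dw^2 + Lz^2)
    sum((sp[-1] + sp[-(m + 1L)]) / 2) / m
  }
  if (arc_unit(1e-9) >= L)
    stop_validation("sinusoid amplitude %.3g mm too large for spine_length %.3g mm",
                    A, L)
  Lz <- stats::uniroot(function(x) arc_unit(x) - L, c(1e-9, L),
                       tol = 1e-10)$root
  sp <- sqrt(dw^2 + Lz^2)
  sf <- c(0, cumsum((sp[-1] + sp[-(m + 1L)]) / 2 / m))
  v <- stats::approx(sf, vf, xout = u * sf[m + 1L])$y
  wv <- A * sin(2 * pi * k * v)
  dwv <- A * 2 * pi * k * cos(2 * pi * k * v)
  d2w <- -A * (2 * pi * k)^2 * sin(2 * pi * k * v)
  spv <- sqrt(dwv^2 + Lz^2)
  pos <- outer(wv, lat) + outer(v * Lz, ax)
  tan <- (outer(dwv, lat) + outer(rep(Lz, n), ax)) / spv
  kap <- abs(d2w * Lz) / spv^3
  th <- atan2(dwv, Lz)
  list(position = pos, tangent = tan, kappa = kap,
       cobb_deg = (max(th) - min(th)) * 180 / pi)
}

#' Generate a synthetic landmark point cloud
#'
#' Samples the template's analytic centerline at `n_vertebrae` equal
#' arc-length stations, places a landmark ring in the plane normal to the
#' local tangent at each station, and adds seeded isotropic Gaussian noise.
#' The analytic ground truth travels with the result so downstream accuracy
#' checks never re-derive it.
#'
#' @param template A [spine_template()].
#' @param spine_id,group Identifier and group label for the resulting cloud.
#' @return A [spine_point_cloud()] whose `"truth"` attribute holds the
#'   station positions and tangents, the true curvature profile `kappa`
#'   (1/mm) and the analytic Cobb angle `cobb_deg`.
#' @export
generate_spine <- function(template, spine_id = "synthetic", group = "synthetic") {
  if (!inherits(template, "spine_template")) stop_usage("not a spine_template")
  truth <- centerline_truth(template)
  n <- template$n_vertebrae
  m <- template$landmarks_per_vertebra
  ang <- 2 * pi * (seq_len(m) - 1) / m
  verts <- with_preserved_seed(template$seed, {
    lapply(seq_len(n), function(i) {
      T <- truth$tangent[i, ]
      ref <- if (abs(T[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n1 <- ref - sum(ref * T) * T
      n1 <- n1 / sqrt(sum(n1^2))
      n2 <- c(T[2] * n1[3] - T[3] * n1[2],
              T[3] * n1[1] - T[1] * n1[3],
              T[1] * n1[2] - T[2] * n1[1])
      ring <- matrix(truth$position[i, ], m, 3, byrow = TRUE) +
        template$ring_radius * (outer(cos(ang), n1) + outer(sin(ang), n2))
      if (template$noise_sd > 0)
        ring <- ring + matrix(stats::rnorm(3 * m, sd = template$noise_sd), m, 3)
      list(index = i, landmarks = ring)
    })
  })
  cloud <- spine_point_cloud(spine_id, group, verts)
  attr(cloud, "truth") <- c(truth, list(template = template))
  cloud
}

# deterministic per-spine sub-seed from a top-level seed and a spine index;
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483647)
}

#' Generate a two-group synthetic spine population
#'
#' Emulates a case-control micro-CT design: per-mouse deformity amplitudes
#' are drawn from Normal(template amplitude, `between_sd`), truncated at 0,
#' and each mouse gets an independent landmark-noise stream derived
#' deterministically from the top-level seed.
#'
#' @param n_per_group Mice per group (>= 2).
#' @param control_template,case_template [spine_template()]s whose
#'   `deformity_amplitude` is the group mean amplitude.
#' @param between_sd Between-mouse amplitude SD; length 1 (shared) or 2
#'   (control, case).
#' @param seed Top-level integer seed.
#' @param labels Group labels, length 2 (control, case).
#' @return A list with `control` and `case`, each a list of
#'   [spine_point_cloud()]s carrying their ground truth.
#' @export
generate_population <- function(n_per_group, control_template, case_template,
                                between_sd = 0, seed = 1L,
                                labels = c("control", "case")) {
  if (n_per_group < 2L) stop_validation("n_per_group must be >= 2")
  between_sd <- rep_len(between_sd, 2L)
  amps <- with_preserved_seed(seed, list(
    control = pmax(0, stats::rnorm(n_per_group, control_template$deformity_amplitude,
                                   between_sd[1])),
    case = pmax(0, stats::rnorm(n_per_group, case_template$deformity_amplitude,
                                between_sd[2]))))
  gen <- function(tpl, amp_vec, label, offset) {
    lapply(seq_len(n_per_group), function(i) {
      t_i <- tpl
      t_i$deformity_amplitude <- amp_vec[i]
      if (t_i$shape == "arc") t_i$deformity_amplitude <- min(t_i$deformity_amplitude, 180)
      t_i$seed <- derive_seed(seed, offset + i)
      generate_spine(t_i, spine_id = sprintf("%s_%02d", label, i), group = label)
    })
  }
  list(control = gen(control_template, amps$control, labels[1], 0L),
       case = gen(case_template, amps$case, labels[2], n_per_group))
}
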