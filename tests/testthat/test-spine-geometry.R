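test_that("vertebra collapse returns landmark means", {
  # cube corners centred at (1, 2, 3)
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) +
    matrix(c(1, 2, 3), 8, 3, byrow = TRUE)
  verts <- lapply(1:4, function(i) list(index = i, landmarks = corners + i))
  cl <- spine_point_cloud("cube", "g", verts)
  cent <- collapse_vertebrae(cl)
  expect_equal(cent, t(sapply(1:4, function(i) c(1, 2, 3) + i)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # single-landmark vertebrae: polyline equals the landmarks
  pts <- cbind(0, 0, 1:5)
  cl1 <- spine_point_cloud("one", "g",
                           lapply(1:5, function(i)
                             list(index = i, landmarks = pts[i, , drop = FALSE])))
  expect_equal(collapse_vertebrae(cl1), pts, tolerance = 0, ignore_attr = TRUE)

  # noise-free ring landmarks average back onto the analytic centerline
  cl2 <- generate_spine(spine_template("arc", deformity_amplitude = 40))
  truth <- attr(cl2, "truth")
  expect_equal(collapse_vertebrae(cl2), truth$position, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("natural spline fit matches the stats::splinefun natural oracle", {
  pts <- circle_arc_points(12)
  curve <- fit_spine_curve(pts)
  tt <- seq(0, 1, length.out = 101)
  ev <- evaluate_curve(curve, tt)
  for (j in 1:3) {
    f <- stats::splinefun(curve$knots, pts[, j], method = "natural")
    expect_equal(ev$position[, j], f(tt), tolerance = 1e-9)
    expect_equal(ev$d1[, j], f(tt, deriv = 1), tolerance = 1e-7)
    expect_equal(ev$d2[, j], f(tt, deriv = 2), tolerance = 1e-6)
  }
})

test_that("fitted splines are C2 with vanishing end second derivatives", {
  set.seed(11)
  amps <- c(arc = 15, sinusoid = 5, s_curve = 15)  # sinusoid amplitude is in mm
  for (shape in c("arc", "sinusoid", "s_curve")) {
    cl <- generate_spine(spine_template(shape, deformity_amplitude = amps[[shape]],
                                        noise_sd = 0.2,
                                        seed = sample.int(1e6, 1)))
    curve <- fit_spine_curve(collapse_vertebrae(cl))
    k <- curve$knots
    n_int <- length(k) - 1L
    for (j in 1:3) {
      cf <- curve$coef[[j]]
      h <- diff(k)
      for (i in seq_len(n_int - 1L)) {
        u <- h[i]
        # value, first and second derivative continuity across knot i+1
        expect_equal(cf[i, "a"] + cf[i, "b"] * u + cf[i, "c"] * u^2 + cf[i, "d"] * u^3,
                     cf[i + 1L, "a"], tolerance = 1e-9)
        expect_equal(cf[i, "b"] + 2 * cf[i, "c"] * u + 3 * cf[i, "d"] * u^2,
                     cf[i + 1L, "b"], tolerance = 1e-8)
        expect_equal(2 * cf[i, "c"] + 6 * cf[i, "d"] * u,
                     2 * cf[i + 1L, "c"], tolerance = 1e-7)
      }
      # natural boundary: gamma'' = 0 at both ends
      expect_lt(abs(2 * cf[1, "c"]), 1e-8)
      expect_lt(abs(2 * cf[n_int, "c"] + 6 * cf[n_int, "d"] * h[n_int]), 1e-8)
    }
    prof <- curvature_profile(curve)
    expect_lt(prof$kappa[1], 1e-8)
    expect_lt(prof$kappa[length(prof$kappa)], 1e-8)
  }
})

test_that("analytic differentiation of stored cubics is exact", {
  # gamma(t) = (t, t^3, 0) on a single interval
  cv <- manual_curve(c(0, 1),
                     rbind(c(a = 0, b = 1, c = 0, d = 0)),
                     rbind(c(a = 0, b = 0, c = 0, d = 1)),
                     rbind(c(a = 0, b = 0, c = 0, d = 0)))
  tt <- c(0, 0.25, 0.5, 1)
  ev <- evaluate_curve(cv, tt)
  expect_equal(ev$position[, 2], tt^3, tolerance = 0)
  expect_equal(ev$d1[, 2], 3 * tt^2, tolerance = 0)
  expect_equal(ev$d2[, 2], 6 * tt, tolerance = 0)
  expect_error(evaluate_curve(cv, 1.5), class = "spinemorph_usage_error")
})

test_that("straight spines have zero curvature and constant tangent direction", {
  pts <- cbind(0, 0, seq(0, 80, length.out = 10))
  curve <- fit_spine_curve(pts)
  prof <- curvature_profile(curve, grid_size = 512)
  expect_lt(max(prof$kappa), 1e-10)
  expect_true(all(is.infinite(prof$radius)))
  d1 <- evaluate_curve(curve, seq(0, 1, length.out = 33))$d1
  dir <- d1 / sqrt(rowSums(d1^2))
  expect_lt(max(abs(sweep(dir, 2, dir[1, ]))), 1e-9)
  s <- prof$summaries
  expect_equal(c(s$max_kappa, s$mean_kappa, s$total_curvature), c(0, 0, 0))
})

test_that("circle-arc curvature recovers 1/R away from the flattened ends", {
  # flat-end boundary error decays by a factor 2 - sqrt(3) per knot, so the
  # constraint's boundary layer is taken as 3 knot spacings at each end
  cl <- generate_spine(spine_template("arc", deformity_amplitude = 60,
                                      spine_length = 20 * pi / 3))
  curve <- fit_spine_curve(collapse_vertebrae(cl))
  prof <- curvature_profile(curve)
  layer <- 3 / 23
  sel <- prof$t_grid >= layer & prof$t_grid <= 1 - layer
  expect_lt(max(abs(prof$kappa[sel] / 0.05 - 1)), 0.02)
  # integral of kappa ds over the whole arc approximates the subtended angle
  expect_equal(prof$summaries$total_curvature, pi / 3, tolerance = 0.03)
  # curvature converges with sample density: midpoint error < 0.5% at 25
  cl25 <- generate_spine(spine_template("arc", deformity_amplitude = 60,
                                        spine_length = 20 * pi / 3,
                                        n_vertebrae = 25))
  p25 <- curvature_profile(fit_spine_curve(collapse_vertebrae(cl25)))
  mid <- abs(p25$t_grid - 0.5) < 0.1
  expect_lt(max(abs(p25$kappa[mid] / 0.05 - 1)), 0.005)
  cl48 <- generate_spine(spine_template("arc", deformity_amplitude = 60,
                                        spine_length = 20 * pi / 3,
                                        n_vertebrae = 48))
  p48 <- curvature_profile(fit_spine_curve(collapse_vertebrae(cl48)))
  sel48 <- p48$t_grid >= 3 / 47 & p48$t_grid <= 1 - 3 / 47
  expect_lt(max(abs(p48$kappa[sel48] / 0.05 - 1)),
            max(abs(prof$kappa[sel] / 0.05 - 1)))
})

test_that("curvature is a similarity invariant of the right weight", {
  cl <- generate_spine(spine_template("sinusoid", deformity_amplitude = 6,
                                      noise_sd = 0.1, seed = 3))
  cent <- collapse_vertebrae(cl)
  prof <- curvature_profile(fit_spine_curve(cent))
  # uniform scaling by 2: kappa halves pointwise, total curvature unchanged
  prof2 <- curvature_profile(fit_spine_curve(cent * 2))
  expect_equal(prof2$kappa, prof$kappa / 2, tolerance = 1e-9)
  expect_equal(prof2$summaries$total_curvature, prof$summaries$total_curvature,
               tolerance = 1e-9)
  # rigid motions leave kappa untouched
  set.seed(21)
  for (rep in 1:3) {
    Q <- random_rotation()
    moved <- cent %*% t(Q) + matrix(stats::rnorm(3, sd = 10), nrow(cent), 3,
                                    byrow = TRUE)
    profR <- curvature_profile(fit_spine_curve(moved))
    expect_equal(profR$kappa, prof$kappa, tolerance = 1e-9)
  }
})

test_that("radius, arc length and summaries satisfy their identities", {
  cl <- generate_spine(spine_template("s_curve", deformity_amplitude = 25))
  prof <- curvature_profile(fit_spine_curve(collapse_vertebrae(cl)))
  nz <- prof$kappa > 0
  expect_true(any(nz))
  expect_equal(prof$kappa[nz] * prof$radius[nz], rep(1, sum(nz)), tolerance = 1e-12)
  expect_true(all(diff(prof$arc_length) >= 0))
  expect_equal(curvature_summary(prof, "mean"),
               prof$summaries$total_curvature / prof$summaries$arc_length,
               tolerance = 1e-12)
  expect_equal(curvature_summary(prof, "max"), max(prof$kappa))
  expect_error(curvature_summary(prof, "torsion"))
  df <- curvature_profile_df(prof)
  expect_identical(nrow(df), 512L)
  expect_identical(names(df),
                   c("t", "x_mm", "y_mm", "z_mm", "kappa_per_mm", "radius_mm",
                     "arclen_mm"))
})

test_that("degenerate fit inputs are rejected", {
  expect_error(fit_spine_curve(cbind(0, 0, 1:3)),
               class = "spinemorph_validation_error")
  pts <- cbind(0, 0, c(0, 1, 1, 2, 3))
  expect_error(fit_spine_curve(pts), "duplicate",
               class = "spinemorph_validation_error")
})
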