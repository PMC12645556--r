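test_that("generator is seed-deterministic and validates templates", {
  tpl <- spine_template("arc", deformity_amplitude = 20, noise_sd = 0.3, seed = 123)
  a <- generate_spine(tpl); b <- generate_spine(tpl)
  for (i in seq_along(a$vertebrae))
    expect_identical(a$vertebrae[[i]]$landmarks, b$vertebrae[[i]]$landmarks)
  c2 <- generate_spine(spine_template("arc", deformity_amplitude = 20,
                                      noise_sd = 0.3, seed = 124))
  expect_false(identical(a$vertebrae[[1]]$landmarks, c2$vertebrae[[1]]$landmarks))

  expect_error(spine_template("arc", deformity_amplitude = 200),
               class = "spinemorph_validation_error")
  expect_error(spine_template("arc", deformity_amplitude = -1),
               class = "spinemorph_validation_error")
  expect_error(spine_template("straight", n_vertebrae = 3),
               class = "spinemorph_validation_error")
  expect_error(spine_template("straight", noise_sd = -0.1),
               class = "spinemorph_validation_error")
  expect_error(generate_population(1, spine_template("straight"),
                                   spine_template("straight")),
               class = "spinemorph_validation_error")
})

test_that("noise-free straight spines are recognized as straight end to end", {
  cl <- generate_spine(spine_template("straight"))
  cent <- collapse_vertebrae(cl)
  # collinear centroids
  dirs <- sweep(cent[-1, ], 2, cent[1, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-9)
  prof <- curvature_profile(fit_spine_curve(cent))
  expect_lt(prof$summaries$max_kappa, 1e-9)
})

test_that("stations sit at equal arc-length spacing with true-radius rings", {
  tpl <- spine_template("arc", deformity_amplitude = 45, ring_radius = 0.5)
  cl <- generate_spine(tpl)
  truth <- attr(cl, "truth")
  gaps <- sqrt(rowSums(diff(truth$position)^2))
  # equal chords on a circle imply equal arc spacing
  expect_lt(diff(range(gaps)), 1e-9)
  # landmarks lie on a ring of the requested radius around the station
  for (i in c(1, 12, 24)) {
    d <- sqrt(rowSums((cl$vertebrae[[i]]$landmarks -
                       matrix(truth$position[i, ], 8, 3, byrow = TRUE))^2))
    expect_equal(d, rep(0.5, 8), tolerance = 1e-9)
    # ring plane is normal to the tangent
    rel <- sweep(cl$vertebrae[[i]]$landmarks, 2, truth$position[i, ])
    expect_lt(max(abs(rel %*% truth$tangent[i, ])), 1e-9)
  }
})

test_that("noise-free deformity recovery matches the analytic ground truth", {
  # arc curvature: interior fitted kappa within 2% of 1/R
  tpl <- spine_template("arc", deformity_amplitude = 50)
  cl <- generate_spine(tpl)
  truth <- attr(cl, "truth")
  prof <- curvature_profile(fit_spine_curve(collapse_vertebrae(cl)))
  layer <- 3 / 23
  sel <- prof$t_grid >= layer & prof$t_grid <= 1 - layer
  expect_lt(max(abs(prof$kappa[sel] / truth$kappa[1] - 1)), 0.02)
  # s-curve Cobb equals twice the per-bend deflection
  cls <- generate_spine(spine_template("s_curve", deformity_amplitude = 12))
  expect_equal(spine_cobb(cls)$angle_deg, attr(cls, "truth")$cobb_deg,
               tolerance = 0.5)
  expect_equal(attr(cls, "truth")$cobb_deg, 24)
})

test_that("smoothing keeps cobb bias small under landmark noise", {
  # interpolation inflates Cobb (extreme-value effect over noisy tangents);
  # GCV smoothing brings the bias down to the 2-degree scale
  raw <- smoothed <- numeric(20)
  for (r in 1:20) {
    tpl <- spine_template("arc", deformity_amplitude = 15, noise_sd = 0.2,
                          seed = 1000 + r)
    cl <- generate_spine(tpl)
    raw[r] <- spine_cobb(cl, grid_size = 256)$angle_deg - 15
    smoothed[r] <- spine_cobb(cl, grid_size = 256, smoothing = "gcv")$angle_deg - 15
  }
  expect_gt(mean(raw), 0)                 # inflation, not attenuation
  expect_lt(abs(mean(smoothed)), 2)
  expect_lt(abs(mean(smoothed)), abs(mean(raw)))
})

test_that("population amplitudes are recovered and sub-seeds are stable", {
  ctrl <- spine_template("arc", deformity_amplitude = 2, noise_sd = 0.1)
  case <- spine_template("arc", deformity_amplitude = 19, noise_sd = 0.1)
  means <- t(vapply(1:40, function(r) {
    pop <- generate_population(5, ctrl, case, between_sd = 5, seed = 5000 + r)
    c(mean(vapply(pop$control, function(cl)
        spine_cobb(cl, grid_size = 128, smoothing = "gcv")$angle_deg, numeric(1))),
      mean(vapply(pop$case, function(cl)
        spine_cobb(cl, grid_size = 128, smoothing = "gcv")$angle_deg, numeric(1))))
  }, numeric(2)))
  # truncation at 0 lifts the control mean; stay within the spec'd 2 degrees
  expect_lt(abs(mean(means[, 1]) - 2), 2)
  expect_lt(abs(mean(means[, 2]) - 19), 2)

  p1 <- generate_population(3, ctrl, case, between_sd = 1, seed = 77)
  p2 <- generate_population(3, ctrl, case, between_sd = 1, seed = 77)
  expect_identical(p1$case[[2]]$vertebrae[[5]]$landmarks,
                   p2$case[[2]]$vertebrae[[5]]$landmarks)
  expect_identical(vapply(p1$control, `[[`, character(1), "group"),
                   rep("control", 3))
})

test_that("null populations give uniform permutation p-values", {
  tpl <- spine_template("arc", deformity_amplitude = 10, noise_sd = 0.1,
                        n_vertebrae = 8, spine_length = 40)
  ps <- vapply(1:500, function(r) {
    pop <- generate_population(5, tpl, tpl, between_sd = 3, seed = 20000 + r)
    summ <- function(cl)
      curvature_profile(fit_spine_curve(collapse_vertebrae(cl)),
                        grid_size = 64)$summaries$mean_kappa
    permutation_test(vapply(pop$control, summ, numeric(1)),
                     vapply(pop$case, summ, numeric(1)))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
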