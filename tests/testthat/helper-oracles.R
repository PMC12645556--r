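# Independent oracles kept deliberately separate from the package's own code
# paths: closed forms, root-finding on the analytic model, and brute-force
# re-evaluation of rules.

# analytic kinetics of the continuous double-exponential transient
# f(t) = A (exp(-t/td) - exp(-t/tr)) / s_norm  (times in ms)
analytic_transient_kinetics <- function(tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms; td <- tau_decay_ms
  t_star <- log(td / tr) * tr * td / (td - tr)
  s_norm <- exp(-t_star / td) - exp(-t_star / tr)
  shape <- function(t) (exp(-t / td) - exp(-t / tr)) / s_norm
  http <- stats::uniroot(function(t) shape(t) - 0.5, c(1e-9, t_star),
                         tol = 1e-12)$root
  t_half_fall <- stats::uniroot(function(t) shape(t) - 0.5, c(t_star, 50 * td),
                                tol = 1e-12)$root
  list(ttp_ms = t_star, http_ms = http, hrt_ms = t_half_fall - t_star)
}

# brute-force re-evaluation of the differential retention rule, one record at
# a time with explicit branches
brute_force_calls <- function(df, min_peptides = 2, lo = -0.321, hi = 0.263,
                              q_max = 0.05) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$n_peptides < min_peptides) return("excluded:low_peptides")
    if (r$q_value > q_max) return("excluded:q_fail")
    if (r$log2_fold_change >= hi) return("up")
    if (r$log2_fold_change <= lo) return("down")
    "excluded:fc_band"
  }, character(1))
}

# exact points on a circular arc of radius R subtending `deg` degrees,
# bending in the x-z plane
circle_arc_points <- function(n, R = 20, deg = 60) {
  th <- (deg * pi / 180) * (seq(0, 1, length.out = n) - 0.5)
  cbind(R * (cos(th[1]) - cos(th)), 0, R * (sin(th) - sin(th[1])))
}

# a spine_curve built directly from known polynomial coefficients on the
# given knots (bypasses the fitting code entirely)
manual_curve <- function(knots, coef_x, coef_y, coef_z) {
  structure(list(knots = knots, coef = list(coef_x, coef_y, coef_z),
                 parametrization = "chord", boundary = "natural"),
            class = "spine_curve")
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(M)) * sample(c(-1, 1), 1)
}
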