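#' Kinetics of a stimulus-evoked calcium transient
#'
#' Computes the standard kinetic descriptors of a single evoked transient:
#' \describe{
#'   \item{`f_rest`}{mean of all pre-stimulus samples.}
#'   \item{`f_max`}{maximum post-stimulus sample.}
#'   \item{`delta_f_over_f0`}{`(f_max - f_rest) / f_rest`.}
#'   \item{`ttp_ms`}{time to peak: stimulus to the `f_max` sample.}
#'   \item{`http_ms`}{half time to peak: stimulus to the first rising-phase
#'     crossing of `f_rest + 0.5 (f_max - f_rest)`, linearly interpolated
#'     between samples.}
#'   \item{`hrt_ms`}{half relaxation time: peak to the first falling-phase
#'     crossing of the same half-amplitude level, linearly interpolated. If
#'     the trace never decays to half amplitude, `hrt_ms` is `NA` and
#'     `hrt_defined` is `FALSE`.}
#' }
#' No smoothing is applied before peak detection unless `median3 = TRUE`,
#' which runs a 3-point running median first (off by default).
#'
#' @param trace A [fluorescence_trace()].
#' @param median3 Apply a 3-point median filter before analysis.
#' @return A list of class `transient_kinetics`.
#' @export
compute_kinetics <- function(trace, median3 = FALSE) {
  if (!inherits(trace, "fluorescence_trace")) stop_usage("not a fluorescence_trace")
  v <- trace$values
  if (median3) v <- stats::runmed(v, 3)
  t <- trace$time
  pre <- t < trace$stimulus_time
  if (sum(pre) < 2L) stop_validation("need >= 2 pre-stimulus samples")
  if (sum(!pre) < 1L) stop_validation("no post-stimulus samples")
  f_rest <- mean(v[pre])
  if (f_rest <= 0) stop_validation("resting fluorescence must be > 0 (got %.4g)", f_rest)
  post_ix <- which(!pre)
  i_peak <- post_ix[which.max(v[post_ix])]
  f_max <- v[i_peak]
  half <- f_rest + 0.5 * (f_max - f_rest)

  # rising phase: first upward crossing of `half` at or after the stimulus
  http_ms <- NA_real_
  if (f_max > f_rest) {
    for (j in post_ix[1]:i_peak) {
      if (v[j] >= half) {
        if (j == 1L || v[j - 1L] >= half) {
          t_cross <- t[j]
        } else {
          t_cross <- t[j - 1L] + (half - v[j - 1L]) / (v[j] - v[j - 1L]) *
            (t[j] - t[j - 1L])
          t_cross <- max(t_cross, trace$stimulus_time)
        }
        http_ms <- (t_cross - trace$stimulus_time) * 1000
        break
      }
    }
  }

  # falling phase: first downward crossing of `half` after the peak
  hrt_ms <- NA_real_
  n <- length(v)
  if (f_max > f_rest && i_peak < n) {
    for (j in (i_peak + 1L):n) {
      if (v[j] <= half) {
        t_cross <- t[j - 1L] + (v[j - 1L] - half) / (v[j - 1L] - v[j]) *
          (t[j] - t[j - 1L])
        hrt_ms <- (t_cross - t[i_peak]) * 1000
        break
      }
    }
  }

  structure(list(f_rest = f_rest, f_max = f_max,
                 delta_f_over_f0 = (f_max - f_rest) / f_rest,
                 ttp_ms = (t[i_peak] - trace$stimulus_time) * 1000,
                 http_ms = http_ms, hrt_ms = hrt_ms,
                 hrt_defined = !is.na(hrt_ms)),
            class = "transient_kinetics")
}

#' @export
print.transient_kinetics <- function(x, ...) {
  cat(sprintf(paste0("transient_kinetics: dF/F0 = %.3f (rest %.1f, peak %.1f), ",
                     "TTP %.2f ms, HTTP %.2f ms, HRT %s ms\n"),
              x$delta_f_over_f0, x$f_rest, x$f_max, x$ttp_ms, x$http_ms,
              if (x$hrt_defined) sprintf("%.2f", x$hrt_ms) else "undefined"))
  invisible(x)
}

#' Generate a synthetic double-exponential calcium transient
#'
#' Resting fluorescence `f_rest` up to the stimulus, then
#' `f_rest + A (exp(-dt/tau_decay) - exp(-dt/tau_rise)) / s_norm`, where
#' `s_norm` scales the double-exponential so its analytic peak equals `A` —
#' i.e. the noise-free peak fluorescence is exactly `f_rest + amplitude`.
#' Gaussian noise of SD `noise_sd` is added with the given seed (values are
#' clamped at 0, as fluorescence is non-negative).
#'
#' @param f_rest Resting fluorescence (a.u., > 0).
#' @param amplitude Peak amplitude above rest (a.u.).
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants in ms
#'   (`tau_decay_ms > tau_rise_ms > 0`).
#' @param sampling_rate Hz (default 300).
#' @param duration_s Trace length in seconds (default 1).
#' @param stimulus_time Stimulus onset in seconds (default 0.1).
#' @param noise_sd Gaussian noise SD (a.u., default 0).
#' @param seed Integer seed for the noise.
#' @return A [fluorescence_trace()].
#' @export
generate_transient <- function(f_rest = 1000, amplitude = 1310,
                               tau_rise_ms = 3, tau_decay_ms = 25,
                               sampling_rate = 300, duration_s = 1,
                               stimulus_time = 0.1, noise_sd = 0, seed = 1L) {
  if (f_rest <= 0) stop_validation("f_rest must be > 0")
  if (!(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0))
    stop_validation("need tau_decay_ms > tau_rise_ms > 0")
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  t <- seq(0, duration_s, by = 1 / sampling_rate)
  dt <- t - stimulus_time
  t_star <- log(td / tr) * tr * td / (td - tr)
  s_norm <- exp(-t_star / td) - exp(-t_star / tr)
  v <- rep(f_rest, length(t))
  on <- dt >= 0
  v[on] <- f_rest + amplitude * (exp(-dt[on] / td) - exp(-dt[on] / tr)) / s_norm
  if (noise_sd > 0)
    v <- with_preserved_seed(seed, v + stats::rnorm(length(v), sd = noise_sd))
  fluorescence_trace(pmax(v, 0), sampling_rate = sampling_rate,
                     stimulus_time = stimulus_time)
}
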