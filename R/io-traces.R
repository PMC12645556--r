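#' Construct a fluorescence trace
#'
#' A uniformly sampled fluorescence recording with a known stimulus time,
#' as acquired for stimulus-evoked calcium transients (300 frames per second
#' in the motivating experiments).
#'
#' @param values Numeric vector of fluorescence intensities (arbitrary units).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param stimulus_time Stimulus onset in seconds from the first sample.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, sampling_rate = 300, stimulus_time) {
  values <- as.numeric(values)
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_validation("sampling_rate must be > 0")
  if (any(!is.finite(values)) || any(values < 0))
    stop_validation("fluorescence values must be finite and non-negative")
  t <- (seq_along(values) - 1) / sampling_rate
  n_pre <- sum(t < stimulus_time)
  n_post <- sum(t >= stimulus_time)
  if (n_pre < 2L || n_post < 2L)
    stop_validation("need >= 2 samples on each side of stimulus_time (have %d pre, %d post)",
                    n_pre, n_post)
  structure(list(values = values, sampling_rate = sampling_rate,
                 stimulus_time = stimulus_time, time = t),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("fluorescence_trace: %d samples @ %g Hz (%.3f s), stimulus at %.4f s\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate, x$stimulus_time))
  invisible(x)
}

#' Read a fluorescence trace from CSV
#'
#' Expects columns `time_s` and `fluorescence`, uniformly sampled (time steps
#' within 1% of their median). The sampling rate is inferred from the median
#' time step.
#'
#' @param path Path to the CSV file.
#' @param stimulus_time Stimulus onset in seconds; by default taken from an
#'   optional `stimulus_time_s` column (constant per file).
#' @return A [fluorescence_trace()].
#' @export
read_trace <- function(path, stimulus_time = NULL) {
  if (!file.exists(path)) stop_format("trace file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("trace CSV %s: %s", path,
                                                 conditionMessage(e)))
  missing <- setdiff(c("time_s", "fluorescence"), names(df))
  if (length(missing))
    stop_format("trace CSV %s: missing column(s) %s",
                path, paste(missing, collapse = ", "))
  if (nrow(df) < 4L)
    stop_validation("trace CSV %s: needs >= 4 samples, got %d", path, nrow(df))
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop_validation("trace CSV %s: time_s must be strictly increasing", path)
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop_validation("trace CSV %s: sampling not uniform within 1%%", path)
  if (is.null(stimulus_time)) {
    if (!"stimulus_time_s" %in% names(df))
      stop_usage("trace CSV %s: no stimulus_time_s column; pass stimulus_time", path)
    stimulus_time <- df$stimulus_time_s[1]
  }
  # trace time base starts at the first sample
  fluorescence_trace(df$fluorescence, sampling_rate = 1 / med,
                     stimulus_time = stimulus_time - df$time_s[1])
}

#' Write a fluorescence trace to CSV
#'
#' @param trace A [fluorescence_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, fluorescence = trace$values,
                   stimulus_time_s = trace$stimulus_time)
  utils::write.csv(format_df_full_precision(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
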