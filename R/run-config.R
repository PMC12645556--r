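#' Run configuration
#'
#' Bundles the tunable settings of a full pipeline run so they travel with
#' every output: curvature grid size, spline smoothing, projection plane,
#' permutation settings, differential-protein thresholds, seed and output
#' directory. Serialized as YAML and embedded in the run manifest.
#'
#' @param grid_size Curvature/Cobb evaluation grid (integer >= 16).
#' @param smoothing Non-negative spline smoothing parameter (0 = interpolate).
#' @param plane Projection plane for Cobb angles: `"coronal"` or `"sagittal"`.
#' @param curvature_summary Per-spine summary used by the permutation test:
#'   `"mean"`, `"max"` or `"total"`.
#' @param n_permutations Monte-Carlo permutation count (>= 100).
#' @param seed Integer seed recorded in every output.
#' @param min_peptides,log2fc_lower,log2fc_upper,q_max Differential-protein
#'   retention thresholds (see [filter_differential()]).
#' @param output_dir Output directory for pipeline artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(grid_size = 512L, smoothing = 0, plane = "coronal",
                       curvature_summary = "mean", n_permutations = 10000L,
                       seed = 1L, min_peptides = 2L, log2fc_lower = -0.321,
                       log2fc_upper = 0.263, q_max = 0.05,
                       output_dir = "results") {
  cfg <- structure(
    list(grid_size = as.integer(grid_size), smoothing = smoothing,
         plane = plane, curvature_summary = curvature_summary,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         min_peptides = as.integer(min_peptides),
         log2fc_lower = log2fc_lower, log2fc_upper = log2fc_upper,
         q_max = q_max, output_dir = output_dir),
    class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$grid_size < 16L) stop_usage("grid_size must be >= 16")
  if (!is.finite(cfg$smoothing) || cfg$smoothing < 0)
    stop_usage("smoothing must be >= 0")
  if (!cfg$plane %in% c("coronal", "sagittal"))
    stop_usage("plane must be 'coronal' or 'sagittal'")
  if (!cfg$curvature_summary %in% c("mean", "max", "total"))
    stop_usage("curvature_summary must be one of mean, max, total")
  if (cfg$n_permutations < 100L) stop_usage("n_permutations must be >= 100")
  if (!(cfg$log2fc_lower < 0 && cfg$log2fc_upper > 0))
    stop_usage("log2 fold-change band must straddle 0")
  if (!(cfg$q_max > 0 && cfg$q_max <= 1)) stop_usage("q_max must be in (0, 1]")
  invisible(cfg)
}

#' Read/write a run configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return For `read_run_config`, a [run_config()]; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
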