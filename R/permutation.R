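#' Two-sample permutation test on per-spine summaries
#'
#' Compares two populations (e.g. per-spine mean curvatures of two genotype
#' groups) by re-assigning the pooled values to groups of the original sizes.
#' The observed statistic is `stat(A) - stat(B)`. When the number of distinct
#' label assignments `choose(nA + nB, nA)` is at most `exhaustive_limit` the
#' null distribution is enumerated exactly and the p-value is the exact
#' proportion of assignments as or more extreme than the observed one
#' (inclusive). Otherwise `n_permutations` random assignments are drawn with
#' the given seed and the add-one estimate
#' `p = (1 + #extreme) / (n_permutations + 1)` is reported, so p is never 0.
#'
#' @param group_a,group_b Numeric vectors of per-unit summaries (non-empty,
#'   finite).
#' @param statistic `"mean_difference"` (default) or `"median_difference"`.
#' @param alternative `"two_sided"` (default, uses |T*| >= |T_obs|),
#'   `"greater"` or `"less"`.
#' @param n_permutations Monte-Carlo draw count (>= 100; ignored in exhaustive
#'   mode).
#' @param seed Integer seed for Monte-Carlo sampling (ignored in exhaustive
#'   mode). The caller's RNG state is left untouched.
#' @param exhaustive_limit Enumerate exactly when the number of assignments is
#'   at most this (default 20000, which covers a 5-vs-5 design's 252
#'   assignments exactly).
#' @return A list of class `permutation_test_result` with `statistic_name`,
#'   `observed`, `n_permutations`, `mode`, `p_value`, `seed`, `alternative`.
#' @export
permutation_test <- function(group_a, group_b,
                             statistic = c("mean_difference", "median_difference"),
                             alternative = c("two_sided", "greater", "less"),
                             n_permutations = 10000L, seed = 1L,
                             exhaustive_limit = 20000L) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_validation("both groups must be non-empty")
  if (any(!is.finite(group_a)) || any(!is.finite(group_b)))
    stop_validation("group values must be finite")
  stat_fun <- switch(statistic, mean_difference = mean, median_difference = stats::median)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  observed <- stat_fun(group_a) - stat_fun(group_b)
  total <- choose(n, na)

  if (total <= exhaustive_limit) {
    sel <- utils::combn(n, na)
    tstar <- if (statistic == "mean_difference") {
      # T* = mean(A*) - mean(B*) expressed via the selected subset's sum
      s <- colSums(matrix(pooled[sel], nrow = na))
      s / na - (sum(pooled) - s) / nb
    } else {
      apply(sel, 2, function(ix) stat_fun(pooled[ix]) - stat_fun(pooled[-ix]))
    }
    p <- extreme_fraction(tstar, observed, alternative, add_one = FALSE)
    return(structure(list(statistic_name = statistic, observed = observed,
                          n_permutations = as.integer(total), mode = "exhaustive",
                          p_value = p, seed = NA_integer_,
                          alternative = alternative),
                     class = "permutation_test_result"))
  }

  if (n_permutations < 100L)
    stop_usage("n_permutations must be >= 100 in monte_carlo mode")
  tstar <- with_preserved_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ix <- sample.int(n, na)
      stat_fun(pooled[ix]) - stat_fun(pooled[-ix])
    }, numeric(1))
  })
  p <- extreme_fraction(tstar, observed, alternative, add_one = TRUE)
  structure(list(statistic_name = statistic, observed = observed,
                 n_permutations = as.integer(n_permutations),
                 mode = "monte_carlo", p_value = p, seed = as.integer(seed),
                 alternative = alternative),
            class = "permutation_test_result")
}

# "as or more extreme" is inclusive; comparisons get a tiny relative slack so
# permuted statistics equal to the observed one up to float round-off count.
extreme_fraction <- function(tstar, observed, alternative, add_one) {
  tol <- 1e-8 * (1 + abs(observed))
  k <- switch(alternative,
              two_sided = sum(abs(tstar) >= abs(observed) - tol),
              greater = sum(tstar >= observed - tol),
              less = sum(tstar <= observed + tol))
  if (add_one) (1 + k) / (length(tstar) + 1) else k / length(tstar)
}

# run code under a given seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("permutation test (%s, %s, %s): observed = %.4g, p = %.4g (%d assignments%s)\n",
              x$statistic_name, x$alternative, x$mode, x$observed, x$p_value,
              x$n_permutations,
              if (x$mode == "monte_carlo") sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}
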