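#' Differential-protein retention rule
#'
#' Applies the study-style retention rule to a quantification table: a protein
#' is kept iff it was quantified on at least `min_peptides` peptides, has
#' `q_value <= q_max`, and its log2 fold change lies outside the band
#' `(log2fc_lower, log2fc_upper)` — i.e. at least a 20% change on the linear
#' scale with the default, deliberately asymmetric, band
#' `[-0.321, 0.263] = [log2 0.8, log2 1.2]`. All comparisons are inclusive.
#' Retained proteins with `log2_fold_change >= log2fc_upper` are called up,
#' those `<= log2fc_lower` down. Excluded rows record the first failing
#' criterion in the order peptides, q, band.
#'
#' @param records A `protein_quant` data frame (see [read_protein_table()]) or
#'   any data frame with columns `protein_id`, `log2_fold_change`, `q_value`,
#'   `n_peptides`.
#' @param min_peptides Minimum peptide count (default 2).
#' @param log2fc_lower,log2fc_upper Exclusion band on the log2 scale; must
#'   straddle 0 (defaults -0.321 and 0.263).
#' @param q_max Significance cutoff (default 0.05).
#' @return A list of class `differential_call_set` with data frames `up`,
#'   `down` and `excluded` (the latter with an extra `reason` column, one of
#'   `low_peptides`, `q_fail`, `fc_band`), plus the `thresholds` used. The
#'   three parts are disjoint and their union is the input.
#' @export
filter_differential <- function(records, min_peptides = 2L,
                                log2fc_lower = -0.321, log2fc_upper = 0.263,
                                q_max = 0.05) {
  need <- c("protein_id", "log2_fold_change", "q_value", "n_peptides")
  if (!all(need %in% names(records)))
    stop_usage("records must have columns %s", paste(need, collapse = ", "))
  if (!(log2fc_lower < 0 && log2fc_upper > 0))
    stop_usage("log2 fold-change band must straddle 0")
  if (!(q_max > 0 && q_max <= 1)) stop_usage("q_max must be in (0, 1]")
  records <- as.data.frame(records)

  reason <- rep(NA_character_, nrow(records))
  fail_pep <- records$n_peptides < min_peptides
  fail_q <- records$q_value > q_max
  in_band <- records$log2_fold_change > log2fc_lower &
             records$log2_fold_change < log2fc_upper
  reason[in_band] <- "fc_band"
  reason[fail_q] <- "q_fail"        # q overrides band,
  reason[fail_pep] <- "low_peptides"  # peptides override both (first in order)
  kept <- is.na(reason)
  up <- kept & records$log2_fold_change >= log2fc_upper
  down <- kept & records$log2_fold_change <= log2fc_lower

  excluded <- records[!kept, , drop = FALSE]
  excluded$reason <- reason[!kept]
  structure(list(up = records[up, , drop = FALSE],
                 down = records[down, , drop = FALSE],
                 excluded = excluded,
                 thresholds = list(min_peptides = min_peptides,
                                   log2fc_lower = log2fc_lower,
                                   log2fc_upper = log2fc_upper,
                                   q_max = q_max)),
            class = "differential_call_set")
}

#' @export
print.differential_call_set <- function(x, ...) {
  cat(sprintf("differential_call_set: %d up, %d down, %d excluded\n",
              nrow(x$up), nrow(x$down), nrow(x$excluded)))
  invisible(x)
}

#' Flatten a differential call set to one row per protein
#'
#' @param callset A [filter_differential()] result.
#' @return The input records with a `call` column (`up`, `down`, or
#'   `excluded:<reason>`), in the original row order.
#' @export
differential_calls_df <- function(callset) {
  tag <- function(df, call) if (nrow(df)) cbind(df, call = call) else NULL
  ex <- callset$excluded
  if (nrow(ex)) {
    ex$call <- paste0("excluded:", ex$reason)
    ex$reason <- NULL
  } else ex <- NULL
  out <- rbind(tag(callset$up, "up"), tag(callset$down, "down"), ex)
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

#' Generate a synthetic protein quantification table
#'
#' Emulates a differential-proteomics result with planted truth: a fraction
#' of proteins is up- or down-regulated with log2 fold changes drawn beyond
#' the retention band and small q-values; null proteins get log2 fold changes
#' near 0 and q-values uniform on [0, 1]. A `truth` column records the
#' planted class.
#'
#' @param n_proteins Total rows.
#' @param frac_up,frac_down Planted regulated fractions.
#' @param effect_l2fc Mean |log2 fold change| of regulated proteins
#'   (default 0.6).
#' @param seed Integer seed.
#' @return A `protein_quant` data frame with an extra `truth` column
#'   (`up`/`down`/`null`).
#' @export
generate_protein_table <- function(n_proteins = 200L, frac_up = 0.1,
                                   frac_down = 0.1, effect_l2fc = 0.6,
                                   seed = 1L) {
  if (frac_up + frac_down > 1) stop_usage("frac_up + frac_down must be <= 1")
  n_up <- round(n_proteins * frac_up)
  n_dn <- round(n_proteins * frac_down)
  n_null <- n_proteins - n_up - n_dn
  with_preserved_seed(seed, {
    l2fc <- c(stats::rnorm(n_up, effect_l2fc, 0.15),
              stats::rnorm(n_dn, -effect_l2fc, 0.15),
              stats::rnorm(n_null, 0, 0.08))
    q <- c(stats::runif(n_up, 0, 0.05), stats::runif(n_dn, 0, 0.05),
           stats::runif(n_null, 0, 1))
    np <- stats::rpois(n_proteins, 5) + 1L
    out <- data.frame(
      protein_id = sprintf("P%04d", seq_len(n_proteins)),
      log2_fold_change = l2fc, q_value = q, n_peptides = np,
      truth = rep(c("up", "down", "null"), c(n_up, n_dn, n_null)),
      stringsAsFactors = FALSE)
    out <- out[sample.int(n_proteins), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("protein_quant", class(out))
    out
  })
}
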