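# Calibration / FDR / power evaluation for simulation benchmarks.

#' Calibration report for a set of null p-values
#'
#' Under the null, valid p-values are Uniform(0, 1). This is assessed two
#' ways: a one-sample Kolmogorov-Smirnov test of the raw p-values against
#' Uniform(0, 1), and quantile-quantile pairs on the -log10 scale for
#' plotting.
#'
#' @param pvalues vector of p-values in \[0, 1\]; at least 100 for a
#'   meaningful KS statistic.
#' @param n_qq number of QQ quantile points to return.
#' @return object of class `calibration_report`: list with `ks_statistic`,
#'   `ks_pvalue`, `n`, and `qq_points` (data.frame `expected`, `observed`,
#'   both -log10 quantiles, sorted by `expected`).
#' @export
evaluate_calibration <- function(pvalues, n_qq = 200L) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0) stop("no p-values supplied")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (length(pvalues) < 100)
    warning("fewer than 100 p-values; the KS test has little resolution")
  ks <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  probs <- (seq_len(n_qq) - 0.5) / n_qq
  qq <- data.frame(
    expected = -log10(rev(probs)),
    observed = -log10(stats::quantile(pvalues, rev(probs), names = FALSE,
                                      type = 8))
  )
  structure(list(ks_statistic = unname(ks$statistic),
                 ks_pvalue = ks$p.value, n = length(pvalues),
                 qq_points = qq),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration of", x$n, "null p-values: KS statistic =",
      format(x$ks_statistic, digits = 4), ", KS p-value =",
      format(x$ks_pvalue, digits = 4), "\n")
  invisible(x)
}

#' Empirical FDR and power against simulation ground truth
#'
#' Calls every gene with q-value at or below `fdr_level` and compares the
#' called set to the known DE labels of a synthetic dataset.
#'
#' @param table a `de_result_table` from [test_all_genes()].
#' @param truth logical vector of ground-truth DE labels, aligned with the
#'   table's genes (or named by gene_id).
#' @param fdr_level q-value threshold.
#' @return object of class `power_fdr_report`: list with `fdr_level`,
#'   `n_called`, `true_positives`, `false_positives`, `empirical_fdr`
#'   (FP / max(1, called)) and `empirical_power` (TP / #DE).
#' @export
evaluate_power_fdr <- function(table, truth, fdr_level = 0.05) {
  if (!is.null(names(truth))) {
    if (!setequal(names(truth), table$gene_id))
      stop("truth labels and result table cover different gene sets")
    truth <- truth[table$gene_id]
  }
  if (length(truth) != nrow(table))
    stop("truth has ", length(truth), " labels for ", nrow(table), " genes")
  called <- !is.na(table$qvalue) & table$qvalue <= fdr_level
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  structure(list(fdr_level = fdr_level, n_called = sum(called),
                 true_positives = tp, false_positives = fp,
                 empirical_fdr = fp / max(1, sum(called)),
                 empirical_power = if (sum(truth) > 0) tp / sum(truth) else NA_real_),
            class = "power_fdr_report")
}

#' @export
print.power_fdr_report <- function(x, ...) {
  cat(sprintf(
    "DE calls at q <= %.3g: %d (TP %d, FP %d); empirical FDR %.3f, power %.3f\n",
    x$fdr_level, x$n_called, x$true_positives, x$false_positives,
    x$empirical_fdr, x$empirical_power))
  invisible(x)
}
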