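#' Evaluation of detection performance on replicated simulations
#'
#' Bookkeeping and metrics for simulation studies where each replicate
#' dataset carries one planted disease combination: per-replicate outcome
#' classification, power / recall / precision / F-measure, and a plug-in
#' per-combination AUC.
#'
#' @name evaluate
NULL

#' Classify per-replicate detection outcomes
#'
#' For each replicate: the planted combination counts as a true positive if
#' it appears among the tested candidates with `p < theta`, and as a false
#' negative if the search stage found it but it failed the test. Non-planted
#' candidates that pass are false positives; non-planted candidates that
#' fail are true negatives. A planted combination the search never found
#' contributes to neither TP nor FN (it is a missed detection, visible in
#' power, which is measured per dataset).
#'
#' @param results list, one element per replicate: a data.frame with
#'   columns `snps` (comma-joined sorted SNP ids or indices) and `p_value`
#'   covering all tested candidates (see [results_table] on the
#'   `all_candidates` attribute of [filter_candidates]).
#' @param truth list (or single vector), one planted combination per
#'   replicate, as the SNP ids/indices used in `results$snps`.
#' @param theta p-value threshold, recycled over replicates, or a vector.
#' @return list of counts `tp`, `fp`, `fn`, `tn` plus `n_datasets` and
#'   `detected` (logical per replicate: planted combination passed).
#' @export
classify_outcomes <- function(results, truth, theta) {
  if (!is.list(truth)) truth <- list(truth)
  n_rep <- length(results)
  if (length(truth) == 1L) truth <- rep(truth, n_rep)
  if (length(truth) != n_rep) stop("truth must have one entry per replicate")
  theta <- rep_len(theta, n_rep)
  tp <- fp <- fn <- tn <- 0L
  detected <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    res <- results[[r]]
    truth_key <- paste(sort(as.character(truth[[r]])), collapse = ",")
    keys <- vapply(strsplit(as.character(res$snps), ","),
                   function(s) paste(sort(s), collapse = ","), character(1))
    planted <- keys == truth_key
    pass <- res$p_value < theta[r]
    tp_r <- any(planted & pass)
    tp <- tp + as.integer(tp_r)
    fn <- fn + as.integer(any(planted) && !tp_r)
    fp <- fp + sum(!planted & pass)
    tn <- tn + sum(!planted & !pass)
    detected[r] <- tp_r
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, n_datasets = n_rep, detected = detected)
}

round_half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

#' F-measure from recall and precision
#'
#' Harmonic mean `2 / (1/recall + 1/precision)`, on whatever scale its
#' inputs share (percent in this package's reports); 0 when recall and
#' precision are both 0.
#'
#' @param recall,precision the two rates.
#' @return the F-measure on the same scale.
#' @export
f_measure <- function(recall, precision) {
  if (recall + precision == 0) return(0)
  2 / (1 / recall + 1 / precision)
}

#' Power, recall, precision and F-measure (percent)
#'
#' Power is the fraction of replicate datasets in which the planted model
#' was detected (passed the threshold). Recall = TP/(TP+FN) and precision =
#' TP/(TP+FP) measure the verification stage; F-measure is their harmonic
#' mean, `2 / (1/recall + 1/precision)`, defined as 0 when recall and
#' precision are both 0. All reported as percentages.
#'
#' @param counts outcome counts from [classify_outcomes] (fields `tp`,
#'   `fp`, `fn`, `tn`).
#' @param n_datasets number of replicate datasets (defaults to
#'   `counts$n_datasets`).
#' @return An `evaluation_report`: list with the counts, `n_datasets`,
#'   `power`, `recall`, `precision`, `f_measure` (percent), and
#'   `degenerate` flagging all-zero denominators.
#' @export
evaluation_metrics <- function(counts, n_datasets = counts$n_datasets) {
  if (is.null(n_datasets) || n_datasets < 1L) stop("n_datasets must be >= 1")
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  degenerate <- character(0)
  frac <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 } else 100 * num / den
  }
  power <- frac(tp, n_datasets, "power")
  recall <- frac(tp, tp + fn, "recall")
  precision <- frac(tp, tp + fp, "precision")
  if (recall + precision == 0) degenerate <- c(degenerate, "f_measure")
  fm <- f_measure(recall, precision)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n_datasets = n_datasets,
                 power = power, recall = recall, precision = precision,
                 f_measure = fm, degenerate = degenerate),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation over", x$n_datasets, "replicate dataset(s)\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  power     %6.2f%%\n", round_half_up(x$power)))
  cat(sprintf("  recall    %6.2f%%\n", round_half_up(x$recall)))
  cat(sprintf("  precision %6.2f%%\n", round_half_up(x$precision)))
  cat(sprintf("  F-measure %6.2f%%\n", round_half_up(x$f_measure)))
  if (length(x$degenerate)) {
    cat("  (zero denominator, reported as 0:", paste(x$degenerate, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Plug-in AUC of a SNP combination
#'
#' Scores each sample by the case fraction of its joint genotype cell
#' (resubstitution plug-in risk) and computes the rank-based (Mann-Whitney)
#' AUC with mid-rank tie handling. An optimistic, exploratory measure: no
#' cross-validation is applied.
#'
#' @param dataset an [snp_dataset] with both classes present.
#' @param combo SNP indices of the combination (length >= 1).
#' @return AUC in `[0, 1]`.
#' @export
auc_combination <- function(dataset, combo) {
  combo <- check_snp_indices(dataset, combo)
  y <- dataset$phenotype
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute an AUC")
  idx <- encode_genotype_tuples(dataset$genotypes[, combo, drop = FALSE])
  ncell <- 3L^length(combo)
  case_frac <- tabulate(idx[y == 1L], nbins = ncell) / pmax(1L, tabulate(idx, nbins = ncell))
  score <- case_frac[idx]
  r <- rank(score)                       # mid-ranks on ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
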