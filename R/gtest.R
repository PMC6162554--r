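#' Improved G-test of genotype-phenotype association
#'
#' Likelihood-ratio (G) test of independence between a k-way genotype
#' combination and case-control status, with a small-cell gate: genotype
#' rows whose total count is at most `xi` are excluded from the statistic and
#' each excluded row reduces the degrees of freedom by one. The gate guards
#' the chi-square approximation against sparse genotype combinations.
#'
#' @name gtest
NULL

#' Expected counts for a genotype-by-phenotype table
#'
#' Independence mode (default): classical margin products
#' `E_ij = row_i total * column_j total / n`. HWE mode: per-locus genotype
#' probabilities `(1-q)^2, 2q(1-q), q^2` from the pooled sample minor-allele
#' frequency `q` of each locus (or supplied `maf`), multiplied across loci
#' and scaled to each phenotype column total (columns renormalised so they
#' sum to the observed column totals).
#'
#' @param observed a `joint_table` with genotype rows and the two phenotype
#'   columns (see [joint_counts]).
#' @param mode `"independence"` (default) or `"hwe"`.
#' @param maf optional per-SNP minor-allele frequencies for HWE mode; when
#'   omitted they are estimated from the pooled genotype margins of the
#'   table.
#' @return numeric matrix of expected counts, same shape as
#'   `observed$counts`.
#' @export
expected_counts <- function(observed, mode = c("independence", "hwe"), maf = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(observed, "joint_table"))
  if (!observed$has_phenotype) stop("expected_counts needs a table with the phenotype axis")
  O <- observed$counts
  n <- sum(O)
  if (n == 0) stop("empty table")
  if (mode == "independence") {
    E <- outer(rowSums(O), colSums(O)) / n
  } else {
    k <- observed$k
    if (is.null(maf)) maf <- maf_from_joint_table(O, k)
    if (anyNA(maf) || any(maf < 0 | maf > 1)) {
      stop("HWE mode needs a computable allele frequency for every locus")
    }
    probs <- 1
    for (q in rev(maf)) {
      locus <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      probs <- as.vector(outer(probs, locus))  # earlier locus varies slowest
    }
    probs <- probs / sum(probs)
    E <- outer(probs, colSums(O))
  }
  dimnames(E) <- dimnames(O)
  E
}

# pooled per-locus minor-allele frequency from the genotype margins of a
# 3^k x 2 joint table (rows in lexicographic tuple order)
maf_from_joint_table <- function(counts, k) {
  rowtot <- rowSums(counts)
  n <- sum(rowtot)
  cell <- seq_len(3L^k) - 1L
  vapply(seq_len(k), function(j) {
    g <- (cell %/% 3L^(k - j)) %% 3L
    gc <- vapply(0:2, function(v) sum(rowtot[g == v]), numeric(1))
    (gc[2L] + 2 * gc[3L]) / (2 * n)
  }, numeric(1))
}

#' G statistic with small-cell gating and adjusted degrees of freedom
#'
#' `G = 2 sum O_ij ln(O_ij / E_ij)` over cells of genotype rows whose total
#' exceeds `xi`; cells with `O_ij = 0` contribute 0. Each gated row (total
#' `<= xi`) contributes nothing to G and decrements the degrees of freedom
#' `(I-1)(J-1)` by one, with a floor at 0.
#'
#' @param observed a `joint_table` (genotype rows x 2 phenotype columns) or
#'   a bare count matrix.
#' @param expected expected counts of the same shape (see
#'   [expected_counts]).
#' @param xi small-cell gate, an integer in `[0, 5]`.
#' @return list with `g`, `df`, `excluded_rows`, and `cell_terms` (the
#'   per-cell `O ln(O/E)` contributions, 0 in gated rows).
#' @export
g_statistic <- function(observed, expected, xi = 5L) {
  O <- if (inherits(observed, "joint_table")) observed$counts else as.matrix(observed)
  E <- as.matrix(expected)
  if (!identical(dim(O), dim(E))) stop("observed and expected shapes differ")
  if (xi < 0 || xi > 5) stop("xi must be an integer in [0, 5]")
  I <- nrow(O); J <- ncol(O)
  rowtot <- rowSums(O)
  included <- rowtot > xi
  if (any(E[included, ] == 0 & O[included, ] > 0)) {
    stop("expected count 0 with positive observed count in an included row: ",
         "the expectation model cannot explain the data")
  }
  terms <- matrix(0, I, J, dimnames = dimnames(O))
  pos <- O > 0 & included
  terms[pos] <- O[pos] * log(O[pos] / E[pos])
  g <- 2 * sum(terms)
  excluded <- sum(!included)
  df <- max(0L, (I - 1L) * (J - 1L) - excluded)
  list(g = g, df = df, excluded_rows = excluded, cell_terms = terms)
}

#' Run the improved G-test on a SNP combination
#'
#' Builds the 3^k-by-2 observed table for the combination, forms expected
#' counts, computes the gated G statistic, and returns the upper-tail
#' chi-square p-value at the adjusted degrees of freedom. With all rows
#' gated (`df = 0`) the p-value is 1: such a combination can never be
#' declared significant.
#'
#' @param dataset an [snp_dataset] with no missing genotypes in the tested
#'   columns.
#' @param combo integer vector of distinct SNP indices.
#' @param xi small-cell gate (default 5).
#' @param mode expectation model, `"independence"` (default) or `"hwe"`.
#' @return An object of class `gtest_result`: list with `g`, `df`,
#'   `p_value`, `excluded_rows`, `cell_terms`, `combo`, `snp_ids`.
#' @export
g_test <- function(dataset, combo, xi = 5L, mode = c("independence", "hwe")) {
  mode <- match.arg(mode)
  combo <- check_snp_indices(dataset, combo)
  obs <- joint_counts(dataset, combo, include_phenotype = TRUE)
  E <- expected_counts(obs, mode = mode)
  gs <- g_statistic(obs, E, xi = xi)
  p <- if (gs$df == 0L) 1 else stats::pchisq(gs$g, df = gs$df, lower.tail = FALSE)
  structure(
    list(g = gs$g, df = gs$df, p_value = p, excluded_rows = gs$excluded_rows,
         cell_terms = gs$cell_terms, combo = combo,
         snp_ids = dataset$snp_ids[combo]),
    class = "gtest_result"
  )
}

#' @export
print.gtest_result <- function(x, ...) {
  cat("G-test:", paste(x$snp_ids, collapse = " x "), "\n")
  cat(sprintf("  G = %.4f, df = %d (%d row(s) gated), p = %.4g\n",
              x$g, x$df, x$excluded_rows, x$p_value))
  invisible(x)
}
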