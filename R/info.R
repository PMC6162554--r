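#' Information-theoretic estimators for genotype/phenotype association
#'
#' Plug-in (maximum-likelihood frequency) estimators of entropy, joint
#' entropy, mutual information, joint mutual information, interaction gain,
#' the interaction weight factor, and symmetrical uncertainty, all in nats.
#' Zero cells contribute 0 to entropy sums (0 log 0 := 0); no pseudocounts
#' are added.
#'
#' @name core-info
NULL

MI_CLAMP_TOL <- 1e-12
DEFAULT_K_MAX <- 6L

#' Discrete probability distribution
#'
#' @param support category labels.
#' @param probs probability per category; non-negative, summing to 1 within
#'   `1e-12`.
#' @param n sample count the estimate came from (optional, `NA` if unknown).
#' @return An object of class `discrete_distribution`.
#' @export
discrete_distribution <- function(support, probs, n = NA_integer_) {
  if (length(support) != length(probs)) stop("support and probs lengths differ")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1 (got ", sum(probs), ")")
  structure(list(support = support, probs = as.numeric(probs), n = n),
            class = "discrete_distribution")
}

# lexicographic cell index over genotype tuples: first SNP most significant,
# so flat order runs (0,..,0), (0,..,1), ..., (2,..,2)
encode_genotype_tuples <- function(G) {
  k <- ncol(G)
  idx <- integer(nrow(G))
  for (j in seq_len(k)) idx <- idx * 3L + G[, j]
  idx + 1L
}

genotype_labels <- function(k) {
  grid <- expand.grid(rev(replicate(k, 0:2, simplify = FALSE)))[, k:1, drop = FALSE]
  apply(grid, 1L, paste, collapse = "/")
}

#' Joint genotype (and phenotype) counts
#'
#' Tabulates the samples of a dataset over the 3^k joint genotype cells of a
#' k-way SNP selection, optionally split by phenotype. Cells with no samples
#' are present with count 0. Genotype cells are ordered lexicographically
#' over genotype tuples, `(0,0,..)` first, `(2,2,..)` last; phenotype columns
#' are ordered control (0), case (1).
#'
#' @param dataset an [snp_dataset] with no missing genotypes among the
#'   selected columns (impute first).
#' @param snp_indices distinct SNP column indices.
#' @param include_phenotype if `TRUE` (default), cross-tabulate with the
#'   phenotype.
#' @return An object of class `joint_table`: list with `counts` (a 3^k x 2
#'   matrix if phenotype included, else a length-3^k vector), `axes`
#'   (variable ids), `k`, `n`, and `has_phenotype`.
#' @export
joint_counts <- function(dataset, snp_indices, include_phenotype = TRUE) {
  stopifnot(inherits(dataset, "snp_dataset"))
  snp_indices <- check_snp_indices(dataset, snp_indices)
  G <- dataset$genotypes[, snp_indices, drop = FALSE]
  if (anyNA(G)) {
    stop("missing genotypes among the selected SNP columns; run impute_knn() first")
  }
  k <- length(snp_indices)
  idx <- encode_genotype_tuples(G)
  ncell <- 3L^k
  labs <- genotype_labels(k)
  if (include_phenotype) {
    counts <- cbind(control = tabulate(idx[dataset$phenotype == 0L], nbins = ncell),
                    case    = tabulate(idx[dataset$phenotype == 1L], nbins = ncell))
    rownames(counts) <- labs
  } else {
    counts <- tabulate(idx, nbins = ncell)
    names(counts) <- labs
  }
  structure(
    list(counts = counts,
         axes = c(dataset$snp_ids[snp_indices],
                  if (include_phenotype) "phenotype"),
         k = k, n = n_samples(dataset),
         has_phenotype = include_phenotype),
    class = "joint_table"
  )
}

# -sum(p log p) from a non-negative count vector, plug-in frequencies
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("empty table: no samples to estimate from")
  c_pos <- counts[counts > 0]
  log(n) - sum(c_pos * log(c_pos)) / n
}

#' Shannon entropy (nats)
#'
#' `H = -sum p log p` with `0 log 0 := 0`. Accepts a
#' [discrete_distribution], a `joint_table` (marginal over all its cells), or
#' a bare numeric vector of probabilities.
#'
#' @param x the distribution.
#' @return entropy in nats, `>= 0`.
#' @export
entropy <- function(x) {
  if (inherits(x, "discrete_distribution")) {
    p <- x$probs[x$probs > 0]
    return(-sum(p * log(p)))
  }
  if (inherits(x, "joint_table")) return(entropy_from_counts(as.vector(x$counts)))
  if (is.numeric(x)) {
    if (any(x < 0)) stop("probabilities must be non-negative")
    if (abs(sum(x) - 1) > 1e-8) stop("probabilities must sum to 1")
    p <- x[x > 0]
    return(-sum(p * log(p)))
  }
  stop("cannot compute entropy of a ", class(x)[1L])
}

#' Joint entropy of a count table (nats)
#'
#' Entropy of the plug-in joint distribution over all cells of a
#' `joint_table` (genotype cells times phenotype states if present).
#'
#' @param table a `joint_table` with `n >= 1`.
#' @return joint entropy in nats.
#' @export
joint_entropy <- function(table) {
  stopifnot(inherits(table, "joint_table"))
  entropy_from_counts(as.vector(table$counts))
}

#' Mutual information between one SNP and the phenotype (nats)
#'
#' `I(X;C) = H(X) + H(C) - H(X,C)` computed from a genotype-by-phenotype
#' count table. Tiny negative values from floating-point cancellation
#' (above `-1e-12`) are clamped to 0.
#'
#' @param x_table a `joint_table` with exactly one SNP axis and the
#'   phenotype axis.
#' @return `I(X;C) >= 0`, in nats.
#' @export
mutual_information <- function(x_table) {
  stopifnot(inherits(x_table, "joint_table"))
  if (!x_table$has_phenotype || x_table$k != 1L) {
    stop("mutual_information needs a table with one SNP axis and the phenotype axis")
  }
  mi_from_matrix(x_table$counts)
}

mi_from_matrix <- function(counts) {
  hx <- entropy_from_counts(rowSums(counts))
  hc <- entropy_from_counts(colSums(counts))
  hxc <- entropy_from_counts(as.vector(counts))
  clamp_mi(hx + hc - hxc)
}

clamp_mi <- function(mi) {
  if (mi < 0) {
    if (mi < -MI_CLAMP_TOL) stop("mutual information is negative beyond float noise: ", mi)
    mi <- 0
  }
  mi
}

#' Joint mutual information between a k-way SNP combination and the phenotype
#'
#' `I([X1..Xk]; C) = H(X1..Xk) + H(C) - H(X1..Xk, C)`, in nats. For `k = 1`
#' this reduces to [mutual_information].
#'
#' @param snp_indices distinct SNP indices, `1 <= k <= k_max`.
#' @param dataset an [snp_dataset].
#' @param k_max largest allowed combination order (default 6): the count
#'   table has 3^k genotype cells and must fit in memory.
#' @return joint mutual information `>= 0`, in nats.
#' @export
joint_mutual_information <- function(snp_indices, dataset, k_max = DEFAULT_K_MAX) {
  k <- length(snp_indices)
  if (k > k_max) {
    stop("combination order k = ", k, " exceeds k_max = ", k_max,
         ": the joint table needs 3^k = ", 3^k, " genotype cells")
  }
  tab <- joint_counts(dataset, snp_indices, include_phenotype = TRUE)
  mi_from_matrix(tab$counts)
}

#' Interaction gain of a SNP pair for the phenotype (nats)
#'
#' `IG(X;Y;C) = I([X,Y];C) - I(X;C) - I(Y;C)`. Positive values indicate
#' synergy (the pair carries more phenotype information than the sum of its
#' members), negative values redundancy.
#'
#' @param x,y distinct SNP indices.
#' @param dataset an [snp_dataset].
#' @return interaction gain in nats (may be negative).
#' @export
interaction_gain <- function(x, y, dataset) {
  if (x == y) stop("interaction gain requires two distinct SNPs")
  joint_mutual_information(c(x, y), dataset) -
    mutual_information(joint_counts(dataset, x)) -
    mutual_information(joint_counts(dataset, y))
}

#' Interaction weight factor of a SNP pair
#'
#' `IWF(X,Y) = 1 + IG(X;Y;C) / (H(X) + H(Y))`, a unitless score in
#' `[0, 2]`: above 1 flags interaction, below 1 redundancy, 1 is neutral.
#' If both SNPs are constant (`H(X)+H(Y) = 0`) the factor is defined as the
#' neutral value 1 and a message is emitted.
#'
#' @param x,y distinct SNP indices.
#' @param dataset an [snp_dataset].
#' @return the interaction weight factor.
#' @export
interaction_weight_factor <- function(x, y, dataset) {
  hx <- entropy_from_counts(joint_counts(dataset, x, include_phenotype = FALSE)$counts)
  hy <- entropy_from_counts(joint_counts(dataset, y, include_phenotype = FALSE)$counts)
  if (hx + hy == 0) {
    message("both SNPs constant: interaction weight factor defined as neutral 1")
    return(1)
  }
  1 + interaction_gain(x, y, dataset) / (hx + hy)
}

#' Symmetrical uncertainty between a SNP and the phenotype
#'
#' Standard form: `SU = 2 I(X;C) / (H(X) + H(C))`, in `[0, 1]`. Modified
#' form (the default, used to rank search seeds): `SU* = 2 I(X;C) / H(X,C)`,
#' in `[0, 2]`; normalising by the joint entropy instead of the marginal sum
#' boosts susceptibility loci whose joint distribution with the phenotype is
#' concentrated, so weak marginal effects are easier to rank. The modified
#' value is always at least the standard one. A constant SNP has SU 0 by
#' convention.
#'
#' @param x SNP index.
#' @param dataset an [snp_dataset] with non-constant phenotype.
#' @param mode `"modified"` (default) or `"standard"`.
#' @return a unitless value.
#' @export
symmetrical_uncertainty <- function(x, dataset, mode = c("modified", "standard")) {
  mode <- match.arg(mode)
  tab <- joint_counts(dataset, x, include_phenotype = TRUE)
  su_from_matrix(tab$counts, mode)
}

su_from_matrix <- function(counts, mode) {
  hx <- entropy_from_counts(rowSums(counts))
  hc <- entropy_from_counts(colSums(counts))
  if (hc == 0) stop("phenotype is constant: symmetrical uncertainty undefined")
  if (hx == 0) return(0)
  hxc <- entropy_from_counts(as.vector(counts))
  mi <- clamp_mi(hx + hc - hxc)
  if (mode == "standard") 2 * mi / (hx + hc) else 2 * mi / hxc
}
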