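#' Case-control SNP genotype dataset
#'
#' Container for a samples-by-SNPs genotype matrix coded 0 (homozygous major
#' allele), 1 (heterozygous), 2 (homozygous minor allele), with `NA` marking a
#' missing genotype, plus a binary phenotype (1 = case, 0 = control).
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param phenotype integer vector of 0/1 disease status, one per sample.
#' @param snp_ids character vector of SNP identifiers (defaults to column
#'   names or `SNP1..SNPN`).
#' @param provenance list recording where the data came from (file path,
#'   simulation spec, resampling indices); free-form.
#'
#' @return An object of class `snp_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `snp_ids`, `provenance`.
#' @export
snp_dataset <- function(genotypes, phenotype, snp_ids = NULL, provenance = list()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (nrow(genotypes) != length(phenotype)) {
    stop("number of genotype rows (", nrow(genotypes),
         ") does not match phenotype length (", length(phenotype), ")")
  }
  bad <- which(!(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(genotypes))
    stop("invalid genotype value '", genotypes[bad[1L]], "' at sample ",
         rc[1L], ", SNP column ", rc[2L], "; genotypes must be 0, 1, 2 or missing")
  }
  if (any(!phenotype %in% c(0L, 1L))) {
    stop("phenotype must be binary: 0 (control) or 1 (case)")
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  if (length(snp_ids) != ncol(genotypes)) {
    stop("length of snp_ids does not match the number of SNP columns")
  }
  colnames(genotypes) <- snp_ids
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_ids = as.character(snp_ids), provenance = provenance),
    class = "snp_dataset"
  )
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("snp_dataset:", nrow(x$genotypes), "samples x", ncol(x$genotypes), "SNPs\n")
  cat("  cases:", sum(x$phenotype == 1L), " controls:", sum(x$phenotype == 0L),
      " missing genotypes:", sum(is.na(x$genotypes)), "\n")
  if (!is.null(x$provenance$source)) cat("  source:", x$provenance$source, "\n")
  if (!is.null(x$provenance$disease_cols)) {
    cat("  simulated disease loci at columns:",
        paste(x$provenance$disease_cols, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.snp_dataset <- function(x) dim(x$genotypes)

n_snps <- function(dataset) ncol(dataset$genotypes)
n_samples <- function(dataset) nrow(dataset$genotypes)

check_snp_indices <- function(dataset, snp_indices) {
  snp_indices <- as.integer(snp_indices)
  if (anyDuplicated(snp_indices)) stop("duplicate SNP index in selection")
  if (any(snp_indices < 1L | snp_indices > n_snps(dataset))) {
    stop("SNP index out of range 1..", n_snps(dataset))
  }
  snp_indices
}

#' Read a case-control genotype table
#'
#' Reads a delimited text file with one header row: SNP columns coded 0/1/2
#' followed by a binary class column. The class column is located by name
#' (`"Class"`, case-insensitive) or, failing that, taken to be the last
#' column. Missing genotypes may be written `NA`, `-9` or left empty.
#'
#' @param path file path.
#' @param dialect `"gametes_tsv"` (tab-separated, the default) or `"csv"`.
#' @param class_column name of the phenotype column; matched
#'   case-insensitively. Default `"Class"`.
#' @return An [snp_dataset].
#' @export
read_dataset <- function(path, dialect = c("gametes_tsv", "csv"),
                         class_column = "Class") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", "-9", ""),
                          colClasses = "integer", data.table = FALSE)
  if (ncol(dt) < 2L) stop("dataset needs at least one SNP column and a class column")
  cls_idx <- which(tolower(names(dt)) == tolower(class_column))
  if (length(cls_idx) == 0L) cls_idx <- ncol(dt)
  if (length(cls_idx) > 1L) stop("multiple columns named '", class_column, "'")
  phenotype <- dt[[cls_idx]]
  if (anyNA(phenotype)) stop("missing values in the class column are not allowed")
  geno <- as.matrix(dt[, -cls_idx, drop = FALSE])
  bad <- which(!(geno %in% c(0L, 1L, 2L) | is.na(geno)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(geno))
    stop("invalid genotype value '", geno[bad[1L]], "' at data row ", rc[1L],
         ", column '", colnames(geno)[rc[2L]], "': expected 0, 1, 2 or a missing marker")
  }
  snp_dataset(geno, phenotype, snp_ids = colnames(geno),
              provenance = list(source = path, dialect = dialect))
}

#' Write a dataset as a GAMETES-style delimited table
#'
#' Emits tab-separated (or comma-separated) text with Unix newlines: one
#' header row of SNP ids followed by a `Class` column; missing genotypes are
#' written as `NA`.
#'
#' @param dataset an [snp_dataset].
#' @param path output file path.
#' @param dialect `"gametes_tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, dialect = c("gametes_tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "snp_dataset"))
  df <- as.data.frame(dataset$genotypes)
  names(df) <- dataset$snp_ids
  df$Class <- dataset$phenotype
  data.table::fwrite(df, path, sep = if (dialect == "csv") "," else "\t",
                     eol = "\n", na = "NA", quote = FALSE)
  invisible(path)
}

#' Impute missing genotypes by k-nearest neighbours
#'
#' Fills each missing genotype with the majority genotype among the
#' `k_neighbors` nearest samples, where distance between two samples is the
#' Hamming distance over their mutually observed SNP columns divided by the
#' number of such columns. Only donors with an observed value at the missing
#' column are eligible. Ties in the vote go to the lower genotype value; ties
#' in distance are broken by sample order, so the result is deterministic.
#'
#' @param dataset an [snp_dataset], possibly with `NA` genotypes.
#' @param k_neighbors number of donor samples to vote (default 5).
#' @return An [snp_dataset] with no missing genotypes; observed cells are
#'   never altered.
#' @export
impute_knn <- function(dataset, k_neighbors = 5L) {
  stopifnot(inherits(dataset, "snp_dataset"), k_neighbors >= 1L)
  G <- dataset$genotypes
  if (!anyNA(G)) return(dataset)
  if (any(colSums(!is.na(G)) == 0L)) {
    stop("cannot impute: at least one SNP column is entirely missing")
  }
  if (any(rowSums(!is.na(G)) == 0L)) {
    stop("cannot impute: at least one sample has no observed genotype")
  }
  obs <- !is.na(G)
  G0 <- G
  G0[!obs] <- 0L
  # pairwise normalized Hamming distance via dot products over shared columns
  shared <- tcrossprod(obs * 1)                      # mutually observed counts
  eq <- matrix(0, nrow(G), nrow(G))
  for (g in 0:2) {
    Ig <- (G0 == g & obs) * 1
    eq <- eq + tcrossprod(Ig)
  }
  mismatch <- shared - eq
  D <- ifelse(shared > 0, mismatch / shared, Inf)
  diag(D) <- Inf
  targets <- which(!obs, arr.ind = TRUE)
  for (r in seq_len(nrow(targets))) {
    i <- targets[r, 1L]; j <- targets[r, 2L]
    donors <- which(obs[, j] & is.finite(D[i, ]))
    if (length(donors) == 0L) stop("no donor with an observed genotype for sample ",
                                   i, ", column ", j)
    donors <- donors[order(D[i, donors], donors)]
    top <- donors[seq_len(min(k_neighbors, length(donors)))]
    votes <- tabulate(G[top, j] + 1L, nbins = 3L)
    G[i, j] <- which.max(votes) - 1L               # which.max ties -> lower genotype
  }
  out <- dataset
  out$genotypes <- G
  out$provenance <- c(dataset$provenance,
                      list(imputation = list(method = "knn", k = k_neighbors,
                                             n_filled = nrow(targets))))
  snp_dataset(out$genotypes, out$phenotype, out$snp_ids, out$provenance)
}

#' Balance class sizes by bootstrap resampling the minority class
#'
#' Resamples the minority class with replacement (seeded) until both classes
#' have the same number of samples; the majority class is untouched. Used to
#' enlarge a small control arm before association testing.
#'
#' @param dataset an [snp_dataset] with both classes present.
#' @param rng_seed integer seed for the resampling.
#' @return An [snp_dataset] with equal case/control counts; provenance records
#'   the resampled row indices.
#' @export
balance_bootstrap <- function(dataset, rng_seed = 1L) {
  stopifnot(inherits(dataset, "snp_dataset"))
  n1 <- sum(dataset$phenotype == 1L)
  n0 <- sum(dataset$phenotype == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to balance")
  if (n1 == n0) return(dataset)
  minority <- if (n0 < n1) 0L else 1L
  idx_min <- which(dataset$phenotype == minority)
  deficit <- abs(n1 - n0)
  extra <- local_seed(rng_seed, sample(idx_min, deficit, replace = TRUE))
  keep <- c(seq_along(dataset$phenotype), extra)
  snp_dataset(dataset$genotypes[keep, , drop = FALSE],
              dataset$phenotype[keep],
              dataset$snp_ids,
              c(dataset$provenance,
                list(bootstrap = list(minority_class = minority, seed = rng_seed,
                                      resampled_rows = extra))))
}

# run expr under a temporary RNG seed, restoring global RNG state afterwards
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
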