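# Naive nested-loop oracles over raw sample vectors, independent of the
# package's counting path (these use paste()/table() keys and definitional
# sums, the package uses base-3 cell encoding and entropy differences).

oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

oracle_joint_entropy <- function(cols) {
  key <- do.call(paste, c(cols, sep = "|"))
  oracle_entropy(key)
}

# definitional sum I = sum p(x,c) log(p(x,c) / (p(x) p(c)))
oracle_mi <- function(x, c) {
  n <- length(x)
  mi <- 0
  for (xv in unique(x)) {
    for (cv in unique(c)) {
      pxy <- sum(x == xv & c == cv) / n
      if (pxy == 0) next
      px <- sum(x == xv) / n
      pc <- sum(c == cv) / n
      mi <- mi + pxy * log(pxy / (px * pc))
    }
  }
  mi
}

oracle_jmi <- function(cols, c) {
  key <- do.call(paste, c(cols, sep = "|"))
  oracle_mi(key, c)
}

oracle_ig <- function(x, y, c) {
  oracle_jmi(list(x, y), c) - oracle_mi(x, c) - oracle_mi(y, c)
}

oracle_iwf <- function(x, y, c) {
  1 + oracle_ig(x, y, c) / (oracle_entropy(x) + oracle_entropy(y))
}

oracle_su <- function(x, c, mode = "modified") {
  mi <- oracle_mi(x, c)
  if (mode == "standard") 2 * mi / (oracle_entropy(x) + oracle_entropy(c))
  else 2 * mi / (oracle_joint_entropy(list(x, c)))
}

# random genotype/phenotype dataset with both classes guaranteed
random_dataset <- function(seed, n, N) {
  set.seed(seed)
  probs <- function() { p <- runif(3); p / sum(p) }
  G <- vapply(seq_len(N), function(j) sample(0:2, n, replace = TRUE, prob = probs()),
              integer(n))
  pheno <- sample(0:1, n, replace = TRUE)
  if (length(unique(pheno)) == 1L) pheno[1L] <- 1L - pheno[1L]
  snp_dataset(G, pheno)
}

# build a dataset realising an exact cell-count specification:
# cells = data.frame with genotype columns g1..gk, column c, column count
dataset_from_cells <- function(cells) {
  gcols <- grep("^g", names(cells), value = TRUE)
  rows <- rep(seq_len(nrow(cells)), cells$count)
  G <- as.matrix(cells[rows, gcols, drop = FALSE])
  rownames(G) <- NULL
  snp_dataset(G, cells$c[rows])
}

# exact XOR-parity construction on binary-coded SNPs: 25 samples per
# (x, y) cell, phenotype = parity; singles carry zero information
xor_dataset <- function(per_cell = 25L) {
  cells <- expand.grid(g1 = 0:1, g2 = 0:1)
  cells$c <- (cells$g1 + cells$g2) %% 2L
  cells$count <- per_cell
  dataset_from_cells(cells)
}

# product-count construction: three mutually independent variables
independent_dataset <- function() {
  cells <- expand.grid(g1 = 0:2, g2 = 0:2, c = 0:1)
  nx <- c(2L, 1L, 1L); ny <- c(1L, 1L, 2L); nc <- c(1L, 1L)
  cells$count <- nx[cells$g1 + 1L] * ny[cells$g2 + 1L] * nc[cells$c + 1L]
  dataset_from_cells(cells)
}
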