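test_that("entropy matches closed forms and handles degenerate distributions", {
  expect_equal(entropy(rep(1 / 3, 3)), log(3), tolerance = 1e-12)
  expect_equal(entropy(c(1, 0, 0)), 0)
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  d <- discrete_distribution(0:2, c(0.5, 0.25, 0.25), n = 100L)
  expect_equal(entropy(d), 1.5 * log(2), tolerance = 1e-12)
  expect_error(discrete_distribution(0:1, c(0.6, 0.6)), "sum to 1")
  expect_error(entropy(c(0.5, 0.6)), "sum to 1")
})

test_that("joint_counts tabulates cells in lexicographic order with zero cells present", {
  d <- snp_dataset(matrix(0L, 4, 1), c(0L, 0L, 1L, 1L))
  tab <- joint_counts(d, 1L)
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(tab$counts["0", ], c(control = 2L, case = 2L))
  expect_equal(sum(tab$counts), 4L)
  expect_equal(unname(tab$counts[c("1", "2"), ]), matrix(0L, 2, 2))

  d3 <- random_dataset(11, 60, 5)
  tab3 <- joint_counts(d3, c(1L, 3L, 5L), include_phenotype = FALSE)
  expect_length(tab3$counts, 27L)
  expect_equal(sum(tab3$counts), 60L)
  # lexicographic order: cell label of sample's tuple indexes its own count
  g <- d3$genotypes[1, c(1, 3, 5)]
  lab <- paste(g, collapse = "/")
  expect_gte(tab3$counts[lab], 1L)

  dm <- d3; dm$genotypes[2, 3] <- NA_integer_
  expect_error(joint_counts(dm, c(1L, 3L)), "impute")
  expect_error(joint_counts(d3, c(2L, 2L)), "duplicate")
})

test_that("joint entropy: duplication, independence additivity, and oracle equality", {
  d <- random_dataset(7, 100, 2)
  d$genotypes[, 2] <- d$genotypes[, 1]           # exact duplicate
  h1 <- joint_entropy(joint_counts(d, 1L, include_phenotype = FALSE))
  h12 <- joint_entropy(joint_counts(d, c(1L, 2L), include_phenotype = FALSE))
  expect_equal(h12, h1, tolerance = 1e-12)

  cells <- expand.grid(g1 = 0:1, g2 = 0:1)
  cells$c <- 0L; cells$count <- 25L
  du <- dataset_from_cells(cells)
  expect_equal(joint_entropy(joint_counts(du, c(1L, 2L), include_phenotype = FALSE)),
               2 * log(2), tolerance = 1e-12)

  d2 <- random_dataset(13, 150, 2)
  tab <- joint_counts(d2, c(1L, 2L), include_phenotype = FALSE)
  expect_equal(joint_entropy(tab),
               oracle_joint_entropy(list(d2$genotypes[, 1], d2$genotypes[, 2])),
               tolerance = 1e-12)
})

test_that("mutual information: independence, identity, and dual-route agreement", {
  du <- independent_dataset()
  expect_equal(mutual_information(joint_counts(du, 1L)), 0, tolerance = 1e-12)

  cells <- data.frame(g1 = c(0L, 1L), c = c(0L, 1L), count = c(30L, 30L))
  did <- dataset_from_cells(cells)
  tab <- joint_counts(did, 1L)
  expect_equal(mutual_information(tab), oracle_entropy(did$phenotype), tolerance = 1e-12)

  cells2 <- expand.grid(g1 = 0:1, c = 0:1)
  cells2$count <- c(30L, 10L, 10L, 30L)
  d2 <- dataset_from_cells(cells2)
  mi_pkg <- mutual_information(joint_counts(d2, 1L))
  mi_orc <- oracle_mi(d2$genotypes[, 1], d2$phenotype)
  expect_equal(mi_pkg, mi_orc, tolerance = 1e-10)
})

test_that("joint mutual information reduces at k=1, saturates on XOR, vanishes under permutation", {
  d <- random_dataset(19, 120, 4)
  expect_equal(joint_mutual_information(2L, d),
               mutual_information(joint_counts(d, 2L)), tolerance = 1e-12)

  dx <- xor_dataset()
  hc <- oracle_entropy(dx$phenotype)
  expect_equal(joint_mutual_information(c(1L, 2L), dx), hc, tolerance = 1e-12)
  expect_lt(mutual_information(joint_counts(dx, 1L)), 1e-12)

  set.seed(101)
  dp <- random_dataset(23, 5000, 2)
  jmi_null <- joint_mutual_information(c(1L, 2L), dp)
  # null JMI ~ chi2_df / (2n); allow 5x the mean chi-square scale
  df_scale <- (9 - 1) * (2 - 1)
  expect_lt(jmi_null, 5 * df_scale / (2 * 5000))

  expect_error(joint_mutual_information(1:7, d), "3\\^k")
})

test_that("interaction gain: redundancy limit, XOR synergy, independence", {
  d <- random_dataset(29, 200, 2)
  d$genotypes[, 2] <- d$genotypes[, 1]
  mi1 <- mutual_information(joint_counts(d, 1L))
  expect_equal(interaction_gain(1L, 2L, d), -mi1, tolerance = 1e-10)

  dx <- xor_dataset()
  expect_equal(interaction_gain(1L, 2L, dx), log(2), tolerance = 1e-12)

  du <- independent_dataset()
  expect_equal(interaction_gain(1L, 2L, du), 0, tolerance = 1e-12)
})

test_that("interaction weight factor: neutrality, redundancy bound, XOR oracle", {
  du <- independent_dataset()
  expect_equal(interaction_weight_factor(1L, 2L, du), 1, tolerance = 1e-12)

  set.seed(31)
  g <- sample(0:2, 300, replace = TRUE)
  pheno <- as.integer(g > 0)                     # informative SNP
  d <- snp_dataset(cbind(g, g), pheno)
  expect_lte(interaction_weight_factor(1L, 2L, d), 1 + 1e-12)

  dx <- xor_dataset()
  iwf_pkg <- interaction_weight_factor(1L, 2L, dx)
  expect_equal(iwf_pkg, oracle_iwf(dx$genotypes[, 1], dx$genotypes[, 2], dx$phenotype),
               tolerance = 1e-12)
  expect_equal(iwf_pkg,
               1 + log(2) / (oracle_entropy(dx$genotypes[, 1]) +
                             oracle_entropy(dx$genotypes[, 2])),
               tolerance = 1e-12)
})

test_that("symmetrical uncertainty: identity, independence, mode ratio identity", {
  cells <- data.frame(g1 = c(0L, 1L), c = c(0L, 1L), count = c(40L, 40L))
  did <- dataset_from_cells(cells)
  expect_equal(symmetrical_uncertainty(1L, did, "standard"), 1, tolerance = 1e-12)
  expect_equal(symmetrical_uncertainty(1L, did, "modified"), 2, tolerance = 1e-12)

  du <- independent_dataset()
  expect_equal(symmetrical_uncertainty(1L, du, "standard"), 0, tolerance = 1e-12)
  expect_equal(symmetrical_uncertainty(1L, du, "modified"), 0, tolerance = 1e-12)

  d <- random_dataset(37, 250, 3)
  for (i in 1:3) {
    s_std <- symmetrical_uncertainty(i, d, "standard")
    s_mod <- symmetrical_uncertainty(i, d, "modified")
    x <- d$genotypes[, i]
    ratio <- (oracle_entropy(x) + oracle_entropy(d$phenotype)) /
      oracle_joint_entropy(list(x, d$phenotype))
    if (s_std > 0) expect_equal(s_mod / s_std, ratio, tolerance = 1e-10)
    expect_gte(s_mod, s_std - 1e-12)
  }
})

test_that("information identities hold across random tables (property sweep)", {
  for (seed in 1:25) {
    d <- random_dataset(seed + 400, sample(30:200, 1), sample(2:6, 1))
    i <- sample(ncol(d$genotypes), 1)
    x <- d$genotypes[, i]; c <- d$phenotype
    mi_pkg <- mutual_information(joint_counts(d, i))
    expect_equal(mi_pkg, oracle_mi(x, c), tolerance = 1e-10)
    expect_gte(mi_pkg, 0)
    expect_lte(mi_pkg, min(oracle_entropy(x), oracle_entropy(c)) + 1e-12)
    # joint entropy is permutation-invariant in its axes
    if (ncol(d$genotypes) >= 2) {
      pair <- sample(ncol(d$genotypes), 2)
      h_ab <- joint_entropy(joint_counts(d, pair, include_phenotype = FALSE))
      h_ba <- joint_entropy(joint_counts(d, rev(pair), include_phenotype = FALSE))
      expect_equal(h_ab, h_ba, tolerance = 1e-12)
    }
  }
})
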