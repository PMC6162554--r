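# deterministic parity model: odd allele-count parity is always a case
parity_model <- function() {
  pen <- outer(0:2, 0:2, function(g1, g2) as.numeric((g1 + g2) %% 2 == 1))
  penetrance_model(c(0.5, 0.5), as.vector(t(pen)), label = "parity")
}

test_that("score_all_su ranks a phenotype-identical SNP first and has the right shape", {
  set.seed(21)
  G <- vapply(1:8, function(j) sample(0:2, 300, replace = TRUE), integer(300))
  pheno <- sample(0:1, 300, replace = TRUE)
  G[, 5] <- pheno                      # SNP identical to the phenotype
  d <- snp_dataset(G, pheno)
  st <- score_all_su(d)
  expect_length(st$su, 8L)
  expect_equal(which.max(st$su), 5L)
  expect_true(all(st$w == 1))
  for (i in 1:8) {
    expect_equal(st$su[i], oracle_su(G[, i], pheno, "modified"), tolerance = 1e-10)
  }
  dconst <- snp_dataset(G, rep(1L, 300))
  expect_error(score_all_su(dconst), "constant")
})

test_that("on an all-null dataset the top SU stays inside the permutation envelope", {
  set.seed(22)
  d <- random_dataset(22, 200, 10)
  st <- score_all_su(d)
  # null envelope: max over SNPs of SU under phenotype permutation, 99th pctile
  perm_max <- replicate(200, {
    dp <- d; dp$phenotype <- sample(d$phenotype)
    max(score_all_su(dp)$su)
  })
  expect_lte(max(st$su), quantile(perm_max, 0.995))
})

test_that("select_seed takes the SU x W argmax with lowest-index ties and signals exhaustion", {
  d <- random_dataset(23, 50, 2)
  st <- score_all_su(d)
  st$su <- c(0.9, 0.5); st$w <- c(0, 1); st$available <- c(TRUE, TRUE)
  expect_equal(select_seed(st), 2L)
  st$su <- c(0.4, 0.4); st$w <- c(1, 1)
  expect_equal(select_seed(st), 1L)
  st$w <- c(0, 0)
  expect_true(is.na(select_seed(st)))

  set.seed(23)
  st$su <- runif(2); st$w <- runif(2)
  score <- st$su * st$w
  expect_equal(select_seed(st), which(score == max(score))[1L])
})

test_that("expand_combination recovers a planted deterministic partner among noise", {
  spec <- simulation_spec(400, 400, 18, parity_model(), rng_seed = 31)
  d <- simulate_dataset(spec)
  planted <- d$provenance$disease_cols
  st <- score_all_su(d)
  combo <- expand_combination(planted[1], st, d, k = 2L)
  expect_equal(sort(combo$indices), sort(planted))
  # exhaustive scan oracle: the partner maximises IWF-weighted relevance
  st2 <- score_all_su(d)
  R <- vapply(setdiff(1:20, planted[1]), function(i) {
    iwf <- oracle_iwf(d$genotypes[, i], d$genotypes[, planted[1]], d$phenotype)
    iwf * (1 + st2$su[i])
  }, numeric(1))
  expect_equal(setdiff(1:20, planted[1])[which.max(R)], planted[2])
})

test_that("first pair equals the exhaustive relevance argmax from the top-SU seed", {
  for (seed in c(41, 42, 43)) {
    d <- random_dataset(seed, 300, 12)
    st <- score_all_su(d)
    seed_snp <- which.max(st$su)
    sc <- run_search(d, search_config(k = 2, K = 1, T_size = 1))
    cand <- setdiff(1:12, seed_snp)
    R <- vapply(cand, function(i) {
      oracle_iwf(d$genotypes[, i], d$genotypes[, seed_snp], d$phenotype) *
        (1 + oracle_su(d$genotypes[, i], d$phenotype, "modified"))
    }, numeric(1))
    expect_equal(sort(sc[[1]]$indices), sort(c(seed_snp, cand[which.max(R)])))
  }
})

test_that("run_search is deterministic, respects T, dedups, and stays under the IWF bound", {
  d <- simulate_dataset(simulation_spec(300, 300, 28, builtin_models()$threshold2,
                                        rng_seed = 51))
  cfg <- search_config(k = 2)
  sc1 <- run_search(d, cfg)
  sc2 <- run_search(d, cfg)
  expect_identical(lapply(sc1, `[[`, "indices"), lapply(sc2, `[[`, "indices"))
  expect_lte(length(sc1), cfg$T_size)
  keys <- vapply(sc1, function(cb) paste(sort(cb$indices), collapse = "-"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (cb in sc1) expect_equal(anyDuplicated(cb$indices), 0L)
  expect_lte(attr(sc1, "n_iwf_evals"), attr(sc1, "iwf_bound"))

  cfg3 <- search_config(k = 3, seed_reuse = "reselect")
  sc3 <- run_search(d, cfg3)
  expect_lte(attr(sc3, "n_iwf_evals"), attr(sc3, "iwf_bound"))
  for (cb in sc3) expect_length(cb$indices, 3L)
})

test_that("an unattainable candidate quota returns short with a warning", {
  d <- random_dataset(61, 100, 6)
  expect_warning(sc <- run_search(d, search_config(k = 2, K = 1, T_size = 50)),
                 "exhausted")
  expect_lt(length(sc), 50L)
  expect_gte(length(sc), 1L)
})

test_that("default_theta follows the Bonferroni-style formula and its boundary cases", {
  expect_equal(default_theta(0.5, 100, 2), 0.01 * 0.5 / choose(100, 2), tolerance = 1e-12)
  expect_equal(default_theta(0.5, 100, 2), 0.005 / 4950, tolerance = 1e-12)
  expect_equal(default_theta(0.2, 7, 7), 0.01 * 0.2, tolerance = 1e-12)
  th <- vapply(c(50, 100, 500, 1000, 5000), function(N) default_theta(0.3, N, 2), numeric(1))
  expect_true(all(diff(th) < 0))
  # log-space survives choose() ranges that overflow naive arithmetic
  expect_gt(default_theta(0.3, 1e6, 6), 0)
  expect_error(default_theta(0.6, 100, 2), "maf")
})

test_that("filter_candidates keeps planted signal, drops null candidates, orders by p", {
  d <- simulate_dataset(simulation_spec(800, 800, 98, builtin_models()$threshold2,
                                        rng_seed = 71))
  cfg <- search_config(k = 2)
  sc <- run_search(d, cfg)
  sig <- filter_candidates(sc, d, cfg)
  keys <- vapply(sig, function(cb) paste(sort(cb$indices), collapse = "-"), character(1))
  expect_true(paste(sort(d$provenance$disease_cols), collapse = "-") %in% keys)
  p <- vapply(sig, function(cb) cb$gtest$p_value, numeric(1))
  expect_true(all(diff(p) >= 0))

  expect_length(filter_candidates(list(), d, cfg), 0L)

  # pure-null candidates at a Bonferroni-scale threshold essentially never pass
  survivors <- 0L
  for (s in 1:20) {
    dn <- random_dataset(900 + s, 400, 10)
    cand <- list(structure(list(indices = c(1L, 2L), snp_ids = dn$snp_ids[1:2],
                                relevance_trace = numeric(0)),
                           class = "snp_combination"))
    survivors <- survivors + length(filter_candidates(cand, dn, search_config(k = 2)))
  }
  expect_lte(survivors, 1L)
})

test_that("edge-list export writes a two-column pair table", {
  d <- simulate_dataset(simulation_spec(300, 300, 18, builtin_models()$threshold2,
                                        rng_seed = 81))
  cfg <- search_config(k = 2)
  sig <- filter_candidates(run_search(d, cfg), d, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(attr(sig, "all_candidates"), path)
  tab <- read.delim(path)
  expect_named(tab, c("snp_a", "snp_b", "p_value"))
  expect_equal(nrow(tab), length(attr(sig, "all_candidates")))
})
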