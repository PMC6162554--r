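#' Penetrance-table case-control simulator
#'
#' Generates case-control genotype datasets in the style of GAMETES: k
#' disease loci drawn under Hardy-Weinberg equilibrium at stated
#' minor-allele frequencies, with disease status assigned from a 3^k
#' penetrance table, embedded among null SNPs independent of status. The
#' simulator takes explicit penetrance tables (it does not search for
#' models with a target heritability) and ships a small catalogue of
#' synthetic fixture models.
#'
#' @name simulate
NULL

#' Disease penetrance model
#'
#' @param maf minor-allele frequency per disease locus, each in `(0, 0.5]`.
#' @param table penetrance `P(case | genotype combination)` per joint
#'   genotype cell, length `3^k`, in lexicographic genotype-tuple order
#'   (`(0,..,0)` first, first locus most significant), values in `[0, 1]`.
#' @param label model name.
#' @return An object of class `penetrance_model` with fields `k`, `maf`,
#'   `table`, `label`.
#' @export
penetrance_model <- function(maf, table, label = "model") {
  k <- length(maf)
  if (k < 1L) stop("at least one disease locus required")
  if (any(maf <= 0 | maf > 0.5)) stop("each MAF must be in (0, 0.5]")
  if (length(table) != 3L^k) {
    stop("penetrance table must have 3^k = ", 3L^k, " entries, got ", length(table))
  }
  if (any(table < 0 | table > 1)) stop("penetrance values must be in [0, 1]")
  tbl <- as.numeric(table)
  names(tbl) <- genotype_labels(k)
  structure(list(k = as.integer(k), maf = as.numeric(maf), table = tbl, label = label),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("penetrance_model '", x$label, "': ", x$k, " locus/loci, MAF ",
      paste(x$maf, collapse = ", "), "\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' Simulation specification
#'
#' @param n_cases,n_controls sample quotas (typical benchmark designs are
#'   800/800 with 100 SNPs and 2000/2000 with 1000 SNPs).
#' @param n_null_snps number of null SNPs independent of status; total SNP
#'   count is `k + n_null_snps`.
#' @param model a [penetrance_model], or `NULL` for a fully null dataset.
#' @param rng_seed integer seed; fixed seed gives a bit-reproducible dataset.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_cases, n_controls, n_null_snps, model = NULL,
                            rng_seed = 1L) {
  if (n_cases < 0 || n_controls < 0 || n_null_snps < 0) stop("counts must be >= 0")
  if (!is.null(model)) stopifnot(inherits(model, "penetrance_model"))
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_null_snps = as.integer(n_null_snps), model = model,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

#' Sample a genotype column under Hardy-Weinberg equilibrium
#'
#' i.i.d. draws with `P(0) = (1-q)^2`, `P(1) = 2q(1-q)`, `P(2) = q^2` for
#' minor-allele frequency `q`. Uses the current RNG stream.
#'
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @param n number of samples.
#' @return integer vector of genotypes.
#' @export
genotype_hwe <- function(maf, n) {
  if (!(maf > 0 && maf <= 0.5)) stop("maf must be in (0, 0.5]")
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample.int(3L, n, replace = TRUE, prob = probs) - 1L
}

#' Simulate a case-control dataset from a penetrance model
#'
#' Rejection sampler: disease-locus genotypes are drawn under HWE at the
#' model MAFs, each draw becomes a case with probability equal to its
#' penetrance, and draws are kept until both the case and control quotas
#' are filled exactly. Null SNP columns are drawn independently of status
#' with MAFs sampled uniformly in `[0.05, 0.5]`. The disease loci are
#' placed at randomised column positions, recorded in
#' `provenance$disease_cols`.
#'
#' @param spec a [simulation_spec].
#' @param max_batches bound on rejection-sampling batches before declaring
#'   the quota unattainable (degenerate penetrance table).
#' @return an [snp_dataset]; `provenance` records the spec, the disease
#'   column positions, and all MAFs.
#' @export
simulate_dataset <- function(spec, max_batches = 1000L) {
  stopifnot(inherits(spec, "simulation_spec"))
  local_seed(spec$rng_seed, {
    n_total <- spec$n_cases + spec$n_controls
    model <- spec$model
    if (!is.null(model)) {
      if (spec$n_cases > 0L && all(model$table == 0)) {
        stop("penetrance table is identically 0: case quota unattainable")
      }
      if (spec$n_controls > 0L && all(model$table == 1)) {
        stop("penetrance table is identically 1: control quota unattainable")
      }
      cases <- matrix(0L, 0L, model$k)
      controls <- matrix(0L, 0L, model$k)
      batch <- max(1000L, 4L * n_total)
      tries <- 0L
      while (nrow(cases) < spec$n_cases || nrow(controls) < spec$n_controls) {
        tries <- tries + 1L
        if (tries > max_batches) {
          stop("case/control quotas not reached after ", max_batches,
               " sampling batches; is the penetrance table degenerate?")
        }
        G <- vapply(model$maf, genotype_hwe, integer(batch), n = batch)
        pen <- model$table[encode_genotype_tuples(G)]
        is_case <- stats::runif(batch) < pen
        if (nrow(cases) < spec$n_cases) {
          cases <- rbind(cases, G[is_case, , drop = FALSE])
        }
        if (nrow(controls) < spec$n_controls) {
          controls <- rbind(controls, G[!is_case, , drop = FALSE])
        }
      }
      disease_geno <- rbind(cases[seq_len(spec$n_cases), , drop = FALSE],
                            controls[seq_len(spec$n_controls), , drop = FALSE])
      phenotype <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
      k <- model$k
    } else {
      disease_geno <- matrix(0L, n_total, 0L)
      phenotype <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
      k <- 0L
    }
    null_maf <- stats::runif(spec$n_null_snps, 0.05, 0.5)
    null_geno <- vapply(null_maf, genotype_hwe, integer(n_total), n = n_total)
    if (spec$n_null_snps == 0L) null_geno <- matrix(0L, n_total, 0L)
    N <- k + spec$n_null_snps
    positions <- sample.int(N, N)           # permutation of column slots
    disease_cols <- sort(positions[seq_len(k)])
    geno <- matrix(0L, n_total, N)
    if (k > 0L) geno[, positions[seq_len(k)]] <- disease_geno
    if (spec$n_null_snps > 0L) geno[, positions[k + seq_len(spec$n_null_snps)]] <- null_geno
    maf_all <- numeric(N)
    if (k > 0L) maf_all[positions[seq_len(k)]] <- model$maf
    if (spec$n_null_snps > 0L) maf_all[positions[k + seq_len(spec$n_null_snps)]] <- null_maf
    row_order <- sample.int(n_total, n_total)
    snp_dataset(geno[row_order, , drop = FALSE], phenotype[row_order],
                snp_ids = paste0("SNP", seq_len(N)),
                provenance = list(
                  source = "simulate_dataset",
                  spec = spec,
                  disease_cols = if (k > 0L) as.integer(disease_cols) else integer(0),
                  maf = maf_all,
                  model_label = if (!is.null(model)) model$label else "null"))
  })
}

#' Catalogue of synthetic fixture disease models
#'
#' Small penetrance models exercising the main epistasis regimes. These are
#' synthetic fixtures, not any published benchmark model set:
#' `multiplicative2` (risk multiplies across risk genotypes, clear marginal
#' effects), `threshold2` (elevated risk only when both loci carry a risk
#' allele), `xor2` (pure parity epistasis at MAF 0.5 — every single-locus
#' marginal penetrance is flat, the regime where seed-guided search is
#' known to struggle), and `nested3` (a 3-locus model whose loci all carry
#' marginal effects, with a 3-way interaction on top).
#'
#' @return named list of [penetrance_model] objects.
#' @export
builtin_models <- function() {
  mult_pen <- outer(0:2, 0:2, function(g1, g2) 0.05 * 1.9^(g1 + g2))
  multiplicative2 <- penetrance_model(c(0.3, 0.3), as.vector(t(mult_pen)),
                                      label = "multiplicative2")
  thr_pen <- outer(0:2, 0:2, function(g1, g2) ifelse(g1 >= 1 & g2 >= 1, 0.6, 0.1))
  threshold2 <- penetrance_model(c(0.3, 0.3), as.vector(t(thr_pen)),
                                 label = "threshold2")
  xor_pen <- outer(0:2, 0:2, function(g1, g2) ifelse((g1 + g2) %% 2 == 1, 0.7, 0.1))
  xor2 <- penetrance_model(c(0.5, 0.5), as.vector(t(xor_pen)), label = "xor2")
  grid <- expand.grid(g3 = 0:2, g2 = 0:2, g1 = 0:2)   # g3 fastest = lexicographic
  nested_pen <- with(grid, 0.05 + 0.12 * (g1 >= 1) + 0.12 * (g2 >= 1) +
                       0.06 * (g3 >= 1) + 0.35 * (g1 >= 1) * (g2 >= 1) * (g3 >= 1))
  nested3 <- penetrance_model(c(0.3, 0.3, 0.25), nested_pen, label = "nested3")
  list(multiplicative2 = multiplicative2, threshold2 = threshold2,
       xor2 = xor2, nested3 = nested3)
}

#' Analytic marginal penetrance of one disease locus
#'
#' `P(case | genotype g at locus j)`, averaging the penetrance table over
#' the HWE genotype distribution of the other loci. Used to check simulated
#' data against its generating model.
#'
#' @param model a [penetrance_model].
#' @param locus locus index in `1..k`.
#' @return numeric length-3 vector, `P(case | g = 0, 1, 2)`.
#' @export
marginal_penetrance <- function(model, locus) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- model$k
  if (locus < 1L || locus > k) stop("locus out of range")
  cell <- seq_len(3L^k) - 1L
  gmat <- vapply(seq_len(k), function(j) as.integer((cell %/% 3^(k - j)) %% 3), integer(3L^k))
  hwe <- lapply(model$maf, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  cellp <- rep(1, 3L^k)
  for (j in seq_len(k)) cellp <- cellp * hwe[[j]][gmat[, j] + 1L]
  vapply(0:2, function(g) {
    sel <- gmat[, locus] == g
    sum(model$table[sel] * cellp[sel]) / sum(cellp[sel])
  }, numeric(1))
}

#' Design-adjusted expectations for a simulated case-control sample
#'
#' Under case-control sampling the genotype frequencies at a disease locus
#' are enriched relative to the population: cases over-represent high-risk
#' genotypes. Given the penetrance model and the case/control quotas, this
#' returns, per locus, the expected sample allele frequency and the expected
#' case fraction stratified by genotype, for checking simulated data against
#' its generating model.
#'
#' @param model a [penetrance_model].
#' @param n_cases,n_controls sampling quotas.
#' @return list with `sample_allele_freq` (per-locus expected minor-allele
#'   frequency in the combined sample), `case_rate` (per-locus length-3
#'   vectors, expected `P(case | g)` under the sampling design),
#'   `genotype_freq` (per-locus expected sample genotype frequencies), and
#'   `prevalence` (population `P(case)` of the model).
#' @export
casecontrol_expectations <- function(model, n_cases, n_controls) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- model$k
  cell <- seq_len(3L^k) - 1L
  gmat <- vapply(seq_len(k), function(j) as.integer((cell %/% 3^(k - j)) %% 3), integer(3L^k))
  hwe <- lapply(model$maf, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  cellp <- rep(1, 3L^k)
  for (j in seq_len(k)) cellp <- cellp * hwe[[j]][gmat[, j] + 1L]
  prev <- sum(model$table * cellp)
  w_total <- n_cases + n_controls
  out_q <- numeric(k); out_rate <- vector("list", k); out_gf <- vector("list", k)
  for (j in seq_len(k)) {
    p_case <- p_ctrl <- numeric(3)
    for (g in 0:2) {
      sel <- gmat[, j] == g
      p_case[g + 1L] <- sum(model$table[sel] * cellp[sel]) / prev
      p_ctrl[g + 1L] <- sum((1 - model$table[sel]) * cellp[sel]) / (1 - prev)
    }
    exp_case_n <- n_cases * p_case
    exp_ctrl_n <- n_controls * p_ctrl
    out_rate[[j]] <- exp_case_n / (exp_case_n + exp_ctrl_n)
    gf <- (exp_case_n + exp_ctrl_n) / w_total
    out_gf[[j]] <- gf
    q <- (gf[2L] + 2 * gf[3L]) / 2
    out_q[j] <- min(q, 1 - q)
  }
  list(sample_allele_freq = out_q, case_rate = out_rate,
       genotype_freq = out_gf, prevalence = prev)
}

#' Analytic disease prevalence of a model
#'
#' @param model a [penetrance_model].
#' @return `P(case)` under HWE genotype frequencies.
#' @export
model_prevalence <- function(model) {
  k <- model$k
  cell <- seq_len(3L^k) - 1L
  gmat <- vapply(seq_len(k), function(j) as.integer((cell %/% 3^(k - j)) %% 3), integer(3L^k))
  hwe <- lapply(model$maf, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  cellp <- rep(1, 3L^k)
  for (j in seq_len(k)) cellp <- cellp * hwe[[j]][gmat[, j] + 1L]
  sum(model$table * cellp)
}
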