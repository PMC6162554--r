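#' Seed-guided interaction-weight forward search
#'
#' The search stage ranks every SNP by modified symmetrical uncertainty
#' (SU), repeatedly picks the available SNP with the largest SU x W product
#' as a seed, and grows each seed into a k-way combination by a forward
#' search: at every step the interaction weight factor (IWF) of each
#' remaining SNP against the most recently added member multiplies that
#' SNP's weight coefficient W, and the SNP maximising the relevance
#' `R = W * (1 + SU)` joins the combination. Weight coefficients persist
#' across the whole run (they are never reset), so later searches are
#' history-dependent by design. Candidates are then verified with the
#' improved G-test.
#'
#' @name search
NULL

#' Search configuration
#'
#' @param k combination order (>= 2).
#' @param K combinations grown per seed (default `k`, the convention used
#'   for simulation studies).
#' @param T_size candidate-set size: the search stops once this many distinct
#'   combinations are collected (default `2 * k`).
#' @param theta G-test p-value threshold for the filtering stage, or
#'   `"auto"` (default) for `0.01 * MAF / choose(N, k)` with MAF the minimum
#'   sample minor-allele frequency among each candidate's SNPs.
#' @param xi small-cell gate for the G-test, integer in `[0, 5]` (default 5).
#' @param expectation_mode expected-count model for the G-test.
#' @param seed_reuse `"literal"` (default): within a seed's K-loop,
#'   combinations after the first start from the last SNP added to the
#'   previous combination; `"reselect"`: every combination starts from a
#'   fresh argmax-SU x W seed.
#' @param tie_break tie rule for all argmax operations; only
#'   `"lowest_index"` is provided.
#' @return a `search_config` list.
#' @export
search_config <- function(k = 2L, K = k, T_size = 2L * k, theta = "auto",
                          xi = 5L, expectation_mode = c("independence", "hwe"),
                          seed_reuse = c("literal", "reselect"),
                          tie_break = "lowest_index") {
  expectation_mode <- match.arg(expectation_mode)
  seed_reuse <- match.arg(seed_reuse)
  k <- as.integer(k); K <- as.integer(K); T_size <- as.integer(T_size)
  if (k < 2L) stop("combination order k must be >= 2")
  if (K < 1L) stop("K must be >= 1")
  if (T_size < 1L) stop("T_size must be >= 1")
  if (!identical(theta, "auto")) {
    theta <- as.numeric(theta)
    if (!(theta > 0 && theta <= 1)) stop("theta must be in (0, 1] or \"auto\"")
  }
  if (tie_break != "lowest_index") stop("only tie_break = \"lowest_index\" is implemented")
  structure(list(k = k, K = K, T_size = T_size, theta = theta, xi = as.integer(xi),
                 expectation_mode = expectation_mode, seed_reuse = seed_reuse,
                 tie_break = tie_break),
            class = "search_config")
}

#' Score every SNP by modified symmetrical uncertainty
#'
#' Initialises the search state: per-SNP modified SU against the phenotype,
#' weight coefficients W all 1, and the availability set F containing every
#' SNP. Per-SNP marginal entropy and mutual information are cached for the
#' interaction-weight updates. Runtime is linear in the number of SNPs.
#'
#' @param dataset an [snp_dataset] with no missing genotypes and a
#'   non-constant phenotype.
#' @return A `weight_state` environment with vectors `su`, `w`, `available`,
#'   `hx`, `mi`, and the counter `n_iwf_evals`.
#' @export
score_all_su <- function(dataset) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (anyNA(dataset$genotypes)) stop("missing genotypes: run impute_knn() first")
  pheno <- dataset$phenotype
  if (length(unique(pheno)) < 2L) stop("phenotype is constant: cannot score SNPs")
  N <- n_snps(dataset)
  su <- numeric(N); hx <- numeric(N); mi <- numeric(N)
  for (i in seq_len(N)) {
    counts <- cbind(tabulate(dataset$genotypes[pheno == 0L, i] + 1L, nbins = 3L),
                    tabulate(dataset$genotypes[pheno == 1L, i] + 1L, nbins = 3L))
    hx[i] <- entropy_from_counts(rowSums(counts))
    if (hx[i] == 0) { su[i] <- 0; mi[i] <- 0; next }
    hc <- entropy_from_counts(colSums(counts))
    hxc <- entropy_from_counts(as.vector(counts))
    mi[i] <- clamp_mi(hx[i] + hc - hxc)
    su[i] <- 2 * mi[i] / hxc
  }
  state <- new.env(parent = emptyenv())
  state$su <- su
  state$w <- rep(1, N)
  state$available <- rep(TRUE, N)
  state$hx <- hx
  state$mi <- mi
  state$n_iwf_evals <- 0L
  class(state) <- "weight_state"
  state
}

#' Select the next seed SNP
#'
#' Argmax of `SU x W` over available SNPs with positive weight; ties go to
#' the lowest SNP index. Returns `NA` when no such SNP remains, signalling
#' search exhaustion.
#'
#' @param state a `weight_state` from [score_all_su].
#' @param tie_break tie rule (only `"lowest_index"`).
#' @return seed SNP index, or `NA_integer_` when the search is exhausted.
#' @export
select_seed <- function(state, tie_break = "lowest_index") {
  eligible <- state$available & state$w > 0
  if (!any(eligible)) return(NA_integer_)
  score <- ifelse(eligible, state$su * state$w, -Inf)
  which.max(score)  # which.max takes the first (lowest-index) maximum
}

# IWF(x, y) from cached marginals; counts the evaluation in the state
iwf_cached <- function(x, y, dataset, state) {
  state$n_iwf_evals <- state$n_iwf_evals + 1L
  hsum <- state$hx[x] + state$hx[y]
  if (hsum == 0) return(1)
  jmi <- joint_mutual_information(c(x, y), dataset)
  ig <- jmi - state$mi[x] - state$mi[y]
  1 + ig / hsum
}

#' Grow one k-way combination from a seed
#'
#' Starts the combination at the seed (removing it from the available set
#' and zeroing its weight), then repeats until k members are collected: for
#' every available SNP the interaction weight factor against the most
#' recently added member multiplies its weight coefficient, the relevance
#' `R = W * (1 + SU)` is computed, and the argmax-R SNP (lowest index on
#' ties) is added and removed from the available set. Weight mutations
#' persist in the shared state.
#'
#' @param seed seed SNP index.
#' @param state a `weight_state`; mutated in place.
#' @param dataset an [snp_dataset].
#' @param k combination order.
#' @return An object of class `snp_combination`: list with `indices`,
#'   `snp_ids`, `relevance_trace`.
#' @export
expand_combination <- function(seed, state, dataset, k) {
  seed <- as.integer(seed)
  if (seed < 1L || seed > n_snps(dataset)) stop("seed index out of range")
  state$available[seed] <- FALSE
  state$w[seed] <- 0
  S <- seed
  trace <- numeric(0)
  while (length(S) < k) {
    F_idx <- which(state$available)
    if (length(F_idx) == 0L) {
      stop(structure(class = c("epiweight_partial_combination", "error", "condition"),
                     list(message = paste0("available SNP set exhausted with only ",
                                           length(S), " of ", k, " members found"),
                          call = sys.call())))
    }
    if (all(state$hx[F_idx] == 0)) {
      stop("no informative SNPs remain: all available SNPs are constant")
    }
    s_a <- S[length(S)]
    for (i in F_idx) {
      state$w[i] <- state$w[i] * iwf_cached(i, s_a, dataset, state)
    }
    R <- state$w[F_idx] * (1 + state$su[F_idx])
    chosen <- F_idx[which.max(R)]
    trace <- c(trace, R[which.max(R)])
    state$available[chosen] <- FALSE
    state$w[chosen] <- 0
    S <- c(S, chosen)
  }
  structure(list(indices = S, snp_ids = dataset$snp_ids[S],
                 relevance_trace = trace),
            class = "snp_combination")
}

combo_key <- function(indices) paste(sort(indices), collapse = "-")

#' Run the full candidate search
#'
#' Outer loop of the search stage: pick a seed, grow `K` combinations from
#' it (per the `seed_reuse` policy), and repeat until `T_size` distinct
#' combinations are collected or the seeds are exhausted (in which case a
#' shorter candidate list is returned with a warning). Deterministic for a
#' given dataset and configuration. The number of interaction-weight
#' evaluations performed is recorded in the `n_iwf_evals` attribute, with
#' its theoretical bound `N * k! * K` in `iwf_bound`.
#'
#' @param dataset an [snp_dataset], imputed.
#' @param config a [search_config].
#' @return list of `snp_combination` candidates (attributes `n_iwf_evals`,
#'   `iwf_bound`, `weight_state`).
#' @export
run_search <- function(dataset, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  if (n_snps(dataset) < config$k) stop("fewer SNPs than the combination order k")
  state <- score_all_su(dataset)
  SC <- list()
  seen <- character(0)
  exhausted <- FALSE
  repeat {
    seed <- select_seed(state, config$tie_break)
    if (is.na(seed)) { exhausted <- TRUE; break }
    for (m in seq_len(config$K)) {
      combo <- tryCatch(
        expand_combination(seed, state, dataset, config$k),
        epiweight_partial_combination = function(e) NULL
      )
      if (is.null(combo)) { exhausted <- TRUE; break }
      key <- combo_key(combo$indices)
      if (!key %in% seen) {
        seen <- c(seen, key)
        SC[[length(SC) + 1L]] <- combo
      }
      if (m < config$K) {
        if (config$seed_reuse == "literal") {
          # the pseudocode re-enters with s_a still bound to the last SNP added
          seed <- combo$indices[config$k]
        } else {
          seed <- select_seed(state, config$tie_break)
          if (is.na(seed)) { exhausted <- TRUE; break }
        }
      }
    }
    if (exhausted || length(SC) >= config$T_size) break
  }
  if (length(SC) < config$T_size) {
    warning("search exhausted after ", length(SC), " of ", config$T_size,
            " requested candidate combinations")
  }
  attr(SC, "n_iwf_evals") <- state$n_iwf_evals
  attr(SC, "iwf_bound") <- n_snps(dataset) * factorial(config$k) * config$K
  attr(SC, "weight_state") <- state
  SC
}

#' Default G-test significance threshold
#'
#' `theta = 0.01 * MAF / choose(N, k)`: a Bonferroni-style bound over the
#' `choose(N, k)` possible k-way combinations, scaled by the minor-allele
#' frequency so rarer variants face a stricter threshold. Computed in log
#' space so large `choose(N, k)` cannot overflow.
#'
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @param N number of SNPs.
#' @param k combination order.
#' @return the threshold.
#' @export
default_theta <- function(maf, N, k) {
  if (!(maf > 0 && maf <= 0.5)) stop("maf must be in (0, 0.5]")
  exp(log(0.01) + log(maf) - lchoose(N, k))
}

# sample minor-allele frequency of one genotype column
sample_maf <- function(genotypes_col) {
  g <- genotypes_col[!is.na(genotypes_col)]
  q <- (sum(g == 1L) + 2 * sum(g == 2L)) / (2 * length(g))
  min(q, 1 - q)
}

#' G-test filtering of candidate combinations
#'
#' Annotates every candidate with its G-test result and returns those with
#' `p < theta`, ordered by ascending p-value. With `theta = "auto"` each
#' candidate gets its own threshold `0.01 * MAF / choose(N, k)` where MAF is
#' the smallest sample minor-allele frequency among its SNPs (the most
#' conservative per-combination bound).
#'
#' @param candidates list of `snp_combination` from [run_search].
#' @param dataset the [snp_dataset] they were found in.
#' @param config the [search_config].
#' @return list of significant `snp_combination`s, each with a `gtest`
#'   element and a `theta` element; attribute `all_candidates` keeps the
#'   full annotated list.
#' @export
filter_candidates <- function(candidates, dataset, config = search_config()) {
  N <- n_snps(dataset)
  annotated <- lapply(candidates, function(combo) {
    combo$gtest <- g_test(dataset, combo$indices, xi = config$xi,
                          mode = config$expectation_mode)
    combo$theta <- if (identical(config$theta, "auto")) {
      maf <- min(vapply(combo$indices,
                        function(i) sample_maf(dataset$genotypes[, i]), numeric(1)))
      if (maf <= 0) maf <- .Machine$double.eps  # monomorphic SNP: vanishing threshold
      default_theta(maf, N, config$k)
    } else config$theta
    combo
  })
  keep <- vapply(annotated, function(cb) cb$gtest$p_value < cb$theta, logical(1))
  sig <- annotated[keep]
  ord <- order(vapply(sig, function(cb) cb$gtest$p_value, numeric(1)))
  sig <- sig[ord]
  attr(sig, "all_candidates") <- annotated
  sig
}

#' Tabulate search/test results
#'
#' @param candidates a list of annotated `snp_combination`s (from
#'   [filter_candidates], or its `all_candidates` attribute).
#' @return data.frame with the SNP ids, G statistic, adjusted df, and
#'   p-value per combination.
#' @export
results_table <- function(candidates) {
  if (length(candidates) == 0L) {
    return(data.frame(snps = character(0), G = numeric(0), df = integer(0),
                      p_value = numeric(0)))
  }
  data.frame(
    snps = vapply(candidates, function(cb) paste(cb$snp_ids, collapse = ","), character(1)),
    G = vapply(candidates, function(cb) cb$gtest$g, numeric(1)),
    df = vapply(candidates, function(cb) cb$gtest$df, integer(1)),
    p_value = vapply(candidates, function(cb) cb$gtest$p_value, numeric(1))
  )
}

#' Export significant pairs as a plain edge list
#'
#' Writes a tab-separated `snp_a`, `snp_b`, `p_value` table for 2-way
#' results, ready for network tools.
#'
#' @param candidates annotated 2-way `snp_combination`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(candidates, path) {
  if (any(vapply(candidates, function(cb) length(cb$indices), integer(1)) != 2L)) {
    stop("edge-list export is defined for 2-way combinations only")
  }
  df <- data.frame(
    snp_a = vapply(candidates, function(cb) cb$snp_ids[1L], character(1)),
    snp_b = vapply(candidates, function(cb) cb$snp_ids[2L], character(1)),
    p_value = vapply(candidates, function(cb) cb$gtest$p_value, numeric(1))
  )
  data.table::fwrite(df, path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}
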