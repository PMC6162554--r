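---
title: "Detecting high-order SNP epistasis with interaction-weight forward search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-order SNP epistasis with interaction-weight forward search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiweight)
```

## The problem

In a case-control genome-wide association study each SNP is coded 0
(homozygous major allele), 1 (heterozygous) or 2 (homozygous minor allele),
and the phenotype C is binary (1 = case, 0 = control). Epistasis is a joint
effect of k loci on disease status that is not explained by the loci's
marginal effects. Testing all `choose(N, k)` combinations is infeasible for
genome-scale N, so `epiweight` implements a two-stage heuristic, FDHE-IW: a
seed-guided forward *search* that assembles a small candidate set using
information-theoretic interaction weights, followed by a *verification*
stage using an improved likelihood-ratio (G) test.

## Information measures

All measures are plug-in (maximum-likelihood frequency) estimates in nats.
Natural logarithms are used throughout: the G-test stage is defined with
`ln`, and the normalised quantities (SU, IWF) are ratios of entropies and
therefore base-invariant, so a single base keeps every code path consistent.
Zero cells contribute 0 to entropy sums and no pseudocounts are added.

* Entropy `H(X) = -sum p(x) log p(x)` and joint entropy over the 3^k cells
  of a genotype combination.
* Mutual information `I(X;C) = H(X) + H(C) - H(X,C)`, and its k-way
  extension `I([X1..Xk];C)`.
* Interaction gain `IG(X;Y;C) = I([X,Y];C) - I(X;C) - I(Y;C)`: positive
  means the pair is synergistic for the phenotype, negative redundant.
* Interaction weight factor `IWF(X,Y) = 1 + IG / (H(X) + H(Y))`, a score in
  [0, 2] with 1 as the neutral point. The printed form of this definition
  is typographically ambiguous between `1 + IG/(H(X)+H(Y))` and
  `(1 + IG)/(H(X)+H(Y))`; only the first satisfies the stated properties
  (neutral value 1 at IG = 0, range [0, 2]), so the first is implemented.
* Symmetrical uncertainty `SU = 2 I(X;C) / (H(X)+H(C))` in [0, 1], and the
  modified form `SU* = 2 I(X;C) / H(X,C)` in [0, 2] used for seeding. The
  joint distribution of a true disease locus with the phenotype tends to be
  more concentrated than marginal sums suggest, so normalising by `H(X,C)`
  lifts weak-marginal susceptibility loci in the ranking; `SU* >= SU`
  always, since `H(X,C) <= H(X) + H(C)`.

Tiny negative mutual-information values caused by floating-point
cancellation are clamped to zero below a tolerance of 1e-12; anything more
negative raises an error, since it indicates a genuine bug rather than
round-off.

## The search stage

With configuration `k` (combination order), `K` (combinations per seed,
default `k`), `T` (candidate-set size, default `2k`):

1. Compute `SU*` for every SNP; set every weight coefficient `W = 1`; all
   SNPs form the available set F.
2. Seed: the SNP maximising `SU* x W` among F.
3. Grow: while the combination has fewer than k members, compute
   `IW = IWF(s_i, s_a)` for every `s_i` in F against the **most recently
   added** member `s_a`, update `W(s_i) <- W(s_i) * IW`, and add the SNP
   maximising the relevance `R = W * (1 + SU*)`; added SNPs leave F and get
   `W = 0`.
4. Repeat from step 2 until T distinct combinations are collected or no
   eligible seed remains (the search then returns short, with a warning).
5. Verify each candidate with the G-test and keep those with `p < theta`.

Three behaviours follow the published pseudocode exactly and deserve
emphasis:

* **Weights persist.** `W` is never reset between seeds or combinations, so
  the candidate list depends on search history. This is intentional and
  makes a run deterministic but order-sensitive.
* **Seed reuse.** Within a seed's K-loop the pseudocode re-enters with the
  loop variable still bound to the last SNP added, so combination m+1 grows
  from the tail of combination m. That literal behaviour is the default
  (`seed_reuse = "literal"`); `"reselect"` re-runs the seed selection
  instead, for users who prefer independent seeds.
* **F shrinks monotonically.** A SNP used in any combination is never
  reconsidered, so the candidates of one run are index-disjoint and at most
  `floor(N/k)` combinations exist; asking for more returns short with a
  warning rather than failing.

All argmax operations break ties by lowest SNP index, making every run
reproducible. The number of IWF evaluations is counted and never exceeds
`N * k! * K`; the count and bound are attached to the result so callers can
audit the complexity claim.

## The verification stage

For a k-way candidate the observed table O has `I = 3^k` genotype rows and
J = 2 phenotype columns, and

```
G = 2 * sum_ij O_ij * ln(O_ij / E_ij)
```

restricted to rows whose total exceeds the small-cell gate `xi` (default 5,
the largest value the method admits). A row with total `<= xi` contributes
nothing to G and reduces the degrees of freedom `(I-1)(J-1)` by one; the
printed description gates the statistic at `> xi` but decrements df at
`< xi`, which is contradictory at equality, so one predicate — excluded iff
total `<= xi` — is applied to both, the conservative side of the boundary.
df floors at 0, in which case p = 1 and the combination can never be
declared significant.

Expected counts default to independence margins (the classical G-test),
which is exact, standard and assumption-free. A Hardy–Weinberg mode is also
provided (`expectation_mode = "hwe"`): per-locus genotype probabilities
`(1-q)^2, 2q(1-q), q^2` from the pooled sample minor-allele frequency,
multiplied across loci and scaled to the phenotype column totals. The HWE
variant is behind a flag because a one-line statement of "expectations from
Hardy–Weinberg principles" underdetermines the multi-locus, case-vs-control
pooling choices; pooled-sample frequencies were chosen as the least
assuming option.

The significance threshold defaults to `theta = 0.01 * MAF / choose(N, k)`
— a Bonferroni-style correction over all k-way combinations scaled by minor
allele frequency — evaluated per candidate with MAF the smallest sample MAF
among its k SNPs (the most conservative choice); `choose(N, k)` is handled
in log space so genome-scale N cannot overflow.

## The simulator

`simulate_dataset()` emulates GAMETES-style benchmark data: k disease loci
drawn under Hardy–Weinberg equilibrium at stated MAFs, disease status
assigned by a 3^k penetrance table via rejection sampling until the case
and control quotas are met exactly, and null SNPs drawn independently of
status with MAFs uniform on [0.05, 0.5] (a conventional GWAS screening
range; the choice is ours, as benchmark descriptions rarely state it).
Columns are mutually independent — no linkage disequilibrium, no population
stratification — and disease loci are placed at randomised, recorded
positions. The generator does *not* search penetrance tables for a target
heritability the way GAMETES does; it takes explicit tables, which is what
the downstream stages need for testing.

Four synthetic fixture models ship with the package (`builtin_models()`):
multiplicative and threshold two-locus models with clear marginal effects,
a pure-parity XOR model at MAF 0.5 whose single-locus marginals are exactly
flat, and a three-locus nested model. They are labelled fixtures — not a
reproduction of any published benchmark model set, whose penetrance tables
are not available here.

Two consequences of the case-control design matter when validating
simulated data. First, at a disease locus the sample allele frequency is
*not* the population MAF: balanced case-control sampling enriches risk
genotypes (for the threshold fixture at MAF 0.3 the expected sample MAF is
0.357). Second, genotype-stratified case fractions differ from marginal
penetrances whenever the sampling fractions differ from prevalence.
`casecontrol_expectations()` computes the design-adjusted analytic values,
and the test suite compares empirical data against those; the raw-parameter
comparison is exact only for null columns.

Because columns are independent, k-nearest-neighbour imputation on this
synthetic data can do no better than each column's majority genotype
(about 54–57% accuracy for MAFs on [0.05, 0.5]); the imputation tests
assert against that ceiling. On real genotype data with linkage
disequilibrium, kNN imputation performs far better — the simulator is not
evidence either way about real-data imputation quality.

## Evaluation conventions

Across replicate datasets with one planted combination each: **power** is
the fraction of datasets in which the planted combination passed the
threshold; **recall** `TP/(TP+FN)` and **precision** `TP/(TP+FP)` describe
the verification stage, where an FN is a planted combination the search
found but the test rejected (a planted combination the search never found
reduces power but is neither TP nor FN); the **F-measure** is the harmonic
mean of recall and precision, defined as 0 when both are 0. Reports print
percentages rounded half-up to two decimals.

`auc_combination()` scores each sample by the plug-in case fraction of its
joint genotype cell and computes the rank-based (Mann–Whitney, mid-rank)
AUC. It is a resubstitution estimate, hence optimistic; it is intended for
comparing a combination against its sub-combinations on the same data, not
as an absolute accuracy claim.

## Problem sizes used in the tests

The suite validates estimator equivalence against naive nested-loop oracles
on 200 random datasets (n ≤ 200, N ≤ 10), calibrates the null G-test on
5,000 permutation replicates at n = 2,000, runs the planted-model recovery
study at the 100-SNP / 800+800 benchmark design over 20 seeded replicates,
and checks simulator fidelity at n = 50,000. These sizes give stable
acceptance bands (binomial 99% intervals, 4-sigma frequency checks) while
keeping a full run in the order of seconds to a minute.

## Known limitations

* Seeding by marginal SU means *pure, strict* epistasis with no marginal
  signal (the XOR fixture) is found only if a disease locus happens to be
  seeded for other reasons; this mirrors the method's published limitation.
  The fixture exists precisely to document the regime.
* Persisting weights make results depend on the order in which seeds are
  consumed; two datasets differing only by column permutation can yield
  different candidate sets beyond the first.
* The G-test is asymptotic; the gate `xi` protects sparse rows but very
  small samples (df driven to 0) simply return p = 1.
* Binary phenotypes only; genotype coding is strictly {0, 1, 2}.

## A minimal session

```{r}
model <- builtin_models()$threshold2
d <- simulate_dataset(simulation_spec(400, 400, 48, model, rng_seed = 7))
cfg <- search_config(k = 2)
sig <- filter_candidates(run_search(d, cfg), d, cfg)
results_table(sig)
d$provenance$disease_cols
```
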