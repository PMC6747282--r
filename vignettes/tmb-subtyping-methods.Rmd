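---
title: "Methods: TMB subtyping, signature extraction, and margin-controlled enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMB subtyping, signature extraction, and margin-controlled enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the models,
the tunable parameters and their defaults, the numerical choices, what
the synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. TMB and the subtype split

TMB here is the raw per-sample count of somatic mutations from
whole-exome calls (`compute_tmb()`, default `all_somatic`). No
per-megabase normalization is applied: counts are only compared within
one cohort captured with one assay. A `nonsynonymous_only` mode exists
because both conventions are in circulation for WES data; the default
counts everything, and the two modes can disagree materially when the
synonymous fraction varies between samples.

The subtype rule is deliberately simple: TMB-H iff TMB strictly exceeds
a population threshold, by default the arithmetic mean. Strictness
matters only for ties at the threshold; with integer TMB and a
fractional mean, ties cannot occur. The median and the k = 2
optimal-cluster boundary are alternative rules; on strongly right-skewed
cohorts the k = 2 boundary sits higher than the mean (the heavy tail
dominates the within-cluster sum of squares), so the two rules typically
agree on 80–90% of samples rather than all of them.

### Optimal univariate k-means

`ckmeans_1d()` minimizes the total within-cluster sum of squares over
all partitions of the 1-D values into k groups. Optimal 1-D clusters
are intervals of the sorted data, so a dynamic program over the sorted
order attains the global optimum — the property Lloyd-style iteration
cannot guarantee. The implementation is the O(k·n²) DP with O(1)
interval costs from prefix sums; at cohort scale (n ≈ 100, k ≤ 9) this
is instantaneous, and exactness is what the test suite leans on (500
random instances against exhaustive enumeration).

### Choosing k by BIC

The model-selection score treats the hard partition as a Gaussian
mixture: each cluster contributes its normal likelihood at the cluster
MLE mean and variance, weighted by the mixing proportion n_q/n, with
parameter count 3k − 1 and `BIC = 2 lnL − (3k − 1) ln n`, maximized
(ties to the smallest k). Two numerical choices:

* **Variance floor** `var_floor = 1e-9`: a cluster of identical values
  has MLE variance 0 and unbounded density; the floor keeps the score
  finite. Its side effect is that duplicated values make fine
  partitions attractive; with counts spread over hundreds of units this
  does not bite.
* **Skewness**: a Gaussian-mixture criterion legitimately spends extra
  components on a skewed unimodal distribution. On lognormal-like TMB
  the selected raw-scale k is therefore often > 1 even without a true
  second mode; on the log scale a single lognormal mode is selected as
  one cluster. The test suite asserts the log-scale behavior and leaves
  the raw-scale k unasserted, because both are correct answers to
  different questions ("how many Gaussians fit these values" vs "how
  many generative modes are there").

## 2. 96-context classification

Each SNV with a trinucleotide context is mapped to one of 96 categories:
6 pyrimidine substitutions × 16 flanking combinations, in the fixed
COSMIC v2 order (C>A block first; within a block the 5′ base varies
slowest). Purine-reference records are reverse-complemented first, so
the mapping is strand-symmetric — reverse-complementing every input
record leaves the 96-vector unchanged (a property test). Contexts can
come from a reference FASTA (`annotate_context()`, which flags and
excludes records whose reference base contradicts the FASTA) or be
supplied directly in the mutation table, which is how the synthetic
generator avoids needing a genome. Indels never receive a context and
never enter signature analysis, but they do count toward TMB.

## 3. Bayesian NMF with automatic relevance determination

The count matrix V (96 × N) is modeled with a Poisson/generalized-KL
objective, D(V‖WH), rather than a Frobenius one — the entries are small
counts, and the KL objective is the Poisson log-likelihood up to
constants. Each component k carries a relevance hyperparameter λ_k
shared by column w_k and row h_k under an exponential (L1) prior by
default (half-normal L2 available):

* multiplicative updates for W and H, each a majorize–minimize step, so
  the penalized objective is non-increasing every sweep (asserted
  per-iteration in a property test);
* closed-form λ update,
  λ_k = (‖w_k‖₁ + ‖h_k‖₁ + b) / (F + N + a + 1),
  the exact minimizer of the inverse-gamma-regularized objective;
* components whose relative relevance falls below `prune_rel = 1e-3` of
  the current maximum are removed (checked every 10 sweeps after a
  50-sweep settling period, and once more at convergence), so
  K_effective is inferred rather than fixed.

Hyperparameters: `a = 10` (prior sharpness) and
`b = (a − 1)·sqrt(mean(V)/K_max)`, which matches the prior expectation
of a component's scale to the data (E[V] ≈ K·λ² for the L1 prior).
Inference restarts `n_restarts = 10` times from random positive
initializations (all driven by one seed; the caller's RNG state is
restored) and keeps the best final objective. Fits are deterministic
given the seed. The probe that motivated these defaults is retained in
the tests: exact two-block factorizations, rank-1 collapse, and
Poisson-noise recovery of three known profiles all behave at cosine ≥
0.9 with K inferred correctly in ≥ 8 of 10 seeds.

Reported signatures are column-normalized (probability vectors over the
96 categories) with the scale folded into H; components are ordered and
labelled `W1, W2, …` by total attributed mutations. The per-sample
"pattern" rescales H so attributions sum exactly to each sample's
annotatable SNV count, which makes patterns comparable across samples
and conserves counts by construction.

**Catalog.** The packaged `synthetic_signature_catalog()` follows the
COSMIC v2 dialect (category order, `"Signature <n>"` names) but its
profiles are parametric constructions — smoking-like broad C>A,
APOBEC-like C>T/C>G at TpC, MMR-like C>T at CpG, plus distinct
distractors. It exists so the package and its tests are self-contained;
analyses of real cohorts should pass the real downloaded catalog (same
layout) to `cosine_match()`.

## 4. Curveball permutation enrichment

The question "do mutations in gene g track signature activity?" cannot
be answered with a plain two-group test: high-TMB samples mutate more
genes, and the signature's activity also grows with TMB, so every
frequently-mutated gene would appear associated. The permutation null
therefore fixes both margins of the binary gene × sample matrix — each
gene's frequency and each sample's mutated-gene count — and asks
whether the observed alignment of gene g's carriers with the
signature's activity exceeds what those margins already imply.

Randomization is by Curveball trades: pick two genes, pool the samples
unique to either, redeal them at random keeping both genes' totals.
Trades on pairs sharing all or none of their distinct samples are
no-ops that still consume trade budget (standard behavior). The
stationary distribution is uniform over the fixed-margin ensemble,
which the acceptance suite verifies directly on a 4×4 matrix whose
ensemble (5 states) is enumerable.

Defaults, where the underlying method description is silent, are
conventions exposed as arguments: `n_trades = 5 ×` genes per
permutation round, burn-in `10 × n_trades`, and one Markov chain whose
successive states serve all genes simultaneously (`mode = "shared"`) —
the design that makes R = 200,000 rounds tractable. A `per_gene` mode
runs an independent chain per gene at G-fold cost. The statistic is the
one-tailed Wilcoxon rank sum of the pattern in the gene's carriers
(ranks computed once; group size is margin-fixed, so statistics are
comparable across rounds), and the empirical p uses the add-one
estimator (1 + #extreme)/(R + 1): a "fraction more extreme" estimator
can return p = 0, which is improper for finite R.

**Testing family.** The intended input is a driver-gene panel (an
external list, or the built-in frequency rule "mutated in ≥ 5
samples"). Note that margins control for *how many* genes a sample has
mutated, not for every generative mechanism: gene pools whose per-gene
mutation probability saturates with TMB (like the generator's
background pool) are genuinely over-aligned with TMB relative to the
uniform fixed-margin ensemble, and the test will report that. This is a
property of the null, not an artifact; it is why the enrichment family
should be the curated panel, as in the analysis the package follows.

## 5. Association and survival statistics

* `fisher_exact_2x2()`: two-sided p by full hypergeometric enumeration
  (tables no more probable than observed, relative tie tolerance 1e-7);
  degenerate margins give p = 1 by convention. The test suite holds it
  exactly equal to an independent enumeration oracle.
* `wilcoxon_rank_sum()`: exhaustive permutation enumeration when both
  groups have ≤ 10 observations (exact even under ties), otherwise the
  normal approximation with tie-corrected variance and continuity
  correction. Two-sided p is the doubled smaller tail, capped at 1.
* `bh_adjust()`: the standard step-up, q_(i) = min_{j≥i} p_(j)·m/j.
* `km_estimate()` / `logrank_test()`: textbook product-limit estimator
  and two-group log-rank chi-square (1 df) with the hypergeometric
  variance. The survival comparison is log-rank by design decision —
  the near-universal companion of KM curves — since the followed
  analysis never names its test. Age is dichotomized at 65
  (configurable); all 2×2 tests are two-sided; only the enrichment
  module is one-tailed. `"unknown"` clinical levels are excluded
  pairwise per test, never by dropping the sample globally.

## 6. The synthetic cohort: what it emulates, and what not

The generator's defaults state the emulated world: n = 101 tumors; TMB
from a two-component lognormal mixture (low mode near 60, high near
400, high-component weight 33/101, clipped to 7–1126, matching the
followed study's reported range, mean scale, and subtype sizes); three
generating signatures with the smoking-like exposure fraction logistic
in log TMB (slope 1.5); a 5% indel fraction; a 50-gene panel with one
TMB-coupled gene (`RYR2L`, logistic slope +2) and one low-TMB-leaning
gene (`EGFRL`, slope −1.5); smoking and age logistic in log TMB (the
clinical couplings the study found) and weak stage/metastasis leanings
(it found none significant); exponential DFS with hazard ratio 2 for
the high component and uniform censoring over 12–60 months, giving
roughly half the cohort an observed event.

One default was revised during development, before any test was frozen:
the split of the non-smoking exposure remainder between the APOBEC- and
MMR-like processes was first drafted as uniform on (0.35, 0.65), which
leaves no near-pure samples — under that world the factorization is
genuinely non-identifiable (a fixed-K KL-NMF cannot separate the two
profiles either, as any interior blend fits equally well). It is now
Beta(0.5, 0.5): episodic, U-shaped exposure, which is both what real
cohorts show for APOBEC activity and the dispersion that makes NMF
identifiable. This is a modeling correction, not a tolerance change.

What the generator does **not** emulate: real gene-level mutation rates
or hotspot structure (panel probabilities are flat apart from the two
coupled genes; background-pool genes absorb the remaining records with
a saturating TMB relationship, see §4); sequencing or calling error;
subclonal structure; transcriptional-strand asymmetry; and any claim of
matching the followed study's exact numbers — a green test establishes
that the pipeline recovers the *stated* structure (labels ≥ 85%
accurate for the latent component, K = 3 with cosine ≥ 0.9, the coupled
gene first in the panel enrichment, hazard direction recovered), not
that it would reproduce accession-level values.

## 7. Known limitations

* The O(k·n²) DP is fine for cohorts, not for n ≫ 10⁴ values.
* ARD-NMF infers K under its prior; strongly correlated exposures or
  very low counts can merge components regardless of K_max — the
  rank-identifiability limit of NMF, not of this implementation.
* The shared-chain permutation reuses one matrix per round across
  genes, so per-gene p-values are positively dependent within a round;
  BH remains valid under the resulting PRDS-type dependence, but joint
  inference across genes should not treat the draws as independent.
* The Fisher enumeration is exact but O(margin) per table; for margins
  in the tens of thousands a normal approximation would be preferable.
* No Cox regression or multivariate adjustment is provided; the
  survival module compares two groups, as the followed analysis did.
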