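# tmbsubtype

Molecular subtyping of tumor cohorts by **tumor mutation burden (TMB)**,
with the downstream analyses that characterize the resulting subtypes:
mutational signatures, margin-controlled gene enrichment, and
disease-free survival.

The package is aimed at analysts working with whole-exome somatic
mutation calls (a MAF-like table) plus a clinical table. It was built
around the analysis design used for a 101-tumor lung adenocarcinoma
cohort, in which a high-burden subtype (TMB-H) carries a dominant
smoking-related C>A signature and a signature-associated gene (*RYR2*),
and the low-burden subtype has longer disease-free survival — but every
component is generic.

## What it computes

**TMB and subtypes.** For WES data TMB is the per-sample count of
somatic mutations. The cohort is split at the population mean (strict
inequality: TMB-H iff TMB > mean; median and optimal-cluster-boundary
rules are available). As a companion, the 1-D TMB distribution is
clustered by **optimal univariate k-means**: a dynamic program over the
sorted values that provably minimizes the within-cluster sum of squares

&nbsp;&nbsp;&nbsp;&nbsp;WCSS = Σ_q Σ_{i∈C_q} (x_i − x̄_q)²,

with k = 1…9 scored by a Gaussian-mixture BIC
(2·lnL − (3k−1)·ln n, maximized).

**Mutational signatures.** SNVs are classified into the 96
trinucleotide categories (pyrimidine-strand convention, COSMIC v2
ordering) and the 96 × N count matrix V is factorized as V ≈ WH by
**Bayesian NMF with automatic relevance determination**: a Poisson/KL
objective with one relevance hyperparameter per component shared by
W's column and H's row, updated in closed form; components whose
relevance collapses are pruned, so the number of signatures K is
inferred. Extracted signatures are matched to a reference catalog by
cosine similarity, and each sample's mutations are attributed to
signatures (the "pattern", scaled so attributions sum to the sample's
SNV count).

**Margin-controlled enrichment.** Testing whether mutations in a gene
track a signature's activity is confounded by TMB: high-burden samples
mutate more genes. The package implements the permutation test that
fixes both margins of the binary gene × sample matrix using the
**Curveball algorithm** (random trades of samples between gene pairs,
uniform over the fixed-margin ensemble). The observed one-tailed
Wilcoxon rank-sum statistic is compared against R randomized matrices,
with the add-one empirical p-value p = (1 + #{T_r ≥ T_obs})/(R + 1)
and BH adjustment across genes.

**Association and survival.** Fisher exact tests (full hypergeometric
enumeration) of gene × subtype and clinical-feature × subtype tables
with Benjamini–Hochberg adjustment; Wilcoxon rank-sum comparisons of
TMB; Kaplan–Meier product-limit curves and the two-group log-rank test
for disease-free survival.

**Synthetic cohorts.** `generate_cohort()` draws a full cohort —
bimodal lognormal TMB, three generating signatures with a smoking-like
exposure rising in TMB, a TMB-coupled gene (`RYR2L`) and a low-TMB
gene (`EGFRL`), TMB-correlated smoking/age, exponential DFS with a
subtype hazard ratio — and returns every latent draw as ground truth.
`generate_null_cohort()` severs all couplings for calibration suites.
The bundled reference catalog (`synthetic_signature_catalog()`) is a
**constructed stand-in** in the COSMIC v2 dialect, not the published
COSMIC profiles; supply a real catalog for real cohorts.

## Worked example

```r
library(tmbsubtype)
sim <- generate_cohort(simulation_params(), seed = 1)
tmb <- compute_tmb(sim$cohort)
(st <- assign_subtypes(tmb))
#> Subtypes (rule = mean , threshold = 187.2376 ):
#> TMB-L TMB-H
#>    64    37
```

64 samples fall at or below the mean TMB (187.2), 37 above — the
TMB-L / TMB-H split.

```r
V   <- classify_96(sim$cohort$mutations, sim$cohort$sample_ids)
fit <- bayesian_nmf(V, K_max = 12, seed = 1, n_restarts = 5)
cosine_match(fit, synthetic_signature_catalog())
#>   signature  best_match    cosine
#> 1        W1 Signature 4 0.9989137
#> 2        W2 Signature 2 0.9980243
#> 3        W3 Signature 6 0.9993688
```

Starting from 12 candidate components, ARD pruning leaves
K_effective = 3; the dominant signature (W1, most attributed
mutations) is the smoking-like C>A profile. Its per-sample pattern
separates the subtypes:

```r
pat <- signature_pattern(fit)
compare_pattern_by_subtype(pat, st, "W1")
#> signature_pattern_by_subtype: statistic = 3071, p = < 2.22e-16
```

Enrichment of panel genes against the W1 pattern, controlling both
margins (2,000 permutations here; use 200,000 for a real analysis):

```r
mm    <- build_mutation_matrix(sim$cohort, nonsynonymous_only = TRUE)
panel <- intersect(default_gene_panel()$gene, rownames(mm))
enr   <- enrichment_test(pat["W1", ], mm[panel, ], R = 2000, seed = 1)
head(enr[order(enr$p), c("gene", "n_mutant", "T_observed", "p", "q")], 3)
#>   gene n_mutant T_observed            p          q
#>  RYR2L       15     1182.0 0.0004997501 0.02498751
#>    G50       24     1549.5 0.0024987506 0.06246877
#>    G21       23     1420.0 0.0094952524 0.15825421
```

The TMB-coupled gene `RYR2L` ranks first (its p is the add-one floor
at R = 2000). It is also the most subtype-enriched gene by Fisher test
(q = 7.1e-3) and carries significantly higher TMB
(`tmb_by_mutation(tmb, mm, "RYR2L")`: p = 5.8e-5); smoking associates
with TMB-H (Fisher p = 1.8e-8). Survival:

```r
cl <- sim$cohort$clinical
logrank_test(cl$dfs_time, cl$dfs_event, st$labels)
#> logrank: statistic = 2.000167, p = 0.15728
```

On this seed the hazard effect (generator HR = 2) does not reach
significance — with ~100 subjects and ~45% censoring the log-rank test
has only moderate power; the power properties are exercised at n = 200
in the acceptance suite.

A one-shot wrapper, `run_pipeline(cohort, out_dir, seed)`, writes all
of the above as TSVs, and `exec/tmb-subtype` exposes the same stages as
a command line (`simulate`, `cluster`, `signatures`, `enrich`,
`associate`, `survival`, `pipeline`).

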