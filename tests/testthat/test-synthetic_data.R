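test_that("generated cohorts conserve counts and are deterministic", {
  sim <- generate_cohort(simulation_params(n_samples = 25), seed = 19)
  gt <- sim$ground_truth$samples
  # per-sample record counts equal the drawn TMB
  counts <- table(factor(sim$cohort$mutations$sample_id,
                         levels = sim$cohort$sample_ids))
  expect_equal(unname(c(counts)), gt$tmb)
  # SNV/indel split and context presence
  mut <- sim$cohort$mutations
  expect_equal(sum(is.na(mut$context)), sum(gt$n_indel))
  # cross-module: context-matrix column sums equal generated SNV counts
  ctx <- classify_96(mut, sim$cohort$sample_ids)
  expect_equal(unname(colSums(ctx)), gt$n_snv)
  expect_identical(ctx, sim$ground_truth$category_counts)
  # determinism: same seed, byte-identical files
  sim2 <- generate_cohort(simulation_params(n_samples = 25), seed = 19)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_cohort(sim, d1); f2 <- write_cohort(sim2, d2)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("generated tables pass validation and TMB stays in range", {
  sim <- generate_cohort(simulation_params(), seed = 23)
  expect_silent(validate_mutations(sim$cohort$mutations))
  expect_silent(validate_clinical(sim$cohort$clinical))
  tmb <- compute_tmb(sim$cohort)
  expect_true(all(tmb >= 7 & tmb <= 1126))
  expect_gt(mean(tmb[sim$ground_truth$samples$component == 1]),
            mean(tmb[sim$ground_truth$samples$component == 0]))
})

test_that("single-component world has no latent cluster structure", {
  # with the high-TMB component switched off the cohort is one lognormal
  # mode; on the log scale (where that mode is Gaussian) BIC should find a
  # single cluster.  On the raw scale the skewness itself legitimately
  # absorbs extra Gaussian components, so the raw-scale k is not asserted.
  ks <- vapply(1:5, function(s) {
    sim <- generate_cohort(simulation_params(p_high = 0), seed = s)
    select_k_bic(log(compute_tmb(sim$cohort)))$k_selected
  }, integer(1))
  expect_gte(sum(ks == 1L), 4L)
})

test_that("subtype labels recover the latent mixture component", {
  acc <- vapply(1:5, function(s) {
    sim <- generate_cohort(simulation_params(), seed = s)
    st <- assign_subtypes(compute_tmb(sim$cohort))
    mean((st$labels == "TMB-H") ==
           (sim$ground_truth$samples$component == 1))
  }, numeric(1))
  expect_true(all(acc >= 0.85))
})

test_that("smoking-like attribution is higher in the high-TMB component", {
  sim <- generate_cohort(simulation_params(), seed = 27)
  gt <- sim$ground_truth$samples
  att <- gt$smoking_like * gt$n_snv
  res <- wilcoxon_rank_sum(att[gt$component == 1],
                           att[gt$component == 0])
  expect_lt(res$p, 0.01)
})

test_that("null cohort severs the couplings", {
  simn <- generate_null_cohort(simulation_params(), seed = 31)
  gt <- simn$ground_truth$samples
  tmb <- compute_tmb(simn$cohort)
  # RYR2L no longer tracks TMB
  mm <- build_mutation_matrix(simn$cohort, nonsynonymous_only = TRUE)
  expect_gt(tmb_by_mutation(tmb, mm, "RYR2L")$p, 0.05)
  # equal hazards: log-rank on the latent component is null
  cl <- simn$cohort$clinical
  comp <- gt$component[match(cl$sample_id, gt$sample_id)]
  if (length(unique(comp)) == 2) {
    res <- logrank_test(cl$dfs_time, cl$dfs_event, comp)
    expect_gt(res$p, 0.01)
  }
  # smoking independent of TMB
  sm <- cl$smoking[match(names(tmb), cl$sample_id)]
  expect_gt(wilcoxon_rank_sum(tmb[sm == "smoker"],
                              tmb[sm == "non_smoker"])$p, 0.01)
})

test_that("infeasible parameters are rejected", {
  expect_error(simulation_params(p_high = 1.5))
  panel <- default_gene_panel(); panel$base_prob[1] <- 1.2
  expect_error(simulation_params(gene_panel = panel))
})
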