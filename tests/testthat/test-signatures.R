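test_that("classify_96 maps strands and conserves counts", {
  mut <- data.frame(
    sample_id = c("A", "A"), gene = "G", chrom = "chr1", pos = 1:2,
    ref = c("G", "C"), alt = c("T", "T"),
    variant_class = "missense", context = c("AGC", "ACG"),
    stringsAsFactors = FALSE)
  m <- classify_96(mut)
  # G>T in AGC reverse-complements to C>A in GCT
  expect_equal(m["G[C>A]T", "A"], 1L)
  # C>T in ACG is already pyrimidine
  expect_equal(m["A[C>T]G", "A"], 1L)
  expect_equal(sum(m), 2L)
  # SNV without context is skipped with a message
  mut$context[2] <- NA
  expect_message(m2 <- classify_96(mut), "skipped")
  expect_equal(sum(m2), 1L)
})

test_that("classify_96 is invariant under reverse-complement re-reporting", {
  sim <- generate_cohort(simulation_params(n_samples = 10), seed = 4)
  mut <- sim$cohort$mutations
  m1 <- classify_96(mut, sim$cohort$sample_ids)
  snv <- tmbsubtype:::is_snv(mut) & !is.na(mut$context)
  mut$context[snv] <- tmbsubtype:::revcomp(mut$context[snv])
  mut$ref[snv] <- chartr("ACGT", "TGCA", mut$ref[snv])
  mut$alt[snv] <- chartr("ACGT", "TGCA", mut$alt[snv])
  m2 <- classify_96(mut, sim$cohort$sample_ids)
  expect_identical(m1, m2)
  # conservation: totals equal annotatable SNV counts
  expect_equal(unname(colSums(m1)), sim$ground_truth$samples$n_snv)
})

test_that("category recovery matches the generating multinomial", {
  set.seed(21)
  p <- as.vector(default_signature_profiles()[, 1])
  cats <- context_categories()
  draw <- sample(96, 1000, replace = TRUE, prob = p)
  tab <- tmbsubtype:::category_table()
  flip <- stats::runif(1000) < 0.5
  al <- tmbsubtype:::category_to_context(draw, flip)
  mut <- data.frame(sample_id = "A", gene = "G", chrom = "chr1",
                    pos = 1:1000, ref = al$ref, alt = al$alt,
                    variant_class = "missense", context = al$context,
                    stringsAsFactors = FALSE)
  m <- classify_96(mut)
  expect_identical(as.integer(m[, "A"]), tabulate(draw, 96))
})

test_that("bayesian_nmf recovers an exact two-block factorization", {
  W0 <- cbind(c(rep(1 / 48, 48), rep(0, 48)),
              c(rep(0, 48), rep(1 / 48, 48)))
  set.seed(5)
  H0 <- matrix(stats::rgamma(2 * 30, shape = 2, scale = 60), 2, 30)
  V <- W0 %*% H0
  rownames(V) <- context_categories()
  fit <- bayesian_nmf(V, K_max = 8, seed = 2, n_restarts = 4)
  expect_equal(fit$K_effective, 2L)
  cm <- cosine_match(W0, fit$W)
  expect_true(all(cm$cosine >= 0.99))
})

test_that("rank-1 data collapse to a single component", {
  v <- default_signature_profiles()[, 2] * 100
  V <- matrix(rep(v, 10), ncol = 10,
              dimnames = list(context_categories(), paste0("s", 1:10)))
  fit <- bayesian_nmf(V, K_max = 6, seed = 3, n_restarts = 3)
  expect_equal(fit$K_effective, 1L)
})

test_that("nmf objective is non-increasing and W columns are normalized", {
  sm <- simulate_context_matrix(default_signature_profiles(),
                                n_samples = 20, seed = 8)
  fit <- bayesian_nmf(sm$V, K_max = 6, seed = 4, n_restarts = 1,
                      prune_rel = 0, trace = TRUE)
  tr <- fit$obj_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_equal(unname(colSums(fit$W)), rep(1, fit$K_effective),
               tolerance = 1e-9)
  expect_error(bayesian_nmf(matrix(0, 96, 3)), "all zero")
  expect_error(bayesian_nmf(matrix(1, 96, 3), K_max = 0), "K_max")
})

test_that("three-profile Poisson simulation is recovered with names", {
  P <- default_signature_profiles()
  sm <- simulate_context_matrix(P, n_samples = 60, mean_total = 200,
                                seed = 31)
  fit <- bayesian_nmf(sm$V, K_max = 12, seed = 31, n_restarts = 4)
  expect_equal(fit$K_effective, 3L)
  cm <- cosine_match(P, fit$W)  # truth against recovered
  expect_true(all(cm$cosine >= 0.90))
  # and the catalog match labels the recovered signatures correctly
  cat_match <- cosine_match(fit, synthetic_signature_catalog())
  expect_setequal(cat_match$best_match,
                  c("Signature 4", "Signature 2", "Signature 6"))
})

test_that("cosine_match identities and error cases", {
  cat96 <- synthetic_signature_catalog()
  cm <- cosine_match(cat96[, "Signature 4", drop = FALSE], cat96)
  expect_equal(cm$best_match, "Signature 4")
  expect_equal(cm$cosine, 1, tolerance = 1e-12)
  expect_error(cosine_match(matrix(0, 96, 1), cat96), "zero-norm")
  expect_error(cosine_match(matrix(1, 10, 1), cat96), "category orders")
})

test_that("signature_pattern conserves per-sample totals", {
  sm <- simulate_context_matrix(default_signature_profiles(),
                                n_samples = 40, seed = 12)
  fit <- bayesian_nmf(sm$V, K_max = 8, seed = 12, n_restarts = 3)
  pat <- signature_pattern(fit)
  expect_equal(unname(colSums(pat)), unname(colSums(sm$V)),
               tolerance = 1e-9)
  expect_true(all(pat >= 0))
  # zero-mutation sample gets zero attribution
  V2 <- sm$V; V2[, 1] <- 0
  fit2 <- bayesian_nmf(V2, K_max = 6, seed = 1, n_restarts = 2)
  expect_equal(sum(signature_pattern(fit2)[, 1]), 0)
  # single-signature model: attribution equals each sample's total
  v <- default_signature_profiles()[, 1] * 50
  V1 <- outer(v, 1:5)
  dimnames(V1) <- list(context_categories(), paste0("s", 1:5))
  fit1 <- bayesian_nmf(V1, K_max = 4, seed = 2, n_restarts = 2)
  expect_equal(unname(signature_pattern(fit1)[1, ]), unname(colSums(V1)),
               tolerance = 1e-6)
})

test_that("attributed counts track the generating exposures", {
  P <- default_signature_profiles()
  sm <- simulate_context_matrix(P, n_samples = 60, mean_total = 200,
                                seed = 77)
  fit <- bayesian_nmf(sm$V, K_max = 10, seed = 77, n_restarts = 3)
  expect_equal(fit$K_effective, 3L)
  pat <- signature_pattern(fit)
  # align recovered components with truth, then RMSE on attributed counts
  cm <- cosine_match(P, fit$W)
  truth <- t(sm$exposures) * rep(colSums(sm$V), each = 3)
  err <- vapply(1:3, function(k) {
    rec <- pat[cm$best_match[k], ]
    sqrt(mean((rec - truth[k, ])^2))
  }, numeric(1))
  expect_true(all(err / mean(colSums(sm$V)) < 0.15))
})

test_that("pattern comparison between subtypes behaves at the extremes", {
  pat <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 1)
  labels <- c("TMB-L", "TMB-L", "TMB-L", "TMB-H", "TMB-H", "TMB-H")
  res <- compare_pattern_by_subtype(pat, labels, 1)
  # exact enumeration: most extreme of C(6,3)=20 orderings, two-sided
  expect_equal(res$p, 0.1)
  one_sided <- wilcoxon_rank_sum(c(10, 20, 30), c(1, 2, 3), "greater")
  expect_equal(one_sided$p, 0.05)
  # identical groups: p = 1, statistic at its null mean
  same <- compare_pattern_by_subtype(matrix(rep(1:3, 2), nrow = 1),
                                     labels, 1)
  expect_equal(same$p, 1)
  expect_error(compare_pattern_by_subtype(pat, rep("TMB-H", 6), 1),
               "empty")
})

test_that("subtype-shifted signature is detected in the synthetic cohort", {
  sim <- generate_cohort(simulation_params(), seed = 13)
  gt <- sim$ground_truth$samples
  pat <- rbind(smoking = gt$smoking_like * gt$n_snv)
  st <- assign_subtypes(compute_tmb(sim$cohort))
  res <- compare_pattern_by_subtype(pat, st, 1)
  expect_lt(res$p, 0.01)
})
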