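test_that("fisher exact matches hand enumeration and the oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # 2 / C(20, 10): only the two perfectly separated tables qualify
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p,
               2 / choose(20, 10), tolerance = 1e-12)
  # degenerate margin
  expect_message(res <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "degenerate")
  expect_equal(res$p, 1)
})

test_that("fisher exact agrees with stats::fisher.test across tables", {
  # exhaustive over all tables with total <= 12, plus random tables with
  # margins up to 30 (the full margin-<=30 grid is enumerated sparsely to
  # stay in budget; agreement is exact, not approximate)
  for (n in 0:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tab <- matrix(c(a, b, cc, n - a - b - cc), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab)$p,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
  set.seed(17)
  for (rep in 1:300) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)  # margins <= 30
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("bh_adjust matches the step-up oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(5)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-order
  }
})

test_that("gene-subtype association flags the enriched gene", {
  # extreme table: gene mutated only in TMB-H
  m <- rbind(hot = c(rep(1L, 10), rep(0L, 10)),
             flat = rep(c(1L, 0L), 10))
  colnames(m) <- paste0("s", 1:20)
  labels <- rep(c("TMB-H", "TMB-L"), each = 10)
  res <- gene_subtype_association(m, labels)
  expect_lt(res$p[res$gene == "hot"], res$p[res$gene == "flat"])
  # identical tables give equal q (BH ties)
  m2 <- rbind(g1 = m["hot", ], g2 = m["hot", ])
  res2 <- gene_subtype_association(m2, labels)
  expect_equal(res2$q[1], res2$q[2])
  # synthetic cohort: the TMB-coupled gene reaches q < 0.05
  sim <- generate_cohort(simulation_params(), seed = 6)
  mm <- build_mutation_matrix(sim$cohort, nonsynonymous_only = TRUE)
  panel <- intersect(default_gene_panel()$gene, rownames(mm))
  st <- assign_subtypes(compute_tmb(sim$cohort))
  ga <- gene_subtype_association(mm, st, genes = panel)
  expect_lt(ga$q[ga$gene == "RYR2L"], 0.05)
})

test_that("tmb_by_mutation detects the TMB-coupled gene", {
  sim <- generate_cohort(simulation_params(), seed = 9)
  mm <- build_mutation_matrix(sim$cohort, nonsynonymous_only = TRUE)
  tmb <- compute_tmb(sim$cohort)
  expect_lt(tmb_by_mutation(tmb, mm, "RYR2L")$p, 0.01)
  m1 <- matrix(1L, 1, 4, dimnames = list("gX", paste0("s", 1:4)))
  expect_error(tmb_by_mutation(c(1, 2, 3, 4), m1, "gX"), "gX")
})

test_that("clinical association couples smoking with the subtype", {
  sim <- generate_cohort(simulation_params(), seed = 10)
  tmb <- compute_tmb(sim$cohort)
  st <- assign_subtypes(tmb)
  res <- clinical_association(sim$cohort$clinical, st, "smoking",
                              tmb = tmb)
  expect_lt(res$fisher$p, 0.05)
  expect_lt(res$tmb_wilcoxon$p, 0.05)
  # extreme case: all smokers TMB-H, all non-smokers TMB-L
  cl <- data.frame(sample_id = paste0("s", 1:20), age = 50,
                   smoking = rep(c("smoker", "non_smoker"), each = 10),
                   stage = "early", metastasis = "no",
                   dfs_time = 1, dfs_event = FALSE,
                   stringsAsFactors = FALSE)
  st2 <- list(labels = stats::setNames(
    factor(rep(c("TMB-H", "TMB-L"), each = 10),
           levels = c("TMB-L", "TMB-H")), cl$sample_id))
  class(st2) <- "subtype_assignment"
  res2 <- clinical_association(cl, st2, "smoking")
  expect_equal(res2$fisher$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("clinical association p is uniform under the permuted null", {
  sim <- generate_null_cohort(simulation_params(), seed = 15)
  tmb <- compute_tmb(sim$cohort)
  st <- assign_subtypes(tmb)
  ps <- replicate(60, {
    cl <- sim$cohort$clinical
    cl$smoking <- sample(cl$smoking)
    suppressMessages(
      clinical_association(cl, st, "smoking")$fisher$p)
  })
  # discrete conservative p: check no excess of small values
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("km_estimate matches closed forms and the survfit oracle", {
  # 2 subjects: event at 1, censored at 2
  cv <- km_estimate(c(1, 2), c(TRUE, FALSE))
  expect_equal(km_surv_at(cv, "all", c(1, 2)), c(0.5, 0.5))
  # no events: S identically 1
  cv0 <- km_estimate(c(3, 5), c(FALSE, FALSE))
  expect_equal(km_surv_at(cv0, "all", c(0, 10)), c(1, 1))
  # S in [0,1], non-increasing; equals survfit on random data
  skip_if_not_installed("survival")
  set.seed(3)
  tt <- round(stats::rexp(40, 0.1), 2)
  ev <- stats::runif(40) < 0.7
  cv <- km_estimate(tt, ev)
  expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  expect_true(all(diff(cv$surv) <= 1e-12))
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km_surv_at(cv, "all", sf$time), sf$surv,
               tolerance = 1e-10)
  # with no censoring KM equals the empirical survival function
  cv2 <- km_estimate(tt, rep(TRUE, 40))
  ut <- sort(unique(tt))
  expect_equal(km_surv_at(cv2, "all", ut), 1 - stats::ecdf(tt)(ut))
})

test_that("km median recovers the exponential hazard", {
  set.seed(44)
  rate <- 1 / 30
  tt <- stats::rexp(200, rate)
  cv <- km_estimate(tt, rep(TRUE, 200))
  med <- cv$time[min(which(cv$surv <= 0.5))]
  expect_lt(abs(med - log(2) / rate) / (log(2) / rate), 0.15)
})

test_that("logrank matches hand computation, the oracle, and symmetry", {
  # group A's events all precede group B's: strongly significant
  tt <- c(1:5, 11:15)
  ev <- rep(TRUE, 10)
  gr <- rep(c("A", "B"), each = 5)
  res <- logrank_test(tt, ev, gr)
  expect_lt(res$p, 0.01)
  # label-swap invariance
  res2 <- logrank_test(tt, ev, rev(gr))
  expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  # identical groups: statistic 0, p 1
  same <- logrank_test(rep(1:3, 2), rep(TRUE, 6), rep(c("A", "B"), 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  # no events at all
  expect_message(ne <- logrank_test(1:4, rep(FALSE, 4),
                                    rep(c("A", "B"), 2)),
                 "no events")
  expect_equal(ne$p, 1)
  skip_if_not_installed("survival")
  set.seed(6)
  tt <- round(stats::rexp(60, 0.05), 1)
  ev <- stats::runif(60) < 0.8
  gr <- rep(c("A", "B"), 30)
  mine <- logrank_test(tt, ev, gr)
  orac <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  expect_equal(mine$statistic, orac$chisq, tolerance = 1e-8)
  expect_equal(mine$p, 1 - stats::pchisq(orac$chisq, 1),
               tolerance = 1e-8)
})

test_that("wilcoxon exact branch matches wilcox.test and handles ties", {
  set.seed(71)
  for (rep in 1:15) {
    x <- stats::rnorm(sample(3:8, 1))
    y <- stats::rnorm(sample(3:8, 1))
    mine <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  # large-sample branch with heavy ties vs the tie-corrected oracle
  x <- sample(1:4, 30, replace = TRUE)
  y <- sample(2:5, 35, replace = TRUE)
  mine <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
})
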