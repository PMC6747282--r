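# Subtype association statistics (Fisher exact, Wilcoxon, BH) and
# disease-free survival analysis (Kaplan-Meier, log-rank).

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by full hypergeometric enumeration: with margins fixed, the
#' p-value is the sum of probabilities of all tables no more probable than
#' the observed one (relative tolerance 1e-7 for probability ties).  The
#' sample odds ratio is reported as the statistic.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return A [test_result()]; for an empty margin, p = 1 by convention with
#'   a message.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  storage.mode(tab) <- "integer"
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    message("degenerate 2x2 table (empty margin): p = 1 by convention")
    return(test_result("fisher_exact", statistic = or, p = 1, table = tab))
  }
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result("fisher_exact", statistic = or, p = min(p, 1), table = tab)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p-values to false-discovery-rate q-values:
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1; the adjustment
#' is monotone in the p-value order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / (m:1)))
  q[order(ord)]
}

#' Gene-by-subtype association with BH adjustment
#'
#' For each gene, builds the 2x2 table of mutation status against subtype
#' and applies [fisher_exact_2x2()]; q-values are BH-adjusted across the
#' supplied gene list (the list defines the testing family).
#'
#' @param m Binary gene x sample matrix.
#' @param subtypes [assign_subtypes()] result or label vector aligned with
#'   the matrix columns.
#' @param genes Genes to test (must be matrix rows); default all rows.
#' @return `data.frame`: `gene`, `n_mutant_H`, `n_mutant_L`, `odds_ratio`,
#'   `p`, `q`, sorted as supplied.
#' @export
gene_subtype_association <- function(m, subtypes, genes = rownames(m)) {
  labels <- if (inherits(subtypes, "subtype_assignment"))
    subtypes$labels else subtypes
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("subtype labels do not align with matrix columns")
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  is_h <- labels == "TMB-H"
  res <- lapply(genes, function(g) {
    mut <- m[g, ] == 1L
    tab <- matrix(c(sum(mut & is_h), sum(mut & !is_h),
                    sum(!mut & is_h), sum(!mut & !is_h)),
                  nrow = 2, byrow = TRUE)
    ft <- suppressMessages(fisher_exact_2x2(tab))
    c(nH = tab[1, 1], nL = tab[1, 2], or = ft$statistic, p = ft$p)
  })
  res <- do.call(rbind, res)
  data.frame(gene = genes, n_mutant_H = res[, "nH"],
             n_mutant_L = res[, "nL"], odds_ratio = res[, "or"],
             p = res[, "p"], q = bh_adjust(res[, "p"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare TMB between mutant and wild-type carriers of a gene
#'
#' Two-sided Wilcoxon rank-sum of per-sample TMB between samples with and
#' without a mutation in `gene`.
#'
#' @param tmb Named TMB vector ([compute_tmb()]).
#' @param m Binary gene x sample matrix (columns aligned with `tmb`).
#' @param gene Gene to test.
#' @return A [test_result()].
#' @export
tmb_by_mutation <- function(tmb, m, gene) {
  if (!gene %in% rownames(m)) stop("gene not in matrix: ", gene)
  mut <- m[gene, ] == 1L
  if (!any(mut) || all(mut))
    stop("gene ", gene, " is mutated in no or all samples")
  res <- wilcoxon_rank_sum(tmb[mut], tmb[!mut])
  res$test_name <- "tmb_by_mutation"
  res
}

#' Clinical feature association with the TMB subtype
#'
#' Builds the 2x2 table of a dichotomous clinical feature against the
#' TMB-H/TMB-L subtype and applies the Fisher exact test.  `"unknown"`
#' values are excluded pairwise (only from this test, not from the
#' cohort).  When a TMB vector is supplied, a two-sided Wilcoxon rank-sum
#' of raw TMB across the two feature levels is run as well.
#'
#' @param clinical Clinical `data.frame` ([read_clinical()]).
#' @param subtypes [assign_subtypes()] result with labels named by sample.
#' @param feature One of `"age_group"`, `"smoking"`, `"stage"`,
#'   `"metastasis"`.
#' @param tmb Optional named TMB vector for the rank-sum companion test.
#' @return List with elements `fisher` (a [test_result()], levels as the
#'   table rows) and `tmb_wilcoxon` (a [test_result()] or `NULL`).
#' @export
clinical_association <- function(clinical, subtypes,
                                 feature = c("age_group", "smoking",
                                             "stage", "metastasis"),
                                 tmb = NULL) {
  feature <- match.arg(feature)
  labels <- subtypes$labels
  lv <- switch(feature,
               age_group = c("at_least65", "under65"),
               smoking = c("smoker", "non_smoker"),
               stage = c("late", "early"),
               metastasis = c("yes", "no"))
  f <- clinical[[feature]][match(names(labels), clinical$sample_id)]
  keep <- !is.na(f) & f != "unknown"
  f <- factor(f[keep], levels = lv)
  s <- factor(as.character(labels)[keep], levels = c("TMB-H", "TMB-L"))
  tab <- table(f, s)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    message("degenerate ", feature, " x subtype table after exclusions")
  fisher <- suppressMessages(fisher_exact_2x2(tab))
  fisher$test_name <- paste0("fisher_", feature, "_by_subtype")
  tw <- NULL
  if (!is.null(tmb)) {
    tv <- tmb[names(labels)][keep]
    g1 <- tv[f == lv[1]]; g2 <- tv[f == lv[2]]
    if (length(g1) && length(g2)) {
      tw <- wilcoxon_rank_sum(g1, g2)
      tw$test_name <- paste0("tmb_by_", feature)
    }
  }
  list(fisher = fisher, tmb_wilcoxon = tw)
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function per group: at each distinct event time
#' the survival probability is multiplied by (1 - d/n), where d is the
#' number of events and n the number at risk; censored subjects leave the
#' risk set after their censoring time without a step.
#'
#' @param times Nonnegative follow-up times.
#' @param events Logical: `TRUE` if the event was observed, `FALSE` if
#'   censored.
#' @param groups Group label per subject (single group if omitted).
#' @return `data.frame` of class `"km_curve"` with one row per distinct
#'   event time per group: `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0))
  events <- as.logical(events)
  if (is.null(groups)) groups <- rep("all", length(times))
  out <- lapply(split(seq_along(times), groups), function(idx) {
    if (!length(idx)) stop("empty group")
    tt <- times[idx]; ev <- events[idx]
    et <- sort(unique(tt[ev]))
    s <- 1
    rows <- lapply(et, function(t0) {
      n_risk <- sum(tt >= t0)
      d <- sum(ev & tt == t0)
      s <<- s * (1 - d / n_risk)
      data.frame(time = t0, n_risk = n_risk, n_event = d, surv = s)
    })
    do.call(rbind, c(list(data.frame(time = 0, n_risk = length(idx),
                                     n_event = 0L, surv = 1)), rows))
  })
  res <- do.call(rbind, Map(function(g, df)
    cbind(group = g, df, stringsAsFactors = FALSE),
    names(out), out))
  rownames(res) <- NULL
  class(res) <- c("km_curve", "data.frame")
  res
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A [km_estimate()] result.
#' @param group Group label.
#' @param at Times at which to read off S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, group, at) {
  cg <- curve[curve$group == group, ]
  vapply(at, function(t0) {
    below <- cg$time <= t0
    if (!any(below)) 1 else cg$surv[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom: at each pooled
#' distinct event time, the observed events in group 1 are compared with
#' the expectation under the hypergeometric null given the risk sets;
#' `X^2 = (O - E)^2 / V` with the summed hypergeometric variance.
#'
#' @param times Nonnegative follow-up times.
#' @param events Logical event indicators.
#' @param groups Exactly two non-empty groups.
#' @return A [test_result()] (statistic = chi-square, two-sided p); with no
#'   events at all, p = 1 with a message.
#' @export
logrank_test <- function(times, events, groups) {
  events <- as.logical(events)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("a group is empty")
  et <- sort(unique(times[events]))
  if (!length(et)) {
    message("no events observed: p = 1")
    return(test_result("logrank", statistic = 0, p = 1,
                       group_sizes = as.integer(table(g))))
  }
  O <- 0; E <- 0; V <- 0
  g1 <- g == levels(g)[1]
  for (t0 in et) {
    at_risk <- times >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(events & times == t0)
    d1 <- sum(events & times == t0 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    message("degenerate risk sets: p = 1")
    return(test_result("logrank", statistic = 0, p = 1,
                       group_sizes = as.integer(table(g))))
  }
  chisq <- (O - E)^2 / V
  test_result("logrank", statistic = chisq,
              p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
              group_sizes = as.integer(table(g)))
}
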