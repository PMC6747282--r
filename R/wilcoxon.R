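# Wilcoxon rank-sum test used by the signature, enrichment, and association
# modules.  The statistic is the rank sum of the first group over the pooled
# ranking (midranks for ties).  p-values by exhaustive subset enumeration
# when both groups are small, otherwise by the normal approximation with the
# tie-corrected variance.

#' Wilcoxon rank-sum test
#'
#' Two-sample rank test on the pooled midranks.  When both groups have at
#' most `exact_max` observations the permutation distribution of the rank
#' sum is enumerated exhaustively (exact even under ties); otherwise the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.  Two-sided p-values are the doubled smaller tail,
#' capped at 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @param exact_max Largest group size for which exhaustive enumeration is
#'   used (default 10).
#' @return A [test_result()] with `statistic` = rank sum of `x` and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              exact_max = 10) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  T_obs <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (nx <= exact_max && ny <= exact_max) {
    subsets <- utils::combn(n, nx)
    sums <- colSums(matrix(r[subsets], nrow = nx))
    p_ge <- mean(sums >= T_obs)
    p_le <- mean(sums <= T_obs)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p_ge <- stats::pnorm((T_obs - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((T_obs - mu + 0.5) / sigma)
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  test_result("wilcoxon_rank_sum", statistic = T_obs, p = p,
              group_sizes = c(nx, ny))
}

#' Construct a generic statistical test result
#'
#' Lightweight container shared by the Fisher, Wilcoxon, log-rank, and
#' permutation tests: a statistic, a p-value, and optional BH q-value, 2x2
#' table, and group sizes.
#'
#' @param test_name Character label of the test.
#' @param statistic Test statistic.
#' @param p p-value in \[0, 1\].
#' @param q Optional BH-adjusted value.
#' @param table Optional 2x2 integer table.
#' @param group_sizes Optional integer group sizes.
#' @return List of class `"test_result"`.
#' @export
test_result <- function(test_name, statistic, p, q = NA_real_,
                        table = NULL, group_sizes = NULL) {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p = min(unname(p), 1), q = q, table = table,
                 group_sizes = group_sizes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p), sep = "")
  if (!is.na(x$q)) cat(", q =", format.pval(x$q))
  cat("\n")
  invisible(x)
}
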