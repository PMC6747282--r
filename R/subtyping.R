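# TMB computation, optimal 1-D k-means by dynamic programming, BIC model
# selection, and TMB-H / TMB-L subtype assignment.

#' Compute per-sample tumor mutation burden
#'
#' For whole-exome data TMB is the raw count of somatic mutations per
#' sample.  `counting_mode = "all_somatic"` counts every record (the
#' default); `"nonsynonymous_only"` excludes synonymous records.  Samples on
#' the cohort roster with no mutations get TMB 0.
#'
#' @param cohort A [cohort_table()].
#' @param counting_mode `"all_somatic"` or `"nonsynonymous_only"`.
#' @return Named integer vector of per-sample counts, in roster order, with
#'   attribute `counting_mode`.
#' @export
compute_tmb <- function(cohort,
                        counting_mode = c("all_somatic",
                                          "nonsynonymous_only")) {
  stopifnot(inherits(cohort, "cohort_table"))
  counting_mode <- match.arg(counting_mode)
  mut <- cohort$mutations
  if (counting_mode == "nonsynonymous_only")
    mut <- mut[mut$variant_class != "synonymous", , drop = FALSE]
  counts <- table(factor(mut$sample_id, levels = cohort$sample_ids))
  tmb <- as.integer(counts)
  names(tmb) <- cohort$sample_ids
  attr(tmb, "counting_mode") <- counting_mode
  tmb
}

# O(1) within-cluster sum of squares for sorted values x[i..j], via prefix
# sums: ss = sum(x^2) - sum(x)^2 / n.
interval_wcss <- function(cs, cs2, i, j) {
  s <- cs[j + 1L] - cs[i]
  s2 <- cs2[j + 1L] - cs2[i]
  max(s2 - s * s / (j - i + 1L), 0)
}

#' Optimal univariate k-means by dynamic programming
#'
#' Partitions 1-D values into exactly `k` groups minimizing the total
#' within-cluster sum of squared deviations from cluster means.  Optimal 1-D
#' clusters are contiguous in sorted order, so a dynamic program over the
#' sorted values attains the global optimum (unlike Lloyd iteration).
#' Complexity O(k n^2) with O(1) interval costs from prefix sums — adequate
#' for cohort-scale n.
#'
#' @param values Finite numeric vector, length n >= k.
#' @param k Number of clusters, 1 <= k <= n.
#' @return List of class `"ckmeans"`: `k`, `assignments` (cluster index per
#'   input value, clusters numbered by increasing center), `centers`,
#'   `sizes`, `boundaries` (k-1 midpoints between adjacent clusters in
#'   sorted order) and `wcss`.
#' @export
ckmeans_1d <- function(values, k) {
  values <- as.numeric(values)
  n <- length(values)
  if (!n) stop("no values to cluster")
  if (any(!is.finite(values))) stop("values must be finite")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds number of values (", n, ")")
  ord <- order(values)
  x <- values[ord]
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  # D[q, j]: optimal cost of clustering x[1..j] into q clusters
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(1L, nrow = k, ncol = n)  # start index of last cluster
  for (j in 1:n) D[1L, j] <- interval_wcss(cs, cs2, 1L, j)
  if (k > 1L) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; arg <- q
        for (i in q:j) {
          cand <- D[q - 1L, i - 1L] + interval_wcss(cs, cs2, i, j)
          if (cand < best) { best <- cand; arg <- i }
        }
        D[q, j] <- best
        B[q, j] <- arg
      }
    }
  }
  # backtrack cluster boundaries over the sorted order
  starts <- integer(k)
  j <- n
  for (q in k:1) {
    starts[q] <- B[q, j]
    j <- starts[q] - 1L
  }
  ends <- c(starts[-1L] - 1L, n)
  assign_sorted <- rep(seq_len(k), times = ends - starts + 1L)
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  centers <- vapply(seq_len(k),
                    function(q) mean(x[starts[q]:ends[q]]), numeric(1))
  boundaries <- if (k > 1L)
    (x[ends[-k]] + x[starts[-1L]]) / 2 else numeric(0)
  structure(list(k = k, assignments = assignments, centers = centers,
                 sizes = ends - starts + 1L, boundaries = boundaries,
                 wcss = D[k, n]),
            class = "ckmeans")
}

# Gaussian-mixture log-likelihood of a fixed hard 1-D partition: mixing
# proportions n_q/n, cluster-MLE variance floored at `var_floor` to survive
# zero-variance clusters.
partition_loglik <- function(values, fit, var_floor = 1e-9) {
  n <- length(values)
  ll <- 0
  for (q in seq_len(fit$k)) {
    xs <- values[fit$assignments == q]
    nq <- length(xs)
    v <- max(sum((xs - mean(xs))^2) / nq, var_floor)
    ll <- ll + sum(stats::dnorm(xs, mean(xs), sqrt(v), log = TRUE)) +
      nq * log(nq / n)
  }
  ll
}

#' Select the number of 1-D clusters by BIC
#'
#' Fits [ckmeans_1d()] for each k in `k_min:k_max` (clamped to n) and scores
#' each partition with a Gaussian-mixture BIC: per-cluster normal
#' likelihoods weighted by mixing proportions n_k/n, parameter count 3k - 1
#' (k means, k variances, k - 1 proportions),
#' `BIC = 2 ln L - (3k - 1) ln n`, maximized; ties go to the smallest k.
#'
#' @param values Finite numeric vector.
#' @param k_min,k_max Range of cluster numbers examined (defaults 1 and 9).
#' @param var_floor Variance floor for degenerate (zero-spread) clusters.
#' @return List of class `"cluster_selection"`: `k_selected`, `k_range`,
#'   `wcss` and `bic` per examined k, and `fit` — the [ckmeans_1d()] result
#'   at the selected k.
#' @export
select_k_bic <- function(values, k_min = 1, k_max = 9, var_floor = 1e-9) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to cluster")
  n <- length(values)
  k_max <- min(as.integer(k_max), n)
  k_min <- max(1L, as.integer(k_min))
  if (k_min > k_max) stop("k_min exceeds k_max after clamping to n")
  ks <- k_min:k_max
  fits <- lapply(ks, function(k) ckmeans_1d(values, k))
  wcss <- vapply(fits, `[[`, numeric(1), "wcss")
  bic <- vapply(seq_along(ks), function(i) {
    2 * partition_loglik(values, fits[[i]], var_floor) -
      (3 * ks[i] - 1) * log(n)
  }, numeric(1))
  best <- which.max(bic)  # which.max takes the first maximum: smallest k
  structure(list(k_selected = ks[best], k_range = ks, wcss = wcss,
                 bic = bic, fit = fits[[best]]),
            class = "cluster_selection")
}

#' Assign TMB-H / TMB-L subtype labels
#'
#' Splits the cohort at a population threshold of the TMB distribution: the
#' arithmetic mean (default, the published rule), the median, or the k = 2
#' optimal-clustering boundary.  The inequality is strict — a sample is
#' TMB-H iff its TMB strictly exceeds the threshold, so threshold ties fall
#' in TMB-L.
#'
#' @param tmb Named numeric vector of per-sample TMB ([compute_tmb()]).
#' @param rule `"mean"`, `"median"`, or `"kmeans_boundary"`.
#' @return List of class `"subtype_assignment"`: `threshold`, `rule`, and
#'   `labels` — a named factor with levels `TMB-L`, `TMB-H`.
#' @export
assign_subtypes <- function(tmb, rule = c("mean", "median",
                                          "kmeans_boundary")) {
  rule <- match.arg(rule)
  if (!length(tmb)) stop("at least one sample required")
  threshold <- switch(rule,
    mean = mean(tmb),
    median = stats::median(tmb),
    kmeans_boundary = {
      if (length(tmb) < 2L)
        stop("kmeans_boundary rule needs at least two samples")
      ckmeans_1d(tmb, 2L)$boundaries
    })
  labels <- factor(ifelse(tmb > threshold, "TMB-H", "TMB-L"),
                   levels = c("TMB-L", "TMB-H"))
  names(labels) <- names(tmb)
  structure(list(threshold = unname(threshold), rule = rule,
                 labels = labels),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("Subtypes (rule =", x$rule, ", threshold =",
      format(x$threshold), "):\n")
  print(table(x$labels))
  invisible(x)
}
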