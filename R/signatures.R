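# 96-context SNV classification, Bayesian NMF signature extraction with
# automatic relevance determination, catalog matching, and subtype
# comparison of per-sample signature patterns.

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution categories
#'
#' Fixed category order shared by context matrices, extracted signatures and
#' reference catalogs: the six pyrimidine substitutions C>A, C>G, C>T, T>A,
#' T>C, T>G in blocks, within each block the 16 flanking-base combinations
#' with the 5' base varying slowest, both alphabetical (the COSMIC v2
#' published order).  Labels look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
context_categories <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s)
    unlist(lapply(BASES, function(p5) paste0(p5, "[", s, "]", BASES)))),
    use.names = FALSE)
}

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Tabulate SNVs into the 96 x N context matrix
#'
#' Each single-nucleotide variant with a valid trinucleotide context
#' increments exactly one of the 96 cells of its sample's column.  Variants
#' whose reference base is a purine (A or G) are mapped to the equivalent
#' pyrimidine representation by reverse complement of the context and
#' complement of the alleles, so every substitution is expressed with a C or
#' T reference.  SNVs lacking a context (or flagged as reference
#' mismatches) are skipped with a reported count.
#'
#' @param mutations Canonical mutation `data.frame` with contexts filled.
#' @param sample_ids Column roster; defaults to samples present in
#'   `mutations` (pass the cohort roster to keep zero-mutation columns).
#' @return Integer 96 x N matrix with category rownames
#'   ([context_categories()]) and sample colnames.
#' @export
classify_96 <- function(mutations, sample_ids = NULL) {
  mutations <- validate_mutations(mutations)
  if (is.null(sample_ids)) sample_ids <- unique(mutations$sample_id)
  snv <- is_snv(mutations)
  if ("ref_mismatch" %in% names(mutations))
    snv <- snv & !mutations$ref_mismatch
  has_ctx <- snv & !is.na(mutations$context)
  n_skipped <- sum(snv & is.na(mutations$context))
  if (n_skipped)
    message(n_skipped, " SNV record(s) without context skipped")
  cats <- context_categories()
  m <- matrix(0L, nrow = 96L, ncol = length(sample_ids),
              dimnames = list(cats, sample_ids))
  if (any(has_ctx)) {
    ctx <- mutations$context[has_ctx]
    ref <- mutations$ref[has_ctx]
    alt <- mutations$alt[has_ctx]
    purine <- ref %in% c("A", "G")
    ctx[purine] <- revcomp(ctx[purine])
    ref[purine] <- chartr("AG", "TC", ref[purine])
    alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
    lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                  substr(ctx, 3, 3))
    tab <- table(factor(lab, levels = cats),
                 factor(mutations$sample_id[has_ctx], levels = sample_ids))
    m[] <- as.integer(tab)
  }
  m
}

# KL (generalized Kullback-Leibler / Poisson) divergence D(V || WH)
kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

# Penalized objective of the ARD model (up to constants): KL fit term plus,
# per component, (||w_k||_1 + ||h_k||_1 + b)/lambda_k + c*log(lambda_k) for
# the exponential prior; half-normal uses squared norms / (2 lambda).
ard_objective <- function(V, W, H, lambda, a, b, prior) {
  Fdim <- nrow(V); N <- ncol(V)
  WH <- W %*% H
  fit <- kl_divergence(V, WH)
  if (prior == "exponential") {
    cst <- Fdim + N + a + 1
    pen <- sum((colSums(W) + rowSums(H) + b) / lambda + cst * log(lambda))
  } else {
    cst <- (Fdim + N) / 2 + a + 1
    pen <- sum((0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b) / lambda +
                 cst * log(lambda))
  }
  fit + pen
}

ard_nmf_once <- function(V, K, a, b, prior, max_iter, tol, prune_rel,
                         trace = FALSE) {
  Fdim <- nrow(V); N <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(Fdim * K, 0.5, 1.5), Fdim, K)
  H <- matrix(stats::runif(K * N, 0.5, 1.5), K, N)
  sc <- sqrt(mean(V) / mean(W %*% H))
  W <- W * sc; H <- H * sc
  lambda <- rep(mean(V), K)
  obj <- Inf
  obj_trace <- if (trace) numeric(max_iter) else NULL
  for (it in seq_len(max_iter)) {
    K_now <- ncol(W)
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    if (prior == "exponential") {
      W <- W * (R %*% t(H)) /
        pmax(matrix(rowSums(H), Fdim, K_now, byrow = TRUE) +
               matrix(1 / lambda, Fdim, K_now, byrow = TRUE), eps)
      WH <- W %*% H
      R <- V / pmax(WH, eps)
      H <- H * (t(W) %*% R) /
        pmax(matrix(colSums(W), K_now, N) + matrix(1 / lambda, K_now, N),
             eps)
      lambda <- (colSums(W) + rowSums(H) + b) / (Fdim + N + a + 1)
    } else {
      W <- W * (R %*% t(H)) /
        pmax(matrix(rowSums(H), Fdim, K_now, byrow = TRUE) +
               W / matrix(lambda, Fdim, K_now, byrow = TRUE), eps)
      WH <- W %*% H
      R <- V / pmax(WH, eps)
      H <- H * (t(W) %*% R) /
        pmax(matrix(colSums(W), K_now, N) + H / matrix(lambda, K_now, N),
             eps)
      lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b) /
        ((Fdim + N) / 2 + a + 1)
    }
    # prune collapsed components once the fit has settled in
    if (it >= 50L && it %% 10L == 0L && ncol(W) > 1L) {
      rel <- lambda / max(lambda)
      keep <- rel >= prune_rel
      if (!all(keep) && any(keep)) {
        W <- W[, keep, drop = FALSE]
        H <- H[keep, , drop = FALSE]
        lambda <- lambda[keep]
      }
    }
    obj_new <- ard_objective(V, W, H, lambda, a, b, prior)
    if (trace) obj_trace[it] <- obj_new
    if (is.finite(obj) && abs(obj - obj_new) <= tol * abs(obj)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (trace) obj_trace <- obj_trace[seq_len(it)]
  # final prune
  if (ncol(W) > 1L) {
    rel <- lambda / max(lambda)
    keep <- rel >= prune_rel
    if (any(keep) && !all(keep)) {
      W <- W[, keep, drop = FALSE]
      H <- H[keep, , drop = FALSE]
      lambda <- lambda[keep]
    }
  }
  list(W = W, H = H, lambda = lambda, objective = obj,
       iterations = it, obj_trace = obj_trace)
}

#' Extract mutational signatures by Bayesian NMF with ARD
#'
#' Factorizes a 96 x N mutation-count matrix V into signatures W and
#' activities H under a Poisson (generalized Kullback-Leibler) objective
#' with an automatic-relevance-determination prior: each component k has a
#' relevance hyperparameter shared by column k of W and row k of H, updated
#' in closed form each sweep (inverse-gamma conjugate step).  Components
#' whose relevance collapses below `prune_rel` of the current maximum are
#' removed, so the effective number of signatures is inferred rather than
#' fixed.  Multiplicative updates keep the penalized objective
#' non-increasing.  The best of `n_restarts` random restarts (by final
#' objective) is returned; results are deterministic given `seed`.
#'
#' @param V Nonnegative count matrix, contexts x samples (>= 2 samples).
#' @param K_max Maximum number of components to start from (default 20).
#' @param prior ARD prior on the component columns/rows: `"exponential"`
#'   (L1, default) or `"half_normal"` (L2).
#' @param a Shape hyperparameter of the inverse-gamma relevance prior
#'   (default 10).
#' @param b Scale hyperparameter; default `(a - 1) * sqrt(mean(V) / K_max)`
#'   matches the prior's expected component scale to the data.
#' @param max_iter,tol Sweep budget and relative objective-change
#'   convergence tolerance.
#' @param seed Integer seed controlling all restarts.
#' @param n_restarts Number of random restarts (default 10).
#' @param prune_rel Relative relevance threshold below which a component is
#'   pruned (default 1e-3); set to 0 to disable pruning.
#' @param trace Record the per-sweep penalized objective (`obj_trace`).
#' @return List of class `"signature_model"`: `W` (96 x K_effective,
#'   columns sum to 1), `H` (activities scaled so `W %*% H` is unchanged),
#'   `relevance`, `K_effective`, `reconstruction_error` (KL divergence),
#'   `objective`, `sample_totals` (column sums of V).  Components are
#'   ordered by total attributed mutations and labelled `W1, W2, ...`.
#' @export
bayesian_nmf <- function(V, K_max = 20,
                         prior = c("exponential", "half_normal"),
                         a = 10, b = NULL, max_iter = 2000, tol = 1e-8,
                         seed = 1, n_restarts = 10, prune_rel = 1e-3,
                         trace = FALSE) {
  prior <- match.arg(prior)
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (sum(V) == 0) stop("V is all zero")
  if (ncol(V) < 2L) stop("at least 2 samples required")
  K_max <- as.integer(K_max)
  if (K_max < 1L) stop("K_max must be >= 1")
  if (is.null(b)) b <- (a - 1) * sqrt(mean(V) / K_max)
  runs <- withr_seed(seed, {
    lapply(seq_len(n_restarts), function(r)
      ard_nmf_once(V, K_max, a, b, prior, max_iter, tol, prune_rel,
                   trace = trace))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  W <- best$W; H <- best$H
  # normalize signatures to probability vectors; fold scale into H
  wsum <- colSums(W)
  keep <- wsum > 0
  W <- W[, keep, drop = FALSE]; H <- H[keep, , drop = FALSE]
  wsum <- wsum[keep]
  W <- sweep(W, 2, wsum, "/")
  H <- H * wsum
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  labels <- paste0("W", seq_len(ncol(W)))
  colnames(W) <- labels
  rownames(H) <- labels
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  structure(list(W = W, H = H, relevance = best$lambda[keep][ord],
                 K_effective = ncol(W),
                 reconstruction_error = kl_divergence(V, W %*% H),
                 objective = best$objective,
                 iterations = best$iterations,
                 obj_trace = best$obj_trace,
                 sample_totals = colSums(V)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Bayesian NMF signature model: K_effective =", x$K_effective,
      "over", ncol(x$H), "samples\n")
  cat("KL reconstruction error:", format(x$reconstruction_error), "\n")
  invisible(x)
}

# run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Match extracted signatures against a reference catalog
#'
#' Computes the cosine similarity `u . v / (|u| |v|)` of every extracted
#' signature against every catalog column and reports, per extracted
#' signature independently (no bipartite matching), the best-matching
#' reference and its similarity.
#'
#' @param model A [bayesian_nmf()] fit, or a 96 x K signature matrix.
#' @param catalog Reference catalog: 96 x R matrix with signature names as
#'   column names and the [context_categories()] row order.
#' @return `data.frame` with columns `signature`, `best_match`, `cosine`.
#' @export
cosine_match <- function(model, catalog) {
  W <- if (inherits(model, "signature_model")) model$W else as.matrix(model)
  catalog <- as.matrix(catalog)
  if (nrow(W) != nrow(catalog))
    stop("category orders differ between signatures and catalog")
  if (is.null(colnames(W)))
    colnames(W) <- paste0("W", seq_len(ncol(W)))
  if (is.null(colnames(catalog)))
    colnames(catalog) <- paste0("ref", seq_len(ncol(catalog)))
  nw <- sqrt(colSums(W^2))
  nc <- sqrt(colSums(catalog^2))
  if (any(nw == 0) || any(nc == 0))
    stop("zero-norm signature: cosine similarity undefined")
  sims <- crossprod(W, catalog) / outer(nw, nc)
  best <- apply(sims, 1L, which.max)
  data.frame(signature = colnames(W),
             best_match = colnames(catalog)[best],
             cosine = sims[cbind(seq_len(ncol(W)), best)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample mutation attribution to each signature
#'
#' The pattern of a signature in a sample is the estimated number of
#' mutations assigned to it: activity H\[k, s\] rescaled so the per-sample
#' attributions sum exactly to the sample's observed (annotatable) SNV
#' count.  Samples with zero mutations get zero attribution throughout.
#'
#' @param model A [bayesian_nmf()] fit.
#' @param totals Optional per-sample totals to attribute; defaults to the
#'   column sums of the fitted count matrix.
#' @return K x N matrix of nonnegative attributed counts.
#' @export
signature_pattern <- function(model, totals = NULL) {
  stopifnot(inherits(model, "signature_model"))
  H <- model$H
  if (is.null(totals)) totals <- model$sample_totals
  hs <- colSums(H)
  scale <- ifelse(hs > 0, totals / hs, 0)
  sweep(H, 2, scale, "*")
}

#' Compare a signature's pattern between subtypes
#'
#' Two-sided Wilcoxon rank-sum test of one signature's per-sample attributed
#' mutation counts between the TMB-H and TMB-L groups.
#'
#' @param pattern K x N attribution matrix ([signature_pattern()]).
#' @param subtypes A [assign_subtypes()] result, or a factor/character
#'   vector of labels `TMB-H` / `TMB-L` aligned with the pattern columns.
#' @param signature Row index or name of the signature to compare.
#' @return A [test_result()].
#' @export
compare_pattern_by_subtype <- function(pattern, subtypes, signature = 1L) {
  labels <- if (inherits(subtypes, "subtype_assignment"))
    subtypes$labels else subtypes
  labels <- as.character(labels)
  if (length(labels) != ncol(pattern))
    stop("subtype labels do not align with pattern columns")
  v <- pattern[signature, ]
  hi <- v[labels == "TMB-H"]
  lo <- v[labels == "TMB-L"]
  if (!length(hi) || !length(lo)) stop("a subtype group is empty")
  res <- wilcoxon_rank_sum(hi, lo, alternative = "two.sided")
  res$test_name <- "signature_pattern_by_subtype"
  res
}
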