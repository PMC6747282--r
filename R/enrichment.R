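# Margin-preserving permutation enrichment: Curveball randomization of the
# binary gene x sample matrix and the one-tailed Wilcoxon permutation test
# of gene mutation status against signature activity.

matrix_to_sets <- function(m) {
  lapply(seq_len(nrow(m)), function(g) which(m[g, ] == 1L))
}

sets_to_matrix <- function(sets, template) {
  m <- matrix(0L, nrow = nrow(template), ncol = ncol(template),
              dimnames = dimnames(template))
  for (g in seq_along(sets)) m[g, sets[[g]]] <- 1L
  m
}

# one Curveball trade between two random genes: the samples unique to
# either gene are pooled and dealt back at random, sizes unchanged.  Pairs
# sharing all or none of their distinct samples are no-ops that still count
# toward the trade budget (standard Curveball behavior).
run_trades <- function(sets, n_trades) {
  G <- length(sets)
  if (G < 2L) return(sets)
  pairs <- matrix(0L, 2L, n_trades)
  for (t in seq_len(n_trades)) pairs[, t] <- sample.int(G, 2L)
  for (t in seq_len(n_trades)) {
    i <- pairs[1L, t]; j <- pairs[2L, t]
    A <- sets[[i]]; B <- sets[[j]]
    onlyA <- A[!(A %in% B)]
    onlyB <- B[!(B %in% A)]
    if (!length(onlyA) || !length(onlyB)) next
    pool <- c(onlyA, onlyB)
    pick <- sample(pool, length(onlyA))
    sets[[i]] <- c(A[A %in% B], pick)
    sets[[j]] <- c(B[B %in% A], pool[!(pool %in% pick)])
  }
  sets
}

#' Curveball randomization of a binary matrix
#'
#' Produces a random binary matrix with exactly the same row sums and
#' column sums as the input by repeated "trades": two rows are picked at
#' random and the columns unique to either row are redealt between them
#' uniformly at random, preserving both rows' totals.  The trade chain's
#' stationary distribution is uniform over the fixed-margin ensemble.
#'
#' @param m Binary (0/1) matrix, rows = genes, columns = samples.
#' @param n_trades Number of trades; default 5 x number of rows.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A randomized matrix with identical margins and dimnames.
#' @export
curveball_shuffle <- function(m, n_trades = 5 * nrow(m), seed = 1) {
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L))) stop("matrix must be binary")
  storage.mode(m) <- "integer"
  sets <- withr_seed(seed, run_trades(matrix_to_sets(m), n_trades))
  out <- sets_to_matrix(sets, m)
  stopifnot(identical(rowSums(out), rowSums(m)),
            identical(colSums(out), colSums(m)))
  out
}

#' Margin-controlled permutation test of genes against signature activity
#'
#' For each tested gene, the observed statistic is the one-tailed Wilcoxon
#' rank sum of the signature pattern in samples carrying a (nonsynonymous)
#' mutation in the gene.  Because samples with high mutation burden mutate
#' more genes by chance, a plain rank-sum test overstates significance; the
#' null distribution is instead built from matrices randomized by the
#' Curveball algorithm, which preserves each gene's mutation frequency and
#' each sample's mutated-gene count.  The empirical p-value uses the
#' add-one estimator `p = (1 + #extreme) / (R + 1)`, which can never return
#' 0 for finite R.
#'
#' In the default `"shared"` mode one randomized matrix per permutation
#' round serves all genes simultaneously (one Markov chain of trades with a
#' burn-in), which keeps R = 200,000 tractable; `"per_gene"` runs an
#' independent chain per gene.
#'
#' @param pattern Numeric vector: per-sample activity of the signature of
#'   interest, aligned with the matrix columns.
#' @param m Binary gene x sample matrix ([build_mutation_matrix()]).
#' @param genes Genes to test; default all rows mutated in at least 1 and
#'   at most N - 1 samples.  Rows outside that range are excluded with a
#'   message.
#' @param R Number of permutations (default 200000).
#' @param seed Integer seed.
#' @param direction `"greater"` (mutant samples have higher activity;
#'   extreme means `T_r >= T_obs`) or `"less"`.
#' @param n_trades Trades per permutation round (default 5 x genes).
#' @param burn_in Initial trades before the first permutation (default
#'   10 x `n_trades`).
#' @param mode `"shared"` or `"per_gene"` (see Details).
#' @return `data.frame` with columns `gene`, `n_mutant`, `T_observed`,
#'   `null_count_extreme`, `R`, `p`, `q` (BH-adjusted across tested genes).
#' @export
enrichment_test <- function(pattern, m, genes = NULL, R = 200000, seed = 1,
                            direction = c("greater", "less"),
                            n_trades = 5 * nrow(m),
                            burn_in = 10 * n_trades,
                            mode = c("shared", "per_gene")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (length(pattern) != ncol(m))
    stop("pattern length must equal the number of samples")
  rs <- rowSums(m)
  testable <- rownames(m)[rs >= 1 & rs <= ncol(m) - 1]
  if (is.null(genes)) genes <- rownames(m)
  dropped <- setdiff(genes, testable)
  if (length(dropped)) {
    message(length(dropped),
            " gene(s) mutated in no or all samples excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    genes <- intersect(genes, testable)
  }
  if (!length(genes)) stop("no testable genes")
  gi <- match(genes, rownames(m))
  ranks <- rank(pattern)
  sets <- matrix_to_sets(m)
  T_obs <- vapply(gi, function(g) sum(ranks[sets[[g]]]), numeric(1))
  count <- integer(length(gi))
  withr_seed(seed, {
    if (mode == "shared") {
      state <- run_trades(sets, burn_in)
      for (r in seq_len(R)) {
        state <- run_trades(state, n_trades)
        T_r <- vapply(gi, function(g) sum(ranks[state[[g]]]), numeric(1))
        count <- count + if (direction == "greater") (T_r >= T_obs)
                         else (T_r <= T_obs)
      }
    } else {
      for (k in seq_along(gi)) {
        state <- run_trades(sets, burn_in)
        for (r in seq_len(R)) {
          state <- run_trades(state, n_trades)
          T_r <- sum(ranks[state[[gi[k]]]])
          count[k] <- count[k] + if (direction == "greater")
            (T_r >= T_obs[k]) else (T_r <= T_obs[k])
        }
      }
    }
  })
  p <- (1 + count) / (R + 1)
  data.frame(gene = genes, n_mutant = rs[gi], T_observed = T_obs,
             null_count_extreme = count, R = R, p = p, q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
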