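# Shared fixtures and independent oracles, all built in code.

# tiny hand-written mutation table
tiny_mutations <- function() {
  data.frame(
    sample_id = c("A", "A", "B", "C"),
    gene = c("TP53", "TP53", "KRAS", "TP53"),
    chrom = "chr1",
    pos = c(10L, 20L, 30L, 40L),
    ref = c("C", "C", "T", "G"),
    alt = c("A", "T", "C", "T"),
    variant_class = c("missense", "synonymous", "missense", "nonsense"),
    context = c("ACA", "ACG", "ATA", "AGC"),
    stringsAsFactors = FALSE)
}

tiny_clinical <- function() {
  data.frame(
    sample_id = c("A", "B", "C"),
    age = c(70, 50, 66),
    smoking = c("smoker", "non_smoker", "unknown"),
    stage = c("late", "early", "early"),
    metastasis = c("no", "no", "yes"),
    dfs_time = c(12.5, 30, 8),
    dfs_event = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

# brute-force minimum WCSS over all contiguous k-partitions of sorted x
brute_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ss(x))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(q)
      ss(x[(b[q] + 1):b[q + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# all binary 4x4 matrices with the given margins (exhaustive scan)
enumerate_ensemble_4x4 <- function(rs, cs) {
  g <- as.matrix(expand.grid(rep(list(0:1), 16)))
  keep <- apply(g, 1, function(v) {
    m <- matrix(v, 4, 4)
    all(rowSums(m) == rs) && all(colSums(m) == cs)
  })
  apply(g[keep, , drop = FALSE], 1, paste, collapse = "")
}

# small synthetic context-count matrix from known profiles and exposures
simulate_context_matrix <- function(profiles, n_samples = 60,
                                    mean_total = 200, seed = 1) {
  set.seed(seed)
  K <- ncol(profiles)
  E <- t(vapply(seq_len(n_samples), function(i) {
    e <- stats::rgamma(K, 1); e / sum(e)
  }, numeric(K)))
  tot <- stats::rpois(n_samples, mean_total)
  V <- vapply(seq_len(n_samples), function(i)
    stats::rpois(96, tot[i] * as.vector(profiles %*% E[i, ])),
    numeric(96))
  dimnames(V) <- list(rownames(profiles),
                      sprintf("s%02d", seq_len(n_samples)))
  list(V = V, exposures = E, totals = tot)
}
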