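# End-to-end pipeline: from mutation + clinical tables to subtype calls,
# signatures, enrichment, association and survival reports, written as
# TSVs with stable column order.  This is what the command-line wrapper
# drives; kept as an ordinary function so tests can assert byte-identical
# reruns.

fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full subtyping pipeline on a cohort
#'
#' Computes per-sample TMB and the mean-rule TMB-H/TMB-L split (with the
#' BIC-selected optimal clustering as a companion report), builds the
#' 96-context matrix and extracts signatures by Bayesian NMF, matches them
#' against a reference catalog, runs the margin-controlled enrichment test
#' of every testable panel gene against the top signature's pattern, and
#' computes gene/clinical association and DFS survival statistics.  All
#' results are written as TSVs under `out_dir`; numeric columns are
#' formatted to a fixed precision so reruns with the same seed are
#' byte-identical.
#'
#' @param cohort A [cohort_table()] with clinical data attached.
#' @param out_dir Output directory.
#' @param seed Integer seed for the NMF restarts and permutations.
#' @param counting_mode TMB counting mode (see [compute_tmb()]).
#' @param rule Subtyping threshold rule (see [assign_subtypes()]).
#' @param k_max Largest cluster number examined by BIC.
#' @param nmf_kmax,nmf_restarts Bayesian NMF size/restart budget.
#' @param catalog Reference catalog (default the synthetic stand-in).
#' @param enrich_genes Genes for the enrichment test; default genes
#'   mutated in at least 5 samples (the frequency rule standing in for an
#'   external driver-gene list).
#' @param enrich_R Permutation count for the enrichment test.
#' @param enrich_signature Signature (row of the attribution matrix) whose
#'   pattern is tested; default `"W1"`, the top signature by attribution.
#' @return Invisibly, a list with the in-memory results (`tmb`,
#'   `subtypes`, `kselect`, `model`, `match`, `pattern`, `enrichment`,
#'   `gene_assoc`, `clinical_assoc`, `survival`) and `files`.
#' @export
run_pipeline <- function(cohort, out_dir, seed = 1,
                         counting_mode = "all_somatic",
                         rule = "mean", k_max = 9,
                         nmf_kmax = 12, nmf_restarts = 5,
                         catalog = synthetic_signature_catalog(),
                         enrich_genes = NULL, enrich_R = 1000,
                         enrich_signature = "W1") {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmb <- compute_tmb(cohort, counting_mode)
  subtypes <- assign_subtypes(tmb, rule = rule)
  kselect <- select_k_bic(tmb, k_max = k_max)
  ctx <- classify_96(cohort$mutations, sample_ids = cohort$sample_ids)
  model <- bayesian_nmf(ctx, K_max = nmf_kmax, seed = seed,
                        n_restarts = nmf_restarts)
  match <- cosine_match(model, catalog)
  pattern <- signature_pattern(model)
  mm <- build_mutation_matrix(cohort, nonsynonymous_only = TRUE)
  if (is.null(enrich_genes))
    enrich_genes <- rownames(mm)[rowSums(mm) >= 5 &
                                   rowSums(mm) <= ncol(mm) - 1]
  enrichment <- enrichment_test(pattern[enrich_signature, ], mm,
                                genes = enrich_genes, R = enrich_R,
                                seed = seed)
  gene_assoc <- gene_subtype_association(mm, subtypes,
                                         genes = enrich_genes)
  feats <- c("age_group", "smoking", "stage", "metastasis")
  clin <- lapply(feats, function(f)
    clinical_association(cohort$clinical, subtypes, f, tmb = tmb))
  names(clin) <- feats
  clin_df <- do.call(rbind, lapply(feats, function(f) {
    cf <- clin[[f]]
    data.frame(feature = f, fisher_p = cf$fisher$p,
               tmb_wilcoxon_p = if (is.null(cf$tmb_wilcoxon)) NA_real_
                                else cf$tmb_wilcoxon$p)
  }))
  cl <- cohort$clinical[match(cohort$sample_ids,
                              cohort$clinical$sample_id), ]
  surv <- logrank_test(cl$dfs_time, cl$dfs_event,
                       as.character(subtypes$labels))
  km <- km_estimate(cl$dfs_time, cl$dfs_event,
                    as.character(subtypes$labels))
  files <- c(
    write_tsv(data.frame(sample_id = names(tmb), tmb = as.integer(tmb),
                         subtype = as.character(subtypes$labels)),
              file.path(out_dir, "subtypes.tsv")),
    write_tsv(data.frame(k = kselect$k_range, wcss = kselect$wcss,
                         bic = kselect$bic,
                         selected = kselect$k_range ==
                           kselect$k_selected),
              file.path(out_dir, "k_selection.tsv")),
    write_tsv(data.frame(category = rownames(model$W),
                         as.data.frame(model$W)),
              file.path(out_dir, "signatures_W.tsv")),
    write_tsv(data.frame(signature = rownames(pattern),
                         as.data.frame(pattern)),
              file.path(out_dir, "signature_pattern.tsv")),
    write_tsv(match, file.path(out_dir, "signature_match.tsv")),
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv")),
    write_tsv(gene_assoc, file.path(out_dir, "gene_association.tsv")),
    write_tsv(clin_df, file.path(out_dir, "clinical_association.tsv")),
    write_tsv(data.frame(statistic = surv$statistic, p = surv$p),
              file.path(out_dir, "logrank.tsv")),
    write_tsv(km, file.path(out_dir, "km_curves.tsv")))
  invisible(list(tmb = tmb, subtypes = subtypes, kselect = kselect,
                 model = model, match = match, pattern = pattern,
                 enrichment = enrichment, gene_assoc = gene_assoc,
                 clinical_assoc = clin, survival = surv, km = km,
                 files = files))
}
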