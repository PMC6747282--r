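# Synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes — a right-skewed TMB distribution with a high-burden
# subpopulation, a smoking-like C>A signature whose exposure grows with
# TMB, a TMB-coupled gene and a low-TMB-leaning gene, clinical covariates
# correlated with TMB, and exponential disease-free survival with a
# subtype hazard effect — and records every latent draw as ground truth
# for parameter-recovery tests.

#' Default mutated-gene panel for the synthetic cohort
#'
#' Fifty genes with per-gene baseline mutation probabilities and a
#' logistic TMB coupling: `RYR2L` (slope +2: its mutation probability
#' rises with TMB), `EGFRL` (slope -1.5: leans to low-TMB samples), and 48
#' uncoupled genes with baseline probabilities cycling over 0.08-0.25.
#'
#' @return `data.frame` with columns `gene`, `base_prob`, `tmb_slope`.
#' @export
default_gene_panel <- function() {
  others <- sprintf("G%02d", 3:50)
  data.frame(
    gene = c("RYR2L", "EGFRL", others),
    base_prob = c(0.10, 0.25,
                  rep(c(0.08, 0.12, 0.18, 0.25), length.out = 48)),
    tmb_slope = c(2.0, -1.5, rep(0, 48)),
    stringsAsFactors = FALSE)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults state the emulated world: 101 tumors; TMB drawn from a
#' two-component lognormal mixture (low mode near 60 mutations, high mode
#' near 400, high-component weight 33/101) clipped to the observed range
#' 7-1126; three generating signatures ([default_signature_profiles()])
#' whose smoking-like exposure fraction follows a logistic link in log
#' TMB; a 5% indel fraction; the [default_gene_panel()]; smoking and age
#' logistic in log TMB; exponential DFS with hazard ratio 2 for the
#' high-TMB component and uniform censoring.
#'
#' @param n_samples Cohort size.
#' @param p_high Mixing weight of the high-TMB component.
#' @param tmb_low_meanlog,tmb_low_sdlog,tmb_high_meanlog,tmb_high_sdlog
#'   Lognormal parameters of the two TMB components.
#' @param tmb_range Clipping range for drawn TMB values.
#' @param signature_profiles 96 x K column-normalized generating profiles;
#'   column 1 is the smoking-like (TMB-coupled) signature.
#' @param exposure_intercept,exposure_slope Logistic link of the
#'   smoking-like exposure fraction on standardized log TMB.
#' @param indel_fraction Expected fraction of mutations that are indels.
#' @param gene_panel Panel `data.frame` (see [default_gene_panel()]).
#' @param n_background_genes Size of the background gene pool absorbing
#'   unassigned mutations.
#' @param smoking_intercept,smoking_slope,age_mean,age_slope,age_sd
#'   Clinical covariate links on standardized log TMB.
#' @param stage_slope,metastasis_slope Weak stage/metastasis couplings.
#' @param dfs_base_median Median DFS (months) of the low-TMB component.
#' @param hazard_ratio Hazard ratio of the high-TMB component (default 2).
#' @param censor_range Uniform censoring-time range in months.
#' @return List of class `"simulation_params"`.
#' @export
simulation_params <- function(n_samples = 101,
                              p_high = 33 / 101,
                              tmb_low_meanlog = log(60),
                              tmb_low_sdlog = 0.55,
                              tmb_high_meanlog = log(400),
                              tmb_high_sdlog = 0.45,
                              tmb_range = c(7, 1126),
                              signature_profiles =
                                default_signature_profiles(),
                              exposure_intercept = 0.2,
                              exposure_slope = 1.5,
                              indel_fraction = 0.05,
                              gene_panel = default_gene_panel(),
                              n_background_genes = 40,
                              smoking_intercept = -0.3,
                              smoking_slope = 1.2,
                              age_mean = 62, age_slope = 4, age_sd = 8,
                              stage_slope = 0.3,
                              metastasis_slope = 0.3,
                              dfs_base_median = 36,
                              hazard_ratio = 2.0,
                              censor_range = c(12, 60)) {
  profiles <- as.matrix(signature_profiles)
  stopifnot(nrow(profiles) == 96,
            max(abs(colSums(profiles) - 1)) < 1e-6,
            all(gene_panel$base_prob > 0 & gene_panel$base_prob < 1),
            p_high >= 0, p_high <= 1, indel_fraction >= 0,
            indel_fraction < 1)
  structure(as.list(environment()), class = "simulation_params")
}

# standardized log-TMB covariate shared by all couplings
tmb_z <- function(tmb) (log(tmb) - log(150)) / 0.8

category_to_context <- function(cat_idx, flip) {
  tab <- category_table()
  p5 <- tab$p5[cat_idx]; p3 <- tab$p3[cat_idx]
  ref <- substr(tab$sub[cat_idx], 1, 1)
  alt <- substr(tab$sub[cat_idx], 3, 3)
  ctx <- paste0(p5, ref, p3)
  ref[flip] <- chartr("CT", "GA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  list(ref = ref, alt = alt, context = ctx)
}

#' Generate a synthetic cohort with stored ground truth
#'
#' Draws a full cohort under the generator's stated world (see
#' [simulation_params()]): per sample, a latent mixture component and TMB,
#' signature exposures, that many mutation records (SNV trinucleotide
#' categories multinomial in the mixed profile, contexts emitted directly
#' in the table with a random strand-of-report flip, a 5% indel
#' fraction), panel-gene mutation indicators (one nonsynonymous record
#' each), clinical covariates, and censored exponential DFS.  Every latent
#' draw is returned in the `ground_truth` bundle.
#'
#' @param params A [simulation_params()] list.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List of class `"synthetic_cohort"` with elements `cohort` (a
#'   [cohort_table()]) and `ground_truth` (per-sample latent table
#'   `samples`, realized panel `gene_indicators` matrix, true 96 x N
#'   `category_counts`, and `params`).
#' @export
generate_cohort <- function(params = simulation_params(), seed = 1) {
  stopifnot(inherits(params, "simulation_params"))
  withr_seed(seed, generate_cohort_impl(params))
}

#' Generate a null cohort with all couplings severed
#'
#' Same marginal structure as [generate_cohort()] but gene indicators,
#' signature exposures, and clinical covariates are independent of TMB,
#' and both survival components share one hazard — the reference world for
#' type-I-error calibration.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(params = simulation_params(), seed = 1) {
  stopifnot(inherits(params, "simulation_params"))
  params$exposure_slope <- 0
  params$smoking_slope <- 0
  params$age_slope <- 0
  params$stage_slope <- 0
  params$metastasis_slope <- 0
  params$hazard_ratio <- 1
  params$gene_panel$tmb_slope <- 0
  withr_seed(seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  comp <- stats::rbinom(n, 1L, p$p_high)
  tmb <- round(ifelse(comp == 1L,
                      stats::rlnorm(n, p$tmb_high_meanlog, p$tmb_high_sdlog),
                      stats::rlnorm(n, p$tmb_low_meanlog, p$tmb_low_sdlog)))
  tmb <- pmin(pmax(tmb, p$tmb_range[1]), p$tmb_range[2])
  z <- tmb_z(tmb)
  # signature exposures: smoking-like fraction logistic in log TMB, the
  # remainder split between the other profiles
  f_smoke <- stats::plogis(p$exposure_intercept + p$exposure_slope * z)
  # episodic APOBEC: U-shaped share of the non-smoking remainder, so many
  # samples are near-pure in one background process (the exposure
  # dispersion real cohorts show, and what makes NMF identifiable)
  w_ap <- stats::rbeta(n, 0.5, 0.5)
  K <- ncol(p$signature_profiles)
  expo <- cbind(f_smoke,
                (1 - f_smoke) * w_ap,
                (1 - f_smoke) * (1 - w_ap))[, seq_len(K), drop = FALSE]
  expo <- expo / rowSums(expo)
  # panel gene indicators, logistic in log TMB
  panel <- p$gene_panel
  ind <- matrix(0L, nrow(panel), n,
                dimnames = list(panel$gene, ids))
  for (g in seq_len(nrow(panel))) {
    pg <- stats::plogis(stats::qlogis(panel$base_prob[g]) +
                          panel$tmb_slope[g] * z)
    ind[g, ] <- stats::rbinom(n, 1L, pg)
  }
  bg_genes <- sprintf("BG%02d", seq_len(p$n_background_genes))
  cat_counts <- matrix(0L, 96L, n,
                       dimnames = list(context_categories(), ids))
  snv_classes <- c("missense", "synonymous", "nonsense", "splice_site")
  snv_class_p <- c(0.55, 0.30, 0.08, 0.07)
  pos_counter <- 0L
  rec <- vector("list", n)
  n_indel <- integer(n)
  for (s in seq_len(n)) {
    ni <- stats::rbinom(1L, tmb[s], p$indel_fraction)
    ns <- tmb[s] - ni
    n_indel[s] <- ni
    p_mix <- as.vector(p$signature_profiles %*% expo[s, ])
    cc <- stats::rmultinom(1L, ns, p_mix)[, 1]
    cat_counts[, s] <- cc
    cat_idx <- sample(rep.int(seq_len(96L), cc))
    flip <- stats::runif(ns) < 0.5
    al <- category_to_context(cat_idx, flip)
    cls <- sample(snv_classes, ns, replace = TRUE, prob = snv_class_p)
    genes <- sample(bg_genes, ns, replace = TRUE)
    hits <- which(ind[, s] == 1L)
    if (length(hits) > ns) {        # cannot host more genes than records
      drop <- hits[-seq_len(ns)]
      ind[drop, s] <- 0L
      hits <- hits[seq_len(ns)]
    }
    if (length(hits)) {
      genes[seq_along(hits)] <- panel$gene[hits]
      cls[seq_along(hits)] <- "missense"  # panel hits are nonsynonymous
    }
    # indels: no context, frameshift-leaning
    icls <- sample(c("frameshift_indel", "nonframeshift_indel"), ni,
                   replace = TRUE, prob = c(0.7, 0.3))
    ins <- stats::runif(ni) < 0.5
    iref <- ifelse(ins, "T", "TA")
    ialt <- ifelse(ins, "TA", "T")
    pos <- pos_counter + seq_len(tmb[s])
    pos_counter <- pos_counter + tmb[s]
    rec[[s]] <- data.frame(
      sample_id = ids[s],
      gene = c(genes, sample(bg_genes, ni, replace = TRUE)),
      chrom = "chr1",
      pos = as.integer(pos),
      ref = c(al$ref, iref),
      alt = c(al$alt, ialt),
      variant_class = c(cls, icls),
      context = c(al$context, rep(NA_character_, ni)),
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, rec)
  rownames(mutations) <- NULL
  # clinical covariates
  smoking <- ifelse(stats::rbinom(n, 1L, stats::plogis(
    p$smoking_intercept + p$smoking_slope * z)) == 1L,
    "smoker", "non_smoker")
  age <- round(pmax(stats::rnorm(n, p$age_mean + p$age_slope * z,
                                 p$age_sd), 30), 1)
  stage <- ifelse(stats::rbinom(n, 1L, stats::plogis(
    -0.4 + p$stage_slope * z)) == 1L, "late", "early")
  metastasis <- ifelse(stats::rbinom(n, 1L, stats::plogis(
    -1.2 + p$metastasis_slope * z)) == 1L, "yes", "no")
  rate <- log(2) / p$dfs_base_median * p$hazard_ratio^comp
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, p$censor_range[1], p$censor_range[2])
  dfs_time <- round(pmin(t_event, t_cens), 2)
  dfs_event <- t_event <= t_cens
  clinical <- data.frame(
    sample_id = ids, age = age,
    age_group = ifelse(age >= 65, "at_least65", "under65"),
    smoking = smoking, stage = stage, metastasis = metastasis,
    dfs_time = dfs_time, dfs_event = dfs_event,
    stringsAsFactors = FALSE)
  gt_samples <- data.frame(
    sample_id = ids, component = comp, tmb = as.integer(tmb),
    n_snv = as.integer(tmb) - n_indel, n_indel = n_indel,
    stringsAsFactors = FALSE)
  colnames(expo) <- colnames(p$signature_profiles)
  gt_samples <- cbind(gt_samples, as.data.frame(expo))
  structure(list(
    cohort = cohort_table(mutations, clinical, sample_ids = ids),
    ground_truth = list(samples = gt_samples, gene_indicators = ind,
                        category_counts = cat_counts, params = p)),
    class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the MAF-like mutation table, the clinical table, and the
#' ground-truth latent table as tab-separated files with stable column
#' order (byte-identical across runs with the same seed).
#'
#' @param sim A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maf <- file.path(dir, "mutations.maf.tsv")
  cli <- file.path(dir, "clinical.tsv")
  gt <- file.path(dir, "ground_truth_samples.tsv")
  write_maf(sim$cohort$mutations, maf)
  write_clinical(sim$cohort$clinical, cli)
  utils::write.table(sim$ground_truth$samples, gt, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(maf, cli, gt))
}
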