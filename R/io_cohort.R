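# Cohort I/O: MAF-like mutation tables, clinical tables, and the derived
# gene x sample binary mutation matrix.

VARIANT_CLASSES <- c("nonsense", "missense", "splice_site", "synonymous",
                     "frameshift_indel", "nonframeshift_indel")

SNV_CLASSES <- c("nonsense", "missense", "splice_site", "synonymous")

#' Default synonym table for variant classification strings
#'
#' Maps common MAF dialect spellings (e.g. `"Missense_Mutation"`,
#' `"Frame_Shift_Del"`) onto the six canonical classes used throughout the
#' package: nonsense, missense, splice_site, synonymous, frameshift_indel,
#' nonframeshift_indel.  Canonical names map to themselves so written tables
#' round-trip.
#'
#' @return Named character vector: names are input spellings, values the
#'   canonical class.
#' @export
default_class_synonyms <- function() {
  c(
    Missense_Mutation  = "missense",
    Nonsense_Mutation  = "nonsense",
    Splice_Site        = "splice_site",
    Silent             = "synonymous",
    Synonymous         = "synonymous",
    Frame_Shift_Del    = "frameshift_indel",
    Frame_Shift_Ins    = "frameshift_indel",
    In_Frame_Del       = "nonframeshift_indel",
    In_Frame_Ins       = "nonframeshift_indel",
    missense           = "missense",
    nonsense           = "nonsense",
    splice_site        = "splice_site",
    synonymous         = "synonymous",
    frameshift_indel   = "frameshift_indel",
    nonframeshift_indel = "nonframeshift_indel"
  )
}

#' MAF dialect configuration
#'
#' Column-name mapping from an input tab-separated mutation table onto the
#' canonical fields.  Defaults follow the common MAF header.  The paper's
#' deposited calls do not pin down one dialect, so the mapping is the escape
#' hatch for any tab-separated variant of it.
#'
#' @param sample,gene,chrom,pos,ref,alt,variant_class Input column names for
#'   the mandatory fields.
#' @param context Optional input column carrying a precomputed trinucleotide
#'   context (middle base equal to the reference allele); when present in the
#'   file a reference FASTA is not needed for signature analysis.
#' @param class_synonyms Named character vector mapping input variant-class
#'   strings to canonical classes (see [default_class_synonyms()]).
#' @return A list of class `"maf_dialect"`.
#' @export
maf_dialect <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        chrom = "Chromosome",
                        pos = "Start_Position",
                        ref = "Reference_Allele",
                        alt = "Tumor_Seq_Allele2",
                        variant_class = "Variant_Classification",
                        context = "context",
                        class_synonyms = default_class_synonyms()) {
  structure(list(sample = sample, gene = gene, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, variant_class = variant_class,
                 context = context, class_synonyms = class_synonyms),
            class = "maf_dialect")
}

is_snv <- function(mutations) {
  mutations$variant_class %in% SNV_CLASSES &
    nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L &
    mutations$ref %in% c("A", "C", "G", "T") &
    mutations$alt %in% c("A", "C", "G", "T")
}

validate_mutations <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  needed <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
              "variant_class")
  missing <- setdiff(needed, names(mutations))
  if (length(missing))
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"context" %in% names(mutations)) mutations$context <- NA_character_
  bad_class <- setdiff(unique(mutations$variant_class), VARIANT_CLASSES)
  if (length(bad_class))
    stop("unknown variant class(es): ", paste(bad_class, collapse = ", "))
  if (nrow(mutations)) {
    if (any(!is.finite(mutations$pos)) || any(mutations$pos < 1))
      stop("positions must be finite and >= 1 (1-based coordinates)")
    if (any(mutations$ref == mutations$alt))
      stop("ref allele equals alt allele in some rows")
    ctx <- mutations$context
    has_ctx <- !is.na(ctx) & nzchar(ctx)
    if (any(has_ctx)) {
      if (any(nchar(ctx[has_ctx]) != 3L))
        stop("trinucleotide contexts must have length 3")
      mid <- substr(ctx[has_ctx], 2L, 2L)
      if (any(mid != mutations$ref[has_ctx]))
        stop("context middle base must equal the reference allele")
    }
  }
  mutations
}

#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated mutation file into the canonical tidy layout used
#' by the rest of the package: one row per mutation per sample with columns
#' `sample_id`, `gene`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `variant_class` and `context` (`NA` when absent).  Exact duplicate rows —
#' likely double-reported calls — are collapsed to one with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect A [maf_dialect()] describing the column mapping.
#' @return A `data.frame` of canonical mutation records, row order preserved.
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  mandatory <- c("sample", "gene", "chrom", "pos", "ref", "alt",
                 "variant_class")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (!col %in% names(raw))
      stop("mandatory column '", col, "' (", field, ") not found in ", path)
  }
  n <- nrow(raw)
  pos <- suppressWarnings(as.numeric(raw[[dialect$pos]]))
  if (n && anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("malformed position '", raw[[dialect$pos]][bad],
         "' at data line ", bad, " of ", path)
  }
  vc_in <- raw[[dialect$variant_class]]
  syn <- dialect$class_synonyms
  unknown <- setdiff(unique(vc_in), names(syn))
  if (n && length(unknown))
    stop("variant class(es) not in the synonym table: ",
         paste(unknown, collapse = ", "))
  ctx <- if (dialect$context %in% names(raw)) raw[[dialect$context]]
         else rep(NA_character_, n)
  ctx[!is.na(ctx) & !nzchar(ctx)] <- NA_character_
  out <- data.frame(
    sample_id     = raw[[dialect$sample]],
    gene          = raw[[dialect$gene]],
    chrom         = raw[[dialect$chrom]],
    pos           = as.integer(pos),
    ref           = raw[[dialect$ref]],
    alt           = raw[[dialect$alt]],
    variant_class = if (n) unname(syn[vc_in]) else character(0),
    context       = if (n) ctx else character(0),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out)
  if (any(dup)) {
    warning(sum(dup), " duplicate mutation row(s) collapsed")
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  validate_mutations(out)
}

#' Write a mutation table in a MAF-like dialect
#'
#' Inverse of [read_maf()]: canonical records are written tab-separated under
#' the dialect's column names, with a stable column order.  `NA` contexts are
#' written as empty strings.
#'
#' @param mutations Canonical mutation `data.frame`.
#' @param path Output path.
#' @inheritParams read_maf
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path, dialect = maf_dialect()) {
  mutations <- validate_mutations(mutations)
  out <- data.frame(
    a = mutations$sample_id, b = mutations$gene, c = mutations$chrom,
    d = mutations$pos, e = mutations$ref, f = mutations$alt,
    g = mutations$variant_class,
    h = ifelse(is.na(mutations$context), "", mutations$context),
    stringsAsFactors = FALSE)
  names(out) <- c(dialect$sample, dialect$gene, dialect$chrom, dialect$pos,
                  dialect$ref, dialect$alt, dialect$variant_class,
                  dialect$context)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `sample_id`, `age`, `smoking`, `stage`,
#' `metastasis`, `dfs_time`, `dfs_event` (and optionally `age_group`).
#' `age_group` is derived from `age` at the 65-year cut when absent and
#' checked for consistency when present.  Unknown categorical values must be
#' spelled `"unknown"`; they form a dedicated level that association tests
#' exclude pairwise.
#'
#' @param path Path to the tab-separated clinical file.
#' @param age_cut Age dichotomization cut in years (default 65).
#' @return A validated clinical `data.frame`.
#' @export
read_clinical <- function(path, age_cut = 65) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_clinical(raw, age_cut = age_cut)
}

validate_clinical <- function(clinical, age_cut = 65) {
  needed <- c("sample_id", "age", "smoking", "stage", "metastasis",
              "dfs_time", "dfs_event")
  missing <- setdiff(needed, names(clinical))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("clinical sample_id values must be unique")
  clinical$age <- as.numeric(clinical$age)
  if (any(clinical$age < 0, na.rm = TRUE)) stop("negative age")
  derived <- ifelse(is.na(clinical$age), "unknown",
                    ifelse(clinical$age >= age_cut, "at_least65", "under65"))
  if (!"age_group" %in% names(clinical)) {
    clinical$age_group <- derived
  } else {
    both <- !is.na(clinical$age) & clinical$age_group != "unknown"
    if (any(clinical$age_group[both] != derived[both]))
      stop("age_group inconsistent with age at the ", age_cut, "-year cut")
  }
  chk <- function(col, levels) {
    bad <- setdiff(unique(clinical[[col]]), levels)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  chk("age_group", c("under65", "at_least65", "unknown"))
  chk("smoking", c("smoker", "non_smoker", "unknown"))
  chk("stage", c("early", "late", "unknown"))
  chk("metastasis", c("yes", "no", "unknown"))
  clinical$dfs_time <- as.numeric(clinical$dfs_time)
  if (any(clinical$dfs_time < 0, na.rm = TRUE)) stop("negative dfs_time")
  clinical$dfs_event <- as.logical(clinical$dfs_event)
  clinical
}

#' Write a clinical table
#'
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  cols <- c("sample_id", "age", "age_group", "smoking", "stage",
            "metastasis", "dfs_time", "dfs_event")
  utils::write.table(clinical[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from mutation and clinical tables
#'
#' A cohort couples the tidy mutation table with the clinical table and an
#' ordered roster of sample ids.  Samples present in the clinical table but
#' carrying zero mutations are retained (their TMB is 0).
#'
#' @param mutations Canonical mutation `data.frame` (see [read_maf()]).
#' @param clinical Optional clinical `data.frame`.
#' @param sample_ids Optional explicit sample roster; defaults to the union
#'   of clinical and mutation sample ids in order of first appearance.
#' @return A list of class `"cohort_table"` with elements `mutations`,
#'   `clinical`, `sample_ids`.
#' @export
cohort_table <- function(mutations, clinical = NULL, sample_ids = NULL) {
  mutations <- validate_mutations(mutations)
  if (!is.null(clinical)) clinical <- validate_clinical(clinical)
  if (is.null(sample_ids)) {
    sample_ids <- unique(c(if (!is.null(clinical)) clinical$sample_id,
                           mutations$sample_id))
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  orphan <- setdiff(mutations$sample_id, sample_ids)
  if (length(orphan))
    stop("mutation sample id(s) absent from the roster: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(mutations = mutations, clinical = clinical,
                 sample_ids = as.character(sample_ids)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort:", length(x$sample_ids), "samples,",
      nrow(x$mutations), "mutations",
      if (!is.null(x$clinical)) "(clinical attached)" else "", "\n")
  invisible(x)
}

#' Fill trinucleotide contexts from a reference FASTA
#'
#' Annotates SNV records with the 3-mer centered on the mutated base, looked
#' up in `reference_fasta` (1-based, fully closed coordinates).  Records at a
#' contig boundary (no 5' or 3' neighbor) are left un-annotated.  Records
#' whose reference base disagrees with the FASTA are flagged: their context
#' is set to `NA` so they never enter signature analysis, and the count is
#' reported.  Indels are never annotated.
#'
#' @param mutations Canonical mutation `data.frame`.
#' @param reference_fasta Path to a FASTA file whose sequence names (first
#'   whitespace-delimited word) match the `chrom` column.
#' @return The mutation table with `context` filled and a logical
#'   `ref_mismatch` column added.
#' @export
annotate_context <- function(mutations, reference_fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("annotate_context() requires the Biostrings package")
  mutations <- validate_mutations(mutations)
  genome <- Biostrings::readDNAStringSet(reference_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  snv <- is_snv(mutations)
  miss <- setdiff(unique(mutations$chrom[snv]), names(genome))
  if (length(miss))
    stop("chromosome(s) absent from FASTA: ", paste(miss, collapse = ", "))
  mutations$ref_mismatch <- FALSE
  idx <- which(snv)
  if (length(idx)) {
    chrom <- mutations$chrom[idx]
    pos <- mutations$pos[idx]
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    inside <- pos > 1L & pos < len
    ctx <- rep(NA_character_, length(idx))
    if (any(inside)) {
      at <- idx[inside]
      ctx[inside] <- as.character(Biostrings::subseq(
        genome[mutations$chrom[at]],
        start = mutations$pos[at] - 1L, end = mutations$pos[at] + 1L))
    }
    mid <- substr(ctx, 2L, 2L)
    bad <- !is.na(ctx) & mid != mutations$ref[idx]
    if (any(bad)) {
      message(sum(bad), " SNV record(s) disagree with the reference base; ",
              "excluded from signature analysis")
      mutations$ref_mismatch[idx[bad]] <- TRUE
      ctx[bad] <- NA_character_
    }
    mutations$context[idx] <- ctx
  }
  mutations
}

#' Build the binary gene x sample mutation matrix
#'
#' Entry (g, s) is 1 iff sample `s` carries at least one qualifying mutation
#' in gene `g` (multiple hits are binarized).  With `nonsynonymous_only`,
#' synonymous records do not qualify — the representation used by the
#' signature enrichment test.  Every cohort sample contributes a column,
#' including samples with zero mutations.
#'
#' @param cohort A [cohort_table()].
#' @param nonsynonymous_only Exclude synonymous records (default `FALSE`).
#' @return Integer 0/1 matrix, genes as rows, samples as columns.
#' @export
build_mutation_matrix <- function(cohort, nonsynonymous_only = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!length(cohort$sample_ids)) stop("empty cohort")
  mut <- cohort$mutations
  if (nonsynonymous_only)
    mut <- mut[mut$variant_class != "synonymous", , drop = FALSE]
  genes <- sort(unique(mut$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(cohort$sample_ids),
              dimnames = list(genes, cohort$sample_ids))
  if (nrow(mut))
    m[cbind(match(mut$gene, genes),
            match(mut$sample_id, cohort$sample_ids))] <- 1L
  m
}
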