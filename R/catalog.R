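# Parametric 96-context signature profiles: the three generating profiles
# used by the synthetic cohort and a SYNTHETIC reference catalog in the
# COSMIC v2 dialect (same category order and naming scheme).
#
# The catalog is a constructed stand-in, NOT the published COSMIC values:
# its columns are built from the parametric constructors below so that the
# package needs no downloaded data.  Any user-supplied 96 x R matrix in the
# same category order can replace it.

category_table <- function() {
  cats <- context_categories()
  data.frame(category = cats,
             sub = substr(cats, 3, 5),
             p5 = substr(cats, 1, 1),
             p3 = substr(cats, 7, 7),
             stringsAsFactors = FALSE)
}

# build a normalized 96-profile from a weight rule over (sub, 5', 3')
make_profile <- function(rule, baseline = 0.01) {
  tab <- category_table()
  w <- baseline + vapply(seq_len(96), function(i)
    rule(tab$sub[i], tab$p5[i], tab$p3[i]), numeric(1))
  w / sum(w)
}

smoking_like_profile <- function() {
  # C>A transversions across the full flanking spectrum, mildly stronger
  # with a 5' C (benzo[a]pyrene-adduct flavor)
  make_profile(function(s, p5, p3) {
    if (s == "C>A") 1 + 0.5 * (p5 == "C") else 0
  }, baseline = 0.02)
}

apobec_like_profile <- function() {
  # C>T and C>G at TpCpN motifs (cytidine-deaminase flavor)
  make_profile(function(s, p5, p3) {
    if (p5 == "T" && s == "C>T") 1 else if (p5 == "T" && s == "C>G") 0.7
    else 0
  }, baseline = 0.005)
}

mmr_like_profile <- function() {
  # C>T at [A/C/G]pCpG motifs (mismatch-repair-deficiency flavor)
  make_profile(function(s, p5, p3) {
    if (s == "C>T" && p3 == "G" && p5 != "T") 1 else 0
  }, baseline = 0.005)
}

#' Default generating signature profiles for the synthetic cohort
#'
#' Three parametric 96-context profiles: a smoking-like broad C>A
#' transversion signature, an APOBEC-like C>T/C>G-at-TpC signature, and a
#' mismatch-repair-like C>T-at-CpG signature.  Columns sum to 1 and share
#' the [context_categories()] order.
#'
#' @return 96 x 3 matrix with columns `smoking_like`, `apobec_like`,
#'   `mmr_like`.
#' @export
default_signature_profiles <- function() {
  m <- cbind(smoking_like = smoking_like_profile(),
             apobec_like = apobec_like_profile(),
             mmr_like = mmr_like_profile())
  rownames(m) <- context_categories()
  m
}

#' Synthetic reference catalog in the COSMIC v2 dialect
#'
#' A constructed stand-in for a 30-signature reference catalog: the column
#' names follow the `"Signature <n>"` convention and the category order is
#' the shared [context_categories()] order, but the profiles are parametric
#' constructions, not the published COSMIC values.  `"Signature 4"` is the
#' smoking-like profile, `"Signature 2"` the APOBEC-like profile, and
#' `"Signature 6"` the MMR-like profile used by the synthetic cohort
#' generator; the remaining columns are distinct distractors.  Use a real
#' downloaded catalog (same layout) for analyses of real cohorts.
#'
#' @return 96 x 8 matrix, columns summing to 1.
#' @export
synthetic_signature_catalog <- function() {
  m <- cbind(
    `Signature 1` = make_profile(function(s, p5, p3)
      if (s == "T>C") 1 else 0, baseline = 0.02),
    `Signature 2` = apobec_like_profile(),
    `Signature 4` = smoking_like_profile(),
    `Signature 5` = make_profile(function(s, p5, p3) 0.2, baseline = 0.05),
    `Signature 6` = mmr_like_profile(),
    `Signature 13` = make_profile(function(s, p5, p3)
      if (p5 == "T" && s == "C>G") 1 else 0, baseline = 0.005),
    `Signature 17` = make_profile(function(s, p5, p3)
      if (s == "T>G" && p3 == "T") 1 else 0, baseline = 0.005),
    `Signature 18` = make_profile(function(s, p5, p3)
      if (s == "C>A" && p3 == "A" && p5 %in% c("G", "T")) 1 else 0,
      baseline = 0.005)
  )
  rownames(m) <- context_categories()
  m
}
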