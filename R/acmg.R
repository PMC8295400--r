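#' Tally ACMG evidence codes into strength tiers
#'
#' Counts the 2015 ACMG/AMP evidence codes carried by each variant by
#' strength tier: very strong (PVS), strong (PS), moderate (PM), supporting
#' (PP) on the pathogenic side and stand-alone (BA), strong (BS), supporting
#' (BP) on the benign side. Codes are matched by prefix, so `PS1`...`PS4`
#' all count towards `n_PS`.
#'
#' @param evidence Character vector; each element the evidence codes of one
#'   variant, semicolon- (or comma-/space-) delimited, e.g. `"PVS1;PM2"`.
#'   `NA` or empty strings mean no evidence.
#' @return A tibble with integer columns `n_PVS`, `n_PS`, `n_PM`, `n_PP`,
#'   `n_BA`, `n_BS`, `n_BP`, one row per input element.
#' @export
#' @examples
#' evidence_profile(c("PVS1;PS1", "PM1;PM2;PP3", ""))
evidence_profile <- function(evidence) {
  evidence[is.na(evidence)] <- ""
  codes <- strsplit(trimws(evidence), "[;, ]+")
  tiers <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")
  counts <- vapply(codes, function(cc) {
    cc <- cc[nzchar(cc)]
    # longest prefixes first so "PVS1" is not counted as "PS"-tier
    pre <- ifelse(startsWith(cc, "PVS"), "PVS",
           ifelse(startsWith(cc, "PS"),  "PS",
           ifelse(startsWith(cc, "PM"),  "PM",
           ifelse(startsWith(cc, "PP"),  "PP",
           ifelse(startsWith(cc, "BA"),  "BA",
           ifelse(startsWith(cc, "BS"),  "BS",
           ifelse(startsWith(cc, "BP"),  "BP", NA_character_)))))))
    if (anyNA(pre)) {
      abort(sprintf("Unrecognised ACMG evidence code(s): %s",
                    paste(cc[is.na(pre)], collapse = ", ")))
    }
    vapply(tiers, function(t) sum(pre == t), integer(1))
  }, integer(7))
  out <- as_tibble(t(counts))
  names(out) <- paste0("n_", tiers)
  out
}

#' Classify variants by the ACMG 2015 combining rules
#'
#' Applies the published evidence-combining rules to tier counts and returns
#' the five-class ACMG call. Pathogenic and likely-pathogenic rules are
#' evaluated first; a variant that simultaneously satisfies a pathogenic-side
#' and a benign-side rule is a variant of uncertain significance (VUS), as is
#' a variant satisfying no rule.
#'
#' @param profile A data frame with columns `n_PVS`, `n_PS`, `n_PM`, `n_PP`,
#'   `n_BA`, `n_BS`, `n_BP` (as from [evidence_profile()]), or a character
#'   vector of delimited evidence codes which is tallied first.
#' @return A character vector with elements in
#'   `c("P", "LP", "VUS", "LB", "B")`.
#' @export
#' @examples
#' classify_acmg(c("PVS1;PS1", "PS1;PM2", "PM2", "BA1", "BS1;BP4"))
classify_acmg <- function(profile) {
  if (is.character(profile)) profile <- evidence_profile(profile)
  profile <- as_tibble(profile)
  need <- c("n_PVS", "n_PS", "n_PM", "n_PP", "n_BA", "n_BS", "n_BP")
  if (!all(need %in% names(profile))) {
    abort("`profile` must contain the seven tier-count columns (see evidence_profile()).")
  }
  cnt <- lapply(profile[need], function(x) {
    if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort("Tier counts must be non-negative integers.")
    }
    as.integer(x)
  })
  pvs <- cnt$n_PVS; ps <- cnt$n_PS; pm <- cnt$n_PM; pp <- cnt$n_PP
  ba <- cnt$n_BA; bs <- cnt$n_BS; bp <- cnt$n_BP

  path <-
    (pvs >= 1 & (ps >= 1 | pm >= 2 | (pm >= 1 & pp >= 1) | pp >= 2)) |
    (ps >= 2) |
    (ps >= 1 & (pm >= 3 | (pm >= 2 & pp >= 2) | (pm >= 1 & pp >= 4)))
  lpath <-
    (pvs >= 1 & pm >= 1) |
    (ps >= 1 & pm >= 1) |
    (ps >= 1 & pp >= 2) |
    (pm >= 3) |
    (pm >= 2 & pp >= 2) |
    (pm >= 1 & pp >= 4)
  benign <- (ba >= 1) | (bs >= 2)
  lbenign <- (bs >= 1 & bp >= 1) | (bp >= 2)

  p_side <- path | lpath
  b_side <- benign | lbenign
  out <- rep("VUS", length(pvs))
  only_p <- p_side & !b_side
  only_b <- b_side & !p_side
  out[only_p & path] <- "P"
  out[only_p & !path] <- "LP"
  out[only_b & benign] <- "B"
  out[only_b & !benign] <- "LB"
  out
}

#' Minimal automatic evidence assigner (optional helper)
#'
#' Full evidence assignment requires external databases and expert curation
#' and is out of scope; this helper covers only the two codes that can be
#' derived from the annotations this package already consumes: `PVS1`
#' (loss-of-function consequence in a gene supplied as having a known
#' loss-of-function disease mechanism) and `PM2` (absent from, or extremely
#' rare in, all reference populations).
#'
#' @param variants Variant table with columns `gene`, `consequence`, and the
#'   population-frequency columns understood by [max_pop_maf()].
#' @param lof_genes Character vector of genes with an established
#'   loss-of-function mechanism.
#' @param pm2_threshold Maximum-population-MAF threshold below which `PM2`
#'   is assigned.
#' @return `variants` with an `auto_evidence` column (semicolon-delimited).
#' @export
assign_auto_evidence <- function(variants, lof_genes = character(),
                                 pm2_threshold = 1e-4) {
  variants <- as_tibble(variants)
  lof_classes <- c("stopgain", "splice_site", "startloss")
  maxmaf <- max_pop_maf(variants)
  ev <- character(nrow(variants))
  pvs1 <- variants$consequence %in% lof_classes & variants$gene %in% lof_genes
  pm2 <- maxmaf < pm2_threshold
  ev[pvs1] <- "PVS1"
  ev[pm2] <- ifelse(nzchar(ev[pm2]), paste0(ev[pm2], ";PM2"), "PM2")
  variants$auto_evidence <- ev
  variants
}
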