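PROTEIN_ALTERING <- c("missense", "splice_site", "stopgain", "startloss",
                      "stoploss")

CONSEQUENCE_LEVELS <- c(PROTEIN_ALTERING, "synonymous", "other")

#' Maximum population-specific minor allele frequency
#'
#' For each variant, folds every available reference-population allele
#' frequency onto the minor side (`min(f, 1 - f)`) and returns the maximum
#' across populations. Populations in which the variant is unobserved
#' (`NA` columns) are ignored; a variant absent from every population is
#' treated as novel with maximum MAF 0.
#'
#' @param variants Data frame with zero or more population frequency columns
#'   named `af_<population>` (e.g. `af_nfe`, `af_afr`), or a bare numeric
#'   matrix/data frame of frequencies.
#' @return Numeric vector of folded maximum MAFs, one per row.
#' @export
#' @examples
#' max_pop_maf(tibble::tibble(af_afr = 0.004, af_nfe = 0.012))   # 0.012
#' max_pop_maf(tibble::tibble(af_eas = 0.995))                   # 0.005
max_pop_maf <- function(variants) {
  variants <- as.data.frame(variants)
  af_cols <- grep("^af_", names(variants), value = TRUE)
  fr <- if (length(af_cols)) {
    as.matrix(variants[af_cols])
  } else if (all(vapply(variants, is.numeric, logical(1)))) {
    as.matrix(variants)
  } else {
    matrix(numeric(0), nrow = nrow(variants), ncol = 0)
  }
  if (length(fr) && any(fr < 0 | fr > 1, na.rm = TRUE)) {
    abort("Population allele frequencies must lie in [0, 1].")
  }
  if (ncol(fr) == 0L) return(rep(0, nrow(variants)))
  folded <- pmin(fr, 1 - fr)
  out <- apply(folded, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) 0 else max(r)
  })
  as.numeric(out)
}

#' Rare protein-altering filter
#'
#' A variant qualifies when its minor allele is the alternative allele, its
#' maximum population-specific minor allele frequency is below `maf_max`,
#' and its consequence is protein-altering (missense, splice site, stopgain,
#' startloss or stoploss). Synonymous variants never qualify; they are kept
#' in the tables only as a negative-control class.
#'
#' @param variants Variant table with columns `minor_is_alt`, `consequence`
#'   and population frequency columns (see [max_pop_maf()]).
#' @param maf_max Frequency threshold (default 0.01).
#' @return Logical vector.
#' @export
passes_rare_protein_altering <- function(variants, maf_max = 0.01) {
  variants <- as_tibble(variants)
  stopifnot(all(c("minor_is_alt", "consequence") %in% names(variants)))
  as.logical(variants$minor_is_alt) &
    max_pop_maf(variants) < maf_max &
    variants$consequence %in% PROTEIN_ALTERING
}

#' Drop multiallelic sites
#'
#' The analysis is restricted to biallelic SNVs: any records sharing a
#' `chrom:pos` coordinate but differing in alternative allele are all
#' removed (the site is multiallelic).
#'
#' @param variants Variant table with `chrom`, `pos`, `alt` columns.
#' @return The filtered tibble; the number of dropped records is reported
#'   via a message.
#' @export
drop_multiallelic <- function(variants) {
  variants <- as_tibble(variants)
  key <- paste(variants$chrom, variants$pos, sep = ":")
  n_alts <- vapply(split(variants$alt, key), function(a) length(unique(a)),
                   integer(1))
  bad_sites <- names(n_alts)[n_alts > 1L]
  keep <- !(key %in% bad_sites)
  if (any(!keep)) {
    inform(sprintf("Dropped %d record(s) at %d multiallelic site(s).",
                   sum(!keep), length(bad_sites)))
  }
  variants[keep, , drop = FALSE]
}

#' Select pathogenic / likely pathogenic analysis variants
#'
#' Returns the (order-preserving) row indices of variants that pass
#' [passes_rare_protein_altering()] and whose ACMG class is `P` or `LP`.
#' If the table has no `acmg_class` column it is derived from the
#' `evidence` column via [classify_acmg()].
#'
#' @inheritParams passes_rare_protein_altering
#' @return Integer vector of row indices into `variants`.
#' @export
select_plp <- function(variants, maf_max = 0.01) {
  variants <- as_tibble(variants)
  cls <- if ("acmg_class" %in% names(variants)) {
    variants$acmg_class
  } else if ("evidence" %in% names(variants)) {
    classify_acmg(variants$evidence)
  } else {
    abort("`variants` needs an `acmg_class` or `evidence` column.")
  }
  which(passes_rare_protein_altering(variants, maf_max) & cls %in% c("P", "LP"))
}
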