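#' Stratum layout of a seven-group bipolar sequencing consortium design
#'
#' Returns the per-stratum case/control sizes of a four-study exome
#' case-control design in which one study contributes four ancestry groups
#' (seven analysis strata in total: three large European-ancestry studies
#' with roughly 1:1 or 1:2 case:control ratios, plus four small
#' ancestry-specific strata). These sizes are the default cohort layout of
#' [cohort_config()].
#'
#' @param scale Positive scaling factor applied to every stratum size
#'   (rounded, with a floor of 10 individuals per arm). `scale = 1` gives the
#'   full design of 3,987 cases and 5,322 controls.
#' @return A tibble with columns `stratum`, `ancestry`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' bsc_strata()
#' bsc_strata(scale = 0.25)
bsc_strata <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  out <- tibble(
    stratum    = c("BRIDGES", "RareBLISS", "Sweden", "KPNC-EUR",
                   "KPNC-AFR", "KPNC-LAT", "KPNC-EAS"),
    ancestry   = c("EUR", "EUR", "EUR", "EUR", "AFR", "LAT", "EAS"),
    n_cases    = c(1712L, 961L, 831L, 192L, 96L, 98L, 97L),
    n_controls = c(1844L, 1039L, 1956L, 192L, 95L, 100L, 96L)
  )
  if (scale != 1) {
    out$n_cases    <- pmax(10L, as.integer(round(out$n_cases * scale)))
    out$n_controls <- pmax(10L, as.integer(round(out$n_controls * scale)))
  }
  out
}

#' Configure the synthetic multi-stratum cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults encode
#' the structure of a large exome case-control consortium: seven strata with
#' fixed case/control counts, a rare-variant site frequency spectrum in which
#' 81% of pathogenic/likely-pathogenic (P-LP) variants are singletons, and
#' 0.7% of exonic SNVs classified P-LP, with about 53 variants per gene so
#' that the per-gene P-LP density (~0.37 variants per gene) matches what
#' large exome studies report.
#'
#' @param strata Data frame with columns `stratum`, `n_cases`, `n_controls`
#'   (optionally `ancestry`); defaults to [bsc_strata()].
#' @param n_genes Number of genes in the simulated exome universe.
#' @param mean_variants_per_gene Mean of the (1 + Poisson) draw for variants
#'   per gene.
#' @param singleton_fraction Fraction of P-LP variants that are cohort
#'   singletons (minor allele count 1).
#' @param plp_fraction Fraction of exonic SNVs classified P or LP.
#' @param nonsingleton_mean_mac Mean minor allele count of non-singleton P-LP
#'   variants (geometric tail starting at 2).
#' @param gene_sets Either a named integer vector of gene-set sizes (sets are
#'   drawn uniformly from the gene universe) or a named list of gene-id
#'   character vectors.
#' @param enriched_sets Named numeric vector of per-P-LP-allele odds ratios,
#'   names matching `gene_sets`; unnamed sets are null. Empty (default)
#'   simulates the global null.
#' @param n_pcs Number of principal components attached to each sample.
#' @param beta_sex,beta_pc Log-odds effects of sex and of each PC on disease
#'   in the generating logistic model (recycled/zero-padded over PCs).
#' @param missing_rate Per-genotype missingness probability (applied to
#'   carrier genotypes; see the methods vignette).
#' @param common_fraction Fraction of non-P-LP variants given a common
#'   (population MAF 1-10%) frequency so that frequency filters have work to
#'   do.
#' @param minor_ref_fraction Fraction of non-P-LP variants whose minor allele
#'   is the reference allele (excluded by the minor-is-alt filter).
#' @param novel_plp_fraction Fraction of P-LP variants absent from every
#'   reference population.
#' @param structured_fraction Fraction of variants whose alleles concentrate
#'   in one "home" stratum (stratum-level frequency shifts).
#' @param seed Integer seed from which all randomness is derived.
#' @return An object of class `cohort_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(strata = bsc_strata(),
                          n_genes = 2000L,
                          mean_variants_per_gene = 53,
                          singleton_fraction = 0.81,
                          plp_fraction = 0.007,
                          nonsingleton_mean_mac = 5.26,
                          gene_sets = default_gene_set_sizes(),
                          enriched_sets = numeric(),
                          n_pcs = 10L,
                          beta_sex = 0.25,
                          beta_pc = c(0.15, -0.1),
                          missing_rate = 0,
                          common_fraction = 0.05,
                          minor_ref_fraction = 0.01,
                          novel_plp_fraction = 0.38,
                          structured_fraction = 0.2,
                          seed = 1L) {
  strata <- as_tibble(strata)
  req <- c("stratum", "n_cases", "n_controls")
  if (!all(req %in% names(strata))) {
    abort("`strata` needs columns stratum, n_cases, n_controls.")
  }
  stop_if_not_count(strata$n_cases, "n_cases")
  stop_if_not_count(strata$n_controls, "n_controls")
  if (anyDuplicated(strata$stratum)) abort("Stratum labels must be unique.")
  if (!"ancestry" %in% names(strata)) strata$ancestry <- "EUR"
  n_genes <- stop_if_not_count(n_genes, "n_genes")
  n_pcs <- stop_if_not_count(n_pcs, "n_pcs")
  stopifnot(mean_variants_per_gene >= 1, nonsingleton_mean_mac > 2)
  stop_if_not_prob(singleton_fraction, "singleton_fraction")
  stop_if_not_prob(plp_fraction, "plp_fraction")
  stop_if_not_prob(missing_rate, "missing_rate")
  stop_if_not_prob(common_fraction, "common_fraction")
  stop_if_not_prob(minor_ref_fraction, "minor_ref_fraction")
  stop_if_not_prob(novel_plp_fraction, "novel_plp_fraction")
  stop_if_not_prob(structured_fraction, "structured_fraction")
  if (length(enriched_sets)) {
    if (is.null(names(enriched_sets)) || any(!nzchar(names(enriched_sets)))) {
      abort("`enriched_sets` must be a named numeric vector of odds ratios.")
    }
    if (any(enriched_sets <= 0)) abort("Enrichment odds ratios must be > 0.")
    set_names <- if (is.list(gene_sets)) names(gene_sets) else names(gene_sets)
    missing_sets <- setdiff(names(enriched_sets), set_names)
    if (length(missing_sets)) {
      abort(sprintf("Enriched set(s) not among gene_sets: %s",
                    paste(missing_sets, collapse = ", ")))
    }
  }
  if (is.list(gene_sets)) {
    bad <- unlist(gene_sets)[!grepl("^GENE", unlist(gene_sets))]
    if (length(bad)) abort("Explicit gene sets must use GENE<k> identifiers.")
  } else {
    stop_if_not_count(gene_sets, "gene_sets sizes")
    if (any(gene_sets > n_genes)) abort("Gene-set size exceeds gene universe.")
  }
  structure(
    list(
      strata = strata, n_genes = n_genes,
      mean_variants_per_gene = mean_variants_per_gene,
      singleton_fraction = singleton_fraction,
      plp_fraction = plp_fraction,
      nonsingleton_mean_mac = nonsingleton_mean_mac,
      gene_sets = gene_sets, enriched_sets = enriched_sets,
      n_pcs = n_pcs, beta_sex = beta_sex, beta_pc = beta_pc,
      missing_rate = missing_rate, common_fraction = common_fraction,
      minor_ref_fraction = minor_ref_fraction,
      novel_plp_fraction = novel_plp_fraction,
      structured_fraction = structured_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default gene-set size layout
#'
#' Ten candidate sets spanning the focused-to-broad size range typical of
#' gene-set burden analyses (81 to 623 genes within a 2,000-gene universe).
#'
#' @return Named integer vector of set sizes.
#' @export
default_gene_set_sizes <- function() {
  c(set01 = 165L, set02 = 153L, set03 = 81L, set04 = 623L, set05 = 550L,
    set06 = 342L, set07 = 306L, set08 = 123L, set09 = 323L, set10 = 251L)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  strata: %d (%s cases / %s controls)\n", nrow(x$strata),
              format(sum(x$strata$n_cases), big.mark = ","),
              format(sum(x$strata$n_controls), big.mark = ",")))
  cat(sprintf("  genes: %d, ~%.0f variants/gene, P-LP fraction %.3f, singleton fraction %.2f\n",
              x$n_genes, x$mean_variants_per_gene, x$plp_fraction,
              x$singleton_fraction))
  if (length(x$enriched_sets)) {
    cat("  enriched sets:",
        paste(sprintf("%s (OR %.2f)", names(x$enriched_sets), x$enriched_sets),
              collapse = ", "), "\n")
  } else {
    cat("  enriched sets: none (global null)\n")
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
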