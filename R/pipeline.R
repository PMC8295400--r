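#' Run the full discovery burden analysis on a cohort
#'
#' Executes the complete gene-set discovery workflow: select qualifying
#' P-LP variants, count per-individual set burden, fit Firth logistic
#' regression within each stratum, combine strata by the weighted Z-score
#' method with an inverse-variance pooled odds ratio, adjust the one-sided
#' p values across the supplied gene-set family by Holm, and validate each
#' set with the stratified CMH statistic calibrated against an empirical
#' null of random same-size gene sets.
#'
#' @param cohort A `rare_cohort` (or a list with `variants`, `genotypes`,
#'   `samples` and `gene_sets`).
#' @param gene_sets Named list of gene-id vectors; defaults to
#'   `cohort$gene_sets`. The Holm family is exactly this list.
#' @param n_pcs Principal components adjusted for in each stratum
#'   (default 5).
#' @param include_total_burden Also adjust for the per-individual total
#'   non-reference allele burden (replication-style model).
#' @param B Random gene sets per empirical null (default 10000; `B = 0`
#'   skips the CMH calibration).
#' @param seed Seed for the empirical-null draws.
#' @param weights Meta-analysis weight type, see [neff_weights()].
#' @param out_dir Optional directory; when given, results, per-stratum
#'   fits and a JSON run manifest are written as TSV/JSON.
#' @return An object of class `discovery_result`: `results` (one row per
#'   gene set: sizes, P-LP allele counts in cases and controls, pooled OR
#'   with 95% CI, one-sided and Holm-adjusted p, CMH statistic and
#'   empirical p), `per_stratum` (all stratum-level Firth fits) and
#'   `manifest`.
#' @export
run_discovery <- function(cohort, gene_sets = cohort$gene_sets, n_pcs = 5,
                          include_total_burden = FALSE, B = 10000L,
                          seed = 1L, weights = c("neff", "n"),
                          out_dir = NULL) {
  weights <- match.arg(weights)
  if (is.null(gene_sets) || !length(gene_sets)) {
    abort("`gene_sets` is empty: supply at least one gene set.")
  }
  samples <- cohort$samples
  plp_idx <- select_plp(cohort$variants)
  gb <- gene_burden_matrix(cohort, plp_idx)
  total_b <- if (include_total_burden) total_nonref_burden(cohort$genotypes) else NULL
  strata <- unique(samples$stratum)

  one_set <- function(set_name) {
    genes <- gene_sets[[set_name]]
    burden <- set_burden(gb, genes)
    fits <- lapply(strata, function(s) {
      suppressWarnings(firth_fit(burden_design(samples, burden, s,
                                               n_pcs = n_pcs,
                                               total_burden = total_b)))
    })
    meta <- tryCatch(suppressMessages(burden_meta(fits, weights = weights)),
                     error = function(e) NULL)
    carriers_case <- sum(burden[samples$case == 1])
    carriers_ctrl <- sum(burden[samples$case == 0])
    cmh_row <- if (B > 0 && !is.null(meta)) {
      emp <- empirical_p(gb, samples$case, samples$stratum, genes, B = B,
                         seed = derive_seed(seed, set_name),
                         gene_universe = unique(cohort$variants$gene))
      tibble(cmh_stat = emp$observed_stat, p_empirical = emp$p_empirical)
    } else {
      tibble(cmh_stat = NA_real_, p_empirical = NA_real_)
    }
    res <- tibble(
      gene_set = set_name,
      n_genes = length(unique(genes)),
      n_genes_plp = sum(unique(genes) %in% colnames(gb)[colSums(gb) > 0]),
      case_plp_count = carriers_case,
      control_plp_count = carriers_ctrl,
      or = if (is.null(meta)) NA_real_ else meta$pooled_or,
      ci_low = if (is.null(meta)) NA_real_ else meta$ci95[1],
      ci_high = if (is.null(meta)) NA_real_ else meta$ci95[2],
      combined_z = if (is.null(meta)) NA_real_ else meta$combined_z,
      p_one_sided = if (is.null(meta)) NA_real_ else meta$p_one_sided
    )
    per <- dplyr::mutate(purrr::map_dfr(fits, glance), gene_set = set_name)
    list(res = dplyr::bind_cols(res, cmh_row), per = per)
  }

  pieces <- lapply(names(gene_sets), one_set)
  results <- purrr::map_dfr(pieces, "res")
  adj <- rep(NA_real_, nrow(results))
  ok <- !is.na(results$p_one_sided)
  if (any(ok)) adj[ok] <- holm_adjust(results$p_one_sided[ok])
  results$p_holm <- adj
  per_stratum <- purrr::map_dfr(pieces, "per")

  manifest <- list(
    config_hash = rlang::hash(list(cohort$config, gene_sets, n_pcs,
                                   include_total_burden, B, seed, weights)),
    seed = as.integer(seed),
    n_samples = nrow(samples),
    n_variants = nrow(cohort$variants),
    n_plp_selected = length(plp_idx),
    n_gene_sets = length(gene_sets),
    weights = weights,
    n_pcs = n_pcs,
    B = as.integer(B)
  )
  out <- structure(list(results = results, per_stratum = per_stratum,
                        manifest = manifest),
                   class = "discovery_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(results, file.path(out_dir, "gene_set_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(per_stratum, file.path(out_dir, "per_stratum_fits.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %d gene set(s), %d qualifying variants\n",
              nrow(x$results), x$manifest$n_plp_selected))
  print(x$results, n = nrow(x$results))
  invisible(x)
}

#' Per-gene burden scan
#'
#' Runs the stratified Firth + weighted-Z meta-analysis for each gene with
#' at least one qualifying P-LP variant (or a supplied subset of genes).
#'
#' @inheritParams run_discovery
#' @param genes Genes to test; default all genes with qualifying variants.
#' @return Tibble: one row per gene with pooled OR, CI, combined Z,
#'   one-sided and Holm-adjusted p.
#' @export
burden_gene_scan <- function(cohort, genes = NULL, n_pcs = 5,
                             include_total_burden = FALSE,
                             weights = c("neff", "n")) {
  weights <- match.arg(weights)
  gb <- gene_burden_matrix(cohort)
  if (is.null(genes)) genes <- colnames(gb)[colSums(gb) > 0]
  total_b <- if (include_total_burden) total_nonref_burden(cohort$genotypes) else NULL
  samples <- cohort$samples
  strata <- unique(samples$stratum)
  res <- purrr::map_dfr(genes, function(g) {
    burden <- set_burden(gb, g)
    fits <- lapply(strata, function(s) {
      suppressWarnings(firth_fit(burden_design(samples, burden, s,
                                               n_pcs = n_pcs,
                                               total_burden = total_b)))
    })
    meta <- tryCatch(suppressMessages(burden_meta(fits, weights = weights)),
                     error = function(e) NULL)
    tibble(
      gene = g,
      n_carriers = sum(burden >= 1),
      or = if (is.null(meta)) NA_real_ else meta$pooled_or,
      ci_low = if (is.null(meta)) NA_real_ else meta$ci95[1],
      ci_high = if (is.null(meta)) NA_real_ else meta$ci95[2],
      combined_z = if (is.null(meta)) NA_real_ else meta$combined_z,
      p_one_sided = if (is.null(meta)) NA_real_ else meta$p_one_sided
    )
  })
  ok <- !is.na(res$p_one_sided)
  res$p_holm <- NA_real_
  if (any(ok)) res$p_holm[ok] <- holm_adjust(res$p_one_sided[ok])
  res
}

#' Descriptive cohort report
#'
#' Summarizes the classified variant spectrum the way consortium papers
#' report it: counts per ACMG class, mean pathogenic and likely-pathogenic
#' alleles carried per individual, the allele-count spectrum of qualifying
#' P-LP variants (singleton fraction), and the fraction of P-LP variants
#' absent from every reference population.
#'
#' @param cohort A `rare_cohort`.
#' @return An object of class `cohort_report` (a list of tibbles/scalars).
#' @export
descriptive_report <- function(cohort) {
  v <- cohort$variants
  n <- nrow(cohort$samples)
  class_counts <- dplyr::count(v, .data$acmg_class, name = "n_variants")
  plp_idx <- select_plp(v)
  plp <- v[plp_idx, , drop = FALSE]
  af_cols <- grep("^af_", names(v), value = TRUE)
  novel <- if (length(af_cols) && nrow(plp)) {
    mean(rowSums(!is.na(as.matrix(plp[af_cols]))) == 0)
  } else {
    NA_real_
  }
  mac <- plp$cohort_mac
  structure(
    list(
      n_samples = n,
      n_variants = nrow(v),
      class_counts = class_counts,
      n_plp_selected = nrow(plp),
      plp_fraction = nrow(plp) / nrow(v),
      mean_p_per_individual = sum(plp$cohort_mac[plp$acmg_class == "P"]) / n,
      mean_lp_per_individual = sum(plp$cohort_mac[plp$acmg_class == "LP"]) / n,
      singleton_fraction = if (length(mac)) mean(mac == 1) else NA_real_,
      novel_fraction = novel,
      mac_spectrum = if (length(mac)) {
        dplyr::count(tibble(mac = pmin(mac, 10)), .data$mac, name = "n_variants")
      } else {
        tibble(mac = integer(), n_variants = integer())
      }
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  %s variants in %s individuals; %s selected P-LP (%.2f%% of SNVs)\n",
              format(x$n_variants, big.mark = ","),
              format(x$n_samples, big.mark = ","),
              format(x$n_plp_selected, big.mark = ","),
              100 * x$plp_fraction))
  cat(sprintf("  mean per individual: %.2f P, %.2f LP alleles\n",
              x$mean_p_per_individual, x$mean_lp_per_individual))
  cat(sprintf("  singleton fraction of P-LP variants: %.3f; novel fraction: %.3f\n",
              x$singleton_fraction, x$novel_fraction))
  invisible(x)
}

#' Synonymous-variant negative control
#'
#' Runs the identical stratified Firth + meta-analysis pipeline on rare
#' synonymous variants exome-wide. Synonymous changes are not expected to
#' alter protein function, so under a sound analysis the pooled odds ratio
#' should sit at 1; a deviation flags residual confounding between cases
#' and controls.
#'
#' @inheritParams run_discovery
#' @param maf_max Rarity threshold on the maximum population MAF.
#' @return A `burden_meta` object (or `NULL` with a warning when the cohort
#'   carries no rare synonymous variants).
#' @export
synonymous_calibration <- function(cohort, n_pcs = 5, maf_max = 0.01,
                                   weights = c("neff", "n")) {
  weights <- match.arg(weights)
  v <- cohort$variants
  idx <- which(v$consequence == "synonymous" &
                 as.logical(v$minor_is_alt) &
                 max_pop_maf(v) < maf_max)
  if (!length(idx)) {
    warn("No rare synonymous variants in the cohort; negative control degenerate.")
    return(NULL)
  }
  burden <- count_burden(cohort$genotypes, idx)
  samples <- cohort$samples
  fits <- lapply(unique(samples$stratum), function(s) {
    suppressWarnings(firth_fit(burden_design(samples, burden, s, n_pcs = n_pcs)))
  })
  suppressMessages(burden_meta(fits, weights = weights))
}
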