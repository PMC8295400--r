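#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set exchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Reading delegates to
#' `fgsea::gmtPathways()` when available.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
  }
  if (!length(sets)) abort("Empty gene-set file.")
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Expects a TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, population frequency columns `af_*`, a semicolon-delimited
#' `evidence` column and optionally `minor_is_alt`. Multiallelic sites are
#' dropped at ingest and the ACMG class is derived from the evidence codes
#' when absent.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_variants <- function(path) {
  v <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(need, names(v))
  if (length(miss)) {
    abort(sprintf("Variant table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  v <- drop_multiallelic(v)
  if (!"minor_is_alt" %in% names(v)) v$minor_is_alt <- TRUE
  if (!"acmg_class" %in% names(v) && "evidence" %in% names(v)) {
    v$acmg_class <- classify_acmg(v$evidence)
  }
  v
}

#' Read a sample covariate table
#'
#' @param path TSV with columns `sample_id`, `stratum`, `case`, `sex` and
#'   `PC1`, `PC2`, ... columns.
#' @return A tibble.
#' @export
read_samples <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "stratum", "case", "sex")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    abort(sprintf("Sample table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  s
}

#' Write a simulated cohort to disk
#'
#' Emits the artifacts downstream tools expect: a minimal VCF 4.2 with
#' GT-only genotypes (via the vcfR package), variant annotation and sample
#' covariate TSVs, and the gene sets as GMT.
#'
#' @param cohort A `rare_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    vcf = file.path(dir, "genotypes.vcf.gz")
  )
  readr::write_tsv(cohort$variants, paths[["variants"]], progress = FALSE)
  readr::write_tsv(cohort$samples, paths[["samples"]], progress = FALSE)
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  rlang::check_installed("vcfR", reason = "to write VCF output")
  gm <- as.matrix(cohort$genotypes)
  gt <- matrix("0/0", nrow(gm), ncol(gm))
  gt[gm == 1] <- "0/1"
  gt[gm == 2] <- "1/1"
  gt[is.na(gm)] <- "./."
  gt <- t(gt)
  colnames(gt) <- rownames(gm)
  v <- cohort$variants
  fix <- cbind(CHROM = as.character(v$chrom), POS = as.character(v$pos),
               ID = v$variant_id, REF = v$ref, ALT = v$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix,
                      gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file = paths[["vcf"]])
  invisible(paths)
}

#' Read GT genotypes from a VCF into a dosage matrix
#'
#' @param path VCF (optionally gzipped) with GT fields.
#' @return Sparse individuals x variants matrix of alternative-allele
#'   counts (`NA` = missing genotype).
#' @export
read_cohort_vcf <- function(path) {
  rlang::check_installed("vcfR", reason = "to read VCF input")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- matrix(0, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  counts[gt %in% c("1/1", "1|1")] <- 2
  counts[is.na(gt) | gt %in% c("./.", ".|.", ".")] <- NA
  out <- t(counts)
  colnames(out) <- vcfR::getID(vcf)
  Matrix::Matrix(out, sparse = TRUE)
}

#' Build a cohort configuration from a YAML file
#'
#' Top-level YAML keys mirror the arguments of [cohort_config()]; `strata`
#' is a list of `{stratum, n_cases, n_controls, ancestry}` maps and
#' `enriched_sets` a map of set name to odds ratio.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `seed` entry.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$strata)) {
    args$strata <- dplyr::bind_rows(lapply(y$strata, as_tibble))
  }
  if (!is.null(y$gene_sets) && !is.list(y$gene_sets[[1]])) {
    args$gene_sets <- unlist(y$gene_sets)
  }
  if (!is.null(y$enriched_sets)) args$enriched_sets <- unlist(y$enriched_sets)
  if (!is.null(seed)) args$seed <- seed
  do.call(cohort_config, args[intersect(names(args), names(formals(cohort_config)))])
}
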