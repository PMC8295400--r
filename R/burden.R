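#' Per-individual qualifying-allele burden
#'
#' Sums minor-allele counts across the selected variants for each
#' individual. Missing genotypes contribute 0 alleles (sequencing-depth QC
#' is assumed upstream; mean imputation is available via `missing`).
#'
#' @param genotypes Numeric matrix or sparse Matrix, individuals x variants.
#' @param variant_indices Column indices (or names) of the qualifying
#'   variants; an empty selection yields an all-zero vector.
#' @param missing Either `"zero"` (default) or `"mean"` (per-variant mean
#'   imputation of missing genotypes).
#' @return Numeric vector, one burden per individual.
#' @export
count_burden <- function(genotypes, variant_indices, missing = c("zero", "mean")) {
  missing <- match.arg(missing)
  if (is.character(variant_indices)) {
    variant_indices <- match(variant_indices, colnames(genotypes))
  }
  if (anyNA(variant_indices) ||
      (length(variant_indices) && max(variant_indices) > ncol(genotypes))) {
    abort("`variant_indices` out of range of the genotype matrix.")
  }
  if (!length(variant_indices)) return(numeric(nrow(genotypes)))
  sub <- genotypes[, variant_indices, drop = FALSE]
  if (missing == "mean" && anyNA(sub)) {
    sub <- as.matrix(sub)
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(sub))) sub[is.na(sub[, j]), j] <- mu[j]
    return(rowSums(sub))
  }
  as.numeric(Matrix::rowSums(sub, na.rm = TRUE))
}

#' Total non-reference allele burden
#'
#' Per-individual sum of minor-allele counts across all variants (before any
#' pathogenicity selection), used as an additional covariate to absorb
#' platform and coverage differences between cohorts.
#'
#' @inheritParams count_burden
#' @return Numeric vector.
#' @export
total_nonref_burden <- function(genotypes) {
  as.numeric(Matrix::rowSums(genotypes, na.rm = TRUE))
}

#' Per-gene P-LP burden matrix
#'
#' Collapses the genotype matrix to an individuals x genes matrix of P-LP
#' allele counts, the workhorse input for gene-set burden and for the
#' random-gene-set empirical null (set burden is then a row sum over the
#' set's columns).
#'
#' @param cohort A `rare_cohort`, or a list with `variants` and `genotypes`.
#' @param plp_index Optional row indices of qualifying variants; defaults to
#'   [select_plp()] on the variant table.
#' @return Dense numeric matrix, individuals x genes (genes with at least
#'   one qualifying variant).
#' @export
gene_burden_matrix <- function(cohort, plp_index = NULL) {
  variants <- cohort$variants
  if (is.null(plp_index)) plp_index <- select_plp(variants)
  if (!length(plp_index)) {
    return(matrix(0, nrow(cohort$genotypes), 0,
                  dimnames = list(rownames(cohort$genotypes), character(0))))
  }
  genes <- variants$gene[plp_index]
  ug <- sort(unique(genes))
  ind <- Matrix::sparseMatrix(
    i = seq_along(plp_index), j = match(genes, ug), x = 1,
    dims = c(length(plp_index), length(ug))
  )
  sub <- cohort$genotypes[, plp_index, drop = FALSE]
  if (inherits(sub, "sparseMatrix")) {
    if (anyNA(sub@x)) sub@x[is.na(sub@x)] <- 0
  } else {
    sub[is.na(sub)] <- 0
    sub <- Matrix::Matrix(sub, sparse = TRUE)
  }
  out <- as.matrix(sub %*% ind)
  dimnames(out) <- list(rownames(cohort$genotypes), ug)
  out
}

#' Assemble a per-stratum burden regression design
#'
#' @param samples Sample table with `case`, `sex`, `stratum` and `PC*`
#'   columns.
#' @param burden Per-individual qualifying-allele count, aligned to
#'   `samples`.
#' @param stratum Stratum label to subset to.
#' @param n_pcs Number of principal components to adjust for (default 5).
#' @param total_burden Optional per-individual total non-reference burden to
#'   include as a covariate (replication-style adjustment).
#' @return A list with `y`, `x` (model matrix whose first non-intercept
#'   column is the burden term) and `stratum`.
#' @export
burden_design <- function(samples, burden, stratum, n_pcs = 5,
                          total_burden = NULL) {
  stopifnot(length(burden) == nrow(samples))
  keep <- samples$stratum == stratum
  if (!any(keep)) abort(sprintf("Unknown stratum '%s'.", stratum))
  pcs_all <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  n_pcs <- min(n_pcs, length(pcs_all))
  pcs <- pcs_all[seq_len(n_pcs)]
  x <- cbind(
    `(Intercept)` = 1,
    burden = burden[keep],
    sex = samples$sex[keep],
    as.matrix(samples[keep, pcs, drop = FALSE])
  )
  if (!is.null(total_burden)) {
    x <- cbind(x, total_burden = total_burden[keep])
  }
  list(y = samples$case[keep], x = x, stratum = stratum)
}
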