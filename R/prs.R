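#' Cross-study SNP filters for polygenic scoring
#'
#' Retains SNPs that are well imputed (info > `info_min`) in every study,
#' common enough (folded MAF > `maf_min`) in every study, and whose
#' per-study allele frequency never deviates from the cross-study mean
#' frequency by more than `freq_dev_max`.
#'
#' @param stats Summary-statistics tibble with a `snp` column.
#' @param study_freqs Tibble: `snp` plus one frequency column per study.
#' @param study_info Tibble: `snp` plus one info/imputation-quality column
#'   per study; omit (`NULL`) to skip the info filter.
#' @param info_min,maf_min,freq_dev_max Filter thresholds (defaults 0.5,
#'   0.01, 0.2).
#' @return `stats` restricted to the retained SNPs, in input order.
#' @export
filter_snps <- function(stats, study_freqs, study_info = NULL,
                        info_min = 0.5, maf_min = 0.01, freq_dev_max = 0.2) {
  stats <- as_tibble(stats)
  stopifnot("snp" %in% names(stats), "snp" %in% names(study_freqs))
  fmat <- as.matrix(study_freqs[setdiff(names(study_freqs), "snp")])
  if (!ncol(fmat)) abort("`study_freqs` has no study columns.")
  rownames(fmat) <- study_freqs$snp
  fmat <- fmat[stats$snp, , drop = FALSE]
  if (anyNA(fmat)) abort("Missing study frequency for some SNPs.")
  keep <- rep(TRUE, nrow(stats))
  if (!is.null(study_info)) {
    imat <- as.matrix(study_info[setdiff(names(study_info), "snp")])
    rownames(imat) <- study_info$snp
    imat <- imat[stats$snp, , drop = FALSE]
    keep <- keep & apply(imat, 1L, min) > info_min
  }
  maf <- pmin(fmat, 1 - fmat)
  keep <- keep & apply(maf, 1L, min) > maf_min
  dev <- abs(fmat - rowMeans(fmat))
  keep <- keep & apply(dev, 1L, max) <= freq_dev_max
  stats[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Selects index SNPs by ascending association p value: the smallest-p
#' unclaimed SNP becomes an index and claims every unclaimed SNP within
#' `window_bp` of it (closed interval around the index position) whose
#' squared correlation with it exceeds `r2_threshold`. Ties on p are broken
#' by position, then by SNP id.
#'
#' @param stats Tibble with columns `snp`, `pos`, `p` (optionally `chrom`;
#'   windows never span chromosomes).
#' @param r2 Symmetric matrix of squared allelic correlations with
#'   dimnames matching `stats$snp`.
#' @param window_bp Physical window half-width in base pairs (default 1e6).
#' @param r2_threshold LD threshold above which a neighbour is claimed
#'   (default 0.1).
#' @return Character vector of index SNP ids (in selection order).
#' @export
ld_clump <- function(stats, r2, window_bp = 1e6, r2_threshold = 0.1) {
  stats <- as_tibble(stats)
  stopifnot(all(c("snp", "pos", "p") %in% names(stats)))
  if (!isTRUE(all.equal(r2, t(r2), tolerance = 1e-8))) {
    abort("`r2` must be symmetric.")
  }
  r2 <- r2[stats$snp, stats$snp, drop = FALSE]
  chrom <- if ("chrom" %in% names(stats)) stats$chrom else rep(1L, nrow(stats))
  ord <- order(stats$p, stats$pos, stats$snp)
  claimed <- rep(FALSE, nrow(stats))
  index <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    index <- c(index, stats$snp[i])
    claimed[i] <- TRUE
    near <- !claimed &
      chrom == chrom[i] &
      abs(stats$pos - stats$pos[i]) <= window_bp &
      r2[i, ] > r2_threshold
    claimed[near] <- TRUE
  }
  index
}

#' Score individuals from dosages and GWAS weights
#'
#' Per-individual weighted sum of risk-allele dosages,
#' `sum_j dosage_ij * w_j` over the selected SNPs. When the cohort's coded
#' allele differs from the summary-statistic effect allele the dosage is
#' complemented (`2 - d`) so the weight always multiplies the effect-allele
#' dose.
#'
#' @param dosages Individuals x SNPs matrix of coded-allele dosages in
#'   `[0, 2]`, with SNP column names.
#' @param stats Summary statistics with `snp`, `log_or`, `effect_allele`.
#' @param snps SNPs to score over (default: all in `stats`). Must be
#'   present in both `stats` and `dosages`.
#' @param coded_alleles Optional named character vector giving the cohort's
#'   coded allele per SNP; defaults to the effect allele (no flips).
#' @return Numeric score per individual.
#' @export
score_individuals <- function(dosages, stats, snps = stats$snp,
                              coded_alleles = NULL) {
  stats <- as_tibble(stats)
  snps <- unique(snps)
  miss <- setdiff(snps, intersect(colnames(dosages), stats$snp))
  if (length(miss)) {
    abort(sprintf("SNP(s) absent from dosages or stats: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  w <- stats$log_or[match(snps, stats$snp)]
  ea <- stats$effect_allele[match(snps, stats$snp)]
  d <- as.matrix(dosages[, snps, drop = FALSE])
  if (!is.null(coded_alleles)) {
    flip <- coded_alleles[snps] != ea
    flip[is.na(flip)] <- FALSE
    d[, flip] <- 2 - d[, flip]
  }
  drop(d %*% w)
}

#' Per-stratum PRS association with inverse-variance meta-analysis
#'
#' Standard (unpenalized) logistic regression of case status on the
#' polygenic score plus covariates within each stratum, combined across
#' strata by inverse-variance weighting of the score coefficients.
#' Nagelkerke pseudo-R2 is reported per stratum as the variance-explained
#' measure.
#'
#' @param samples Sample table with `case`, `sex`, `stratum`, `PC*` columns.
#' @param score Per-individual polygenic score aligned with `samples`.
#' @param n_pcs Number of PCs to adjust for (default 5).
#' @return A list with `per_stratum` (tibble: stratum, beta, se, p,
#'   nagelkerke_r2, n) and `meta` (beta, se, z, p two-sided).
#' @export
prs_association <- function(samples, score, n_pcs = 5) {
  stopifnot(length(score) == nrow(samples))
  if (stats::sd(score) == 0) abort("Polygenic score has zero variance.")
  pcs_all <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  pcs <- pcs_all[seq_len(min(n_pcs, length(pcs_all)))]
  per <- purrr::map_dfr(unique(samples$stratum), function(s) {
    rows <- samples$stratum == s
    if (stats::sd(score[rows]) == 0) {
      abort(sprintf("Score is constant within stratum '%s'.", s))
    }
    dat <- data.frame(case = samples$case[rows], score = score[rows],
                      sex = samples$sex[rows],
                      samples[rows, pcs, drop = FALSE])
    fit <- stats::glm(case ~ ., data = dat, family = stats::binomial())
    null_fit <- stats::glm(case ~ 1, data = dat, family = stats::binomial())
    n <- nrow(dat)
    cox_snell <- 1 - exp((fit$deviance - null_fit$deviance) / n)
    r2 <- cox_snell / (1 - exp(-null_fit$deviance / n))
    cf <- unname(summary(fit)$coefficients["score", ])
    tibble(stratum = s, beta = cf[1], se = cf[2],
           p = cf[4], nagelkerke_r2 = r2, n = n)
  })
  w <- 1 / per$se^2
  beta <- sum(w * per$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  list(
    per_stratum = per,
    meta = tibble(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)))
  )
}
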