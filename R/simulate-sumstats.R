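#' Simulate GWAS summary statistics with block LD structure
#'
#' Generates a reference dosage panel with block-diagonal linkage
#' disequilibrium (a Gaussian copula over haplotypes within consecutive
#' blocks), per-SNP GWAS summary statistics (effect-allele log odds ratios
#' with sampling noise at a nominal GWAS sample size, Wald p values,
#' frequencies, imputation-quality scores) and the empirical pairwise r2
#' matrix of the panel. Feeds the polygenic-score pipeline
#' ([filter_snps()], [ld_clump()], [score_individuals()]).
#'
#' @param n_snps Number of SNPs.
#' @param block_size SNPs per LD block (the last block may be shorter).
#' @param r_within Latent within-block correlation of the copula.
#' @param n_ref Reference-panel individuals.
#' @param n_causal Number of causal SNPs (true effects `N(0, effect_sd^2)`).
#' @param effect_sd Causal effect-size standard deviation (log-OR scale).
#' @param n_gwas Nominal GWAS sample size controlling the sampling noise of
#'   the summary statistics.
#' @param n_studies Number of per-study frequency/info columns to emit.
#' @param seed Integer seed.
#' @return A list: `sumstats` (tibble with `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `log_or`, `se`, `p`, `freq`, `info`,
#'   `causal`), `r2` (empirical squared-correlation matrix of the panel),
#'   `dosages` (n_ref x n_snps), `study_freqs`, `study_info`.
#' @export
simulate_sumstats_and_ld <- function(n_snps = 200L, block_size = 10L,
                                     r_within = 0.9, n_ref = 500L,
                                     n_causal = 20L, effect_sd = 0.1,
                                     n_gwas = 10000L, n_studies = 4L,
                                     seed = 1L) {
  n_snps <- stop_if_not_count(n_snps, "n_snps")
  block_size <- stop_if_not_count(block_size, "block_size")
  n_ref <- stop_if_not_count(n_ref, "n_ref")
  stopifnot(r_within >= 0, r_within < 1, n_causal <= n_snps)
  with_seed_local(derive_seed(seed, "sumstats"), {
    snp <- sprintf("rs%06d", seq_len(n_snps))
    block <- (seq_len(n_snps) - 1L) %/% block_size
    pos <- 10000L + seq_len(n_snps) * 5000L
    freq <- runif(n_snps, 0.05, 0.5)

    # Gaussian-copula haplotypes: one shared factor per block per haplotype
    draw_haplo <- function() {
      shared <- rnorm(n_ref * (max(block) + 1L))
      dim(shared) <- c(n_ref, max(block) + 1L)
      z <- sqrt(r_within) * shared[, block + 1L] +
        sqrt(1 - r_within) * matrix(rnorm(n_ref * n_snps), n_ref, n_snps)
      sweep(z, 2L, qnorm(freq), `<`) * 1
    }
    dosages <- draw_haplo() + draw_haplo()
    colnames(dosages) <- snp
    rownames(dosages) <- sprintf("R%05d", seq_len(n_ref))
    r2 <- stats::cor(dosages)^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 1

    causal <- seq_len(n_snps) %in% sample.int(n_snps, n_causal)
    beta_true <- ifelse(causal, rnorm(n_snps, 0, effect_sd), 0)
    se <- 1 / sqrt(2 * freq * (1 - freq) * n_gwas * 0.25)
    log_or <- beta_true + rnorm(n_snps, 0, se)
    p <- 2 * pnorm(-abs(log_or / se))
    info <- pmin(1, pmax(0.05, 1 - stats::rexp(n_snps, rate = 12)))

    nts <- c("A", "C", "G", "T")
    ea <- sample(nts, n_snps, replace = TRUE)
    oa <- nts[(match(ea, nts) + sample(1:3, n_snps, TRUE) - 1L) %% 4L + 1L]

    studies <- paste0("study", seq_len(n_studies))
    sf <- tibble(snp = snp)
    si <- tibble(snp = snp)
    for (st in studies) {
      sf[[st]] <- pmin(0.999, pmax(0.001, freq + rnorm(n_snps, 0, 0.02)))
      si[[st]] <- pmin(1, pmax(0.05, info + rnorm(n_snps, 0, 0.05)))
    }

    list(
      sumstats = tibble(snp = snp, chrom = 1L, pos = pos,
                        effect_allele = ea, other_allele = oa,
                        log_or = log_or, se = se, p = p, freq = freq,
                        info = info, causal = causal),
      r2 = r2,
      dosages = dosages,
      study_freqs = sf,
      study_info = si
    )
  })
}
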