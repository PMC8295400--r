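test_that("cross-study SNP filters apply the min-info, min-MAF and drift rules", {
  stats <- tibble::tibble(snp = paste0("rs", 1:4))
  freqs <- tibble::tibble(
    snp = stats$snp,
    s1 = c(0.30, 0.30, 0.005, 0.30),
    s2 = c(0.55, 0.32, 0.30, 0.72)
  )
  info <- tibble::tibble(
    snp = stats$snp,
    s1 = c(0.9, 0.9, 0.9, 0.9),
    s2 = c(0.9, 0.4, 0.9, 0.9)
  )
  out <- filter_snps(stats, freqs, info)
  # rs1: drift 0.125 <= 0.2 keeps; rs2 fails info; rs3 fails MAF; rs4 drift 0.21 fails
  expect_equal(out$snp, "rs1")
  expect_error(filter_snps(stats, tibble::tibble(snp = stats$snp)), "no study columns")
})

test_that("LD clumping follows the greedy definition", {
  stats <- tibble::tibble(snp = paste0("rs", 1:3),
                          pos = c(100, 200, 5e6), p = c(0.5, 0.01, 0.2))
  r0 <- diag(3); dimnames(r0) <- list(stats$snp, stats$snp)
  expect_setequal(ld_clump(stats, r0), stats$snp)    # no LD: all index SNPs
  r1 <- matrix(0.9, 3, 3, dimnames = dimnames(r0)); diag(r1) <- 1
  expect_equal(ld_clump(stats, r1), c("rs2", "rs3")) # rs3 outside the 1 Mb window
  stats2 <- dplyr::mutate(stats, pos = c(100, 200, 300))
  expect_equal(ld_clump(stats2, r1), "rs2")          # one index claims everything
  expect_error(ld_clump(stats, r1 + matrix(c(0, 1e-3, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
})

test_that("clumped index sets are invariant to row order", {
  set.seed(11)
  n <- 30
  stats <- tibble::tibble(snp = sprintf("rs%02d", 1:n),
                          pos = sort(sample.int(3e6, n)), p = runif(n))
  z <- matrix(rnorm(n * 5), n)
  r2 <- stats::cor(t(z))^2
  dimnames(r2) <- list(stats$snp, stats$snp)
  a <- ld_clump(stats, r2)
  perm <- sample(n)
  b <- ld_clump(stats[perm, ], r2)
  expect_identical(a, b)
})

test_that("scores are linear dosage-weight sums with allele-orientation flips", {
  d <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  stats <- tibble::tibble(snp = c("rs1", "rs2"), log_or = c(log(1.5), 0.2),
                          effect_allele = c("A", "C"))
  expect_equal(score_individuals(d, stats, "rs1")[1], 2 * log(1.5))
  expect_equal(score_individuals(d, dplyr::mutate(stats, log_or = 0)),
               c(0, 0, 0))
  # flipped coded allele scores (2 - d) * w
  flipped <- score_individuals(d, stats, "rs1", coded_alleles = c(rs1 = "G"))
  expect_equal(flipped, (2 - d[, "rs1"]) * log(1.5))
  # linearity over disjoint SNP subsets
  s_all <- score_individuals(d, stats)
  expect_equal(s_all, score_individuals(d, stats, "rs1") +
                 score_individuals(d, stats, "rs2"))
  expect_error(score_individuals(d, stats, "rs9"), "absent")
})

test_that("PRS association recovers a simulated effect and pools sensibly", {
  set.seed(21)
  n <- 5000
  samples <- tibble::tibble(
    sample_id = as.character(1:n),
    stratum = rep(c("a", "b"), each = n / 2),
    sex = rbinom(n, 1, 0.5),
    PC1 = rnorm(n), PC2 = rnorm(n)
  )
  score <- rnorm(n)
  samples$case <- rbinom(n, 1, plogis(-0.1 + 0.3 * score))
  res <- prs_association(samples, score, n_pcs = 2)
  expect_equal(nrow(res$per_stratum), 2)
  expect_lt(abs(res$meta$beta - 0.3), 3 * res$meta$se)
  expect_true(all(res$per_stratum$nagelkerke_r2 > 0 &
                    res$per_stratum$nagelkerke_r2 < 1))
  expect_error(prs_association(samples, rep(1, n)), "zero variance")
})

test_that("two strata with equal effects pool to that effect", {
  set.seed(22)
  n <- 400
  h <- n / 2   # two strata with byte-identical data
  samples <- tibble::tibble(
    sample_id = as.character(1:n), stratum = rep(c("a", "b"), each = h),
    sex = rep(rbinom(h, 1, 0.5), 2), PC1 = rep(rnorm(h), 2)
  )
  score <- rep(rnorm(h), 2)
  samples$case <- rep(rbinom(h, 1, plogis(0.4 * score[1:h])), 2)
  res <- prs_association(samples, score, n_pcs = 1)
  expect_equal(res$per_stratum$beta[1], res$per_stratum$beta[2], tolerance = 1e-8)
  expect_equal(res$meta$beta, res$per_stratum$beta[1], tolerance = 1e-8)
})

test_that("retaining more truly causal SNPs strengthens the association", {
  sim <- simulate_sumstats_and_ld(n_snps = 120, block_size = 6, r_within = 0.7,
                                  n_ref = 400, n_causal = 30, effect_sd = 0.25,
                                  seed = 31)
  keep <- filter_snps(sim$sumstats, sim$study_freqs, sim$study_info)
  idx <- ld_clump(keep, sim$r2)
  stats_idx <- keep[keep$snp %in% idx, ]
  n <- nrow(sim$dosages)
  set.seed(31)
  truth <- drop(sim$dosages %*% ifelse(sim$sumstats$causal,
                                       sim$sumstats$log_or, 0))
  samples <- tibble::tibble(sample_id = rownames(sim$dosages), stratum = "a",
                            sex = rbinom(n, 1, 0.5), PC1 = rnorm(n),
                            case = rbinom(n, 1, plogis(scale(truth) * 0.8)))
  p_at <- vapply(c(0.01, 0.5), function(thr) {
    snps <- stats_idx$snp[stats_idx$p < thr]
    if (length(snps) < 2) return(NA_real_)
    sc <- score_individuals(sim$dosages, stats_idx, snps)
    prs_association(samples, sc, n_pcs = 1)$meta$p
  }, numeric(1))
  expect_lt(p_at[2], 0.05)     # generous threshold keeps most causal signal
})
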