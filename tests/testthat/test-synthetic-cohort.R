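test_that("configuration validation rejects inconsistent settings", {
  expect_error(cohort_config(strata = tibble::tibble(
    stratum = "a", n_cases = 0L, n_controls = 10L)), "positive")
  expect_error(cohort_config(singleton_fraction = 1.2), "probability")
  expect_error(cohort_config(enriched_sets = c(nope = 2.0)),
               "not among gene_sets")
  expect_error(cohort_config(enriched_sets = c(set01 = -1)), "> 0")
  expect_error(cohort_config(gene_sets = c(big = 10000L)), "exceeds")
})

test_that("identical seed and config reproduce identical cohorts", {
  cfg <- cohort_config(strata = bsc_strata(scale = 0.03), n_genes = 80,
                       gene_sets = c(s = 15L), enriched_sets = c(s = 1.5),
                       seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(as.matrix(a$genotypes), as.matrix(b$genotypes))
  expect_identical(a$samples, b$samples)
  expect_identical(a$gene_sets, b$gene_sets)
  c2 <- simulate_cohort(cohort_config(strata = bsc_strata(scale = 0.03),
                                      n_genes = 80, gene_sets = c(s = 15L),
                                      enriched_sets = c(s = 1.5), seed = 78))
  expect_false(identical(a$samples$case, c2$samples$case))
})

test_that("stratum sizes, genotype range and allele-count bookkeeping hold", {
  co <- tiny_cohort(scale = 0.05, n_genes = 100, gene_sets = c(s = 20L), seed = 5)
  counts <- dplyr::count(dplyr::filter(co$samples, case == 1), stratum)
  want <- bsc_strata(scale = 0.05)
  expect_equal(counts$n[match(want$stratum, counts$stratum)], want$n_cases)
  g <- as.matrix(co$genotypes)
  expect_true(all(g[!is.na(g)] %in% 0:2))
  expect_equal(unname(Matrix::colSums(co$genotypes, na.rm = TRUE)),
               co$variants$cohort_mac)
})

test_that("under a global null the case-control burden difference is centred at zero", {
  diffs <- vapply(1:50, function(i) {
    co <- simulate_cohort(cohort_config(
      strata = tibble::tibble(stratum = "s1", n_cases = 150L, n_controls = 150L),
      n_genes = 60, gene_sets = c(s = 10L), n_pcs = 2, seed = 500 + i
    ))
    b <- count_burden(co$genotypes, which(co$variants$is_plp_truth))
    mean(b[co$samples$case == 1]) - mean(b[co$samples$case == 0])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("the P-LP allele-count spectrum hits the configured singleton fraction", {
  mac <- draw_mac_spectrum(6000, singleton_fraction = 0.81, seed_local = 12)
  expect_true(all(mac >= 1))
  expect_lt(abs(mean(mac == 1) - 0.81), 0.02)
  mac2 <- draw_mac_spectrum(4000, singleton_fraction = 0.5,
                            nonsingleton_mean_mac = 11, seed_local = 12)
  expect_lt(abs(mean(mac2 == 1) - 0.5), 0.03)
})

test_that("conditional Bernoulli sampling has the exact inclusion probabilities", {
  w <- c(1, 2, 3, 1, 0.5)
  n <- 2
  combos <- utils::combn(5, n)
  probs <- apply(combos, 2, function(s) prod(w[s]))
  probs <- probs / sum(probs)
  incl_exact <- vapply(1:5, function(i) {
    sum(probs[apply(combos, 2, function(s) i %in% s)])
  }, numeric(1))
  set.seed(99)
  draws <- replicate(4000, sample_conditional_bernoulli(w, n))
  incl_mc <- vapply(1:5, function(i) mean(apply(draws, 2, function(s) i %in% s)),
                    numeric(1))
  se <- sqrt(incl_exact * (1 - incl_exact) / 4000)
  expect_true(all(abs(incl_mc - incl_exact) < 4 * se + 1e-3))
  expect_identical(sample_conditional_bernoulli(w, 0), integer(0))
  expect_identical(sample_conditional_bernoulli(w, 5), 1:5)
  expect_error(sample_conditional_bernoulli(w, 6), "more items")
  expect_error(sample_conditional_bernoulli(c(1, -1), 1), "positive")
})

test_that("simulated summary statistics and LD panel are internally consistent", {
  sim <- simulate_sumstats_and_ld(n_snps = 1, block_size = 1, n_ref = 50,
                                  n_causal = 0, seed = 4)
  expect_equal(sim$r2, matrix(1, 1, 1, dimnames = list("rs000001", "rs000001")))
  sim2 <- simulate_sumstats_and_ld(n_snps = 40, block_size = 4, r_within = 0,
                                   n_ref = 10000, n_causal = 0, seed = 4)
  off <- sim2$r2[upper.tri(sim2$r2)]
  expect_lt(mean(off), 0.001)        # independent SNPs: empirical r2 near 0
  sim3 <- simulate_sumstats_and_ld(n_snps = 40, block_size = 4, r_within = 0.9,
                                   n_ref = 2000, n_causal = 5, seed = 4)
  blk <- (seq_len(40) - 1) %/% 4
  same <- outer(blk, blk, "==") & upper.tri(sim3$r2)
  expect_gt(mean(sim3$r2[same]), 10 * mean(sim3$r2[!same & upper.tri(sim3$r2)]))
  expect_true(all(sim3$sumstats$p > 0 & sim3$sumstats$p <= 1))
  expect_true(all(sim3$dosages %in% 0:2))
})
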