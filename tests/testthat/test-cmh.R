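test_that("stratified 2x2 tables tally carriers and alleles correctly", {
  burden <- c(1, 2, rep(0, 8), 1, rep(0, 9))
  y <- c(rep(1, 10), rep(0, 10))
  tab <- build_tables(burden, y, rep("s1", 20))
  expect_equal(unlist(tab[1, -1], use.names = FALSE), c(2, 8, 1, 9))
  tab_a <- build_tables(burden, y, rep("s1", 20), mode = "allele")
  expect_equal(unlist(tab_a[1, -1], use.names = FALSE), c(3, 17, 1, 19))
  # no carriers anywhere: zero "with" column
  tab0 <- build_tables(rep(0, 20), y, rep(c("s1", "s2"), each = 10))
  expect_true(all(tab0$case_with == 0 & tab0$control_with == 0))
  # three strata, hand-tallied
  b3 <- c(1, 0, 0, 0, 2, 0, 0, 0, 1, 1, 0, 0)
  y3 <- c(1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0)
  s3 <- rep(c("x", "y", "z"), each = 4)
  t3 <- build_tables(b3, y3, s3)
  expect_equal(t3$case_with, c(1, 1, 2))
  expect_equal(t3$control_with, c(0, 0, 0))
})

test_that("single-stratum CMH equals Pearson chi-square without continuity correction", {
  tab <- tibble::tibble(case_with = 12, case_without = 88,
                        control_with = 5, control_without = 95)
  got <- cmh_chisq(tab)$statistic
  want <- unname(stats::chisq.test(matrix(c(12, 88, 5, 95), 2, byrow = TRUE),
                                   correct = FALSE)$statistic)
  expect_equal(got, want, tolerance = 1e-12)
  # identical proportions: exactly zero
  expect_equal(cmh_chisq(tibble::tibble(case_with = 10, case_without = 90,
                                        control_with = 10, control_without = 90))$statistic, 0)
})

test_that("duplicating a stratum doubles the Cochran statistic", {
  one <- tibble::tibble(case_with = 12, case_without = 88,
                        control_with = 5, control_without = 95)
  two <- dplyr::bind_rows(one, one)
  expect_equal(cmh_chisq(two)$statistic, 2 * cmh_chisq(one)$statistic)
})

test_that("the hypergeometric-variance variant matches mantelhaen.test", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    tab <- tibble::tibble(case_with = sample(1:30, k), case_without = sample(20:80, k),
                          control_with = sample(1:30, k), control_without = sample(20:80, k))
    arr <- array(0, c(2, 2, k))
    for (s in seq_len(k)) {
      arr[, , s] <- matrix(c(tab$case_with[s], tab$case_without[s],
                             tab$control_with[s], tab$control_without[s]),
                           2, byrow = TRUE)
    }
    got <- cmh_chisq(tab, variance = "mh")$statistic
    want <- unname(stats::mantelhaen.test(arr, correct = FALSE)$statistic)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("degenerate strata are skipped and fully degenerate input errors", {
  tab <- tibble::tibble(case_with = c(12, 0), case_without = c(88, 50),
                        control_with = c(5, 0), control_without = c(95, 50))
  expect_equal(cmh_chisq(tab)$n_strata_used, 1)
  expect_equal(cmh_chisq(tab)$statistic, cmh_chisq(tab[1, ])$statistic)
  expect_error(cmh_chisq(tab[2, ]), "degenerate")
})

test_that("empirical p respects the add-one correction, bounds and determinism", {
  co <- tiny_cohort(scale = 0.05, n_genes = 80, gene_sets = c(s = 20L), seed = 31)
  gb <- gene_burden_matrix(co)
  uni <- unique(co$variants$gene)
  e1 <- empirical_p(gb, co$samples$case, co$samples$stratum,
                    co$gene_sets$s, B = 199, seed = 9, gene_universe = uni)
  e2 <- empirical_p(gb, co$samples$case, co$samples$stratum,
                    co$gene_sets$s, B = 199, seed = 9, gene_universe = uni)
  expect_identical(e1$null_stats, e2$null_stats)
  expect_equal(e1$p_empirical,
               (1 + sum(e1$null_stats >= e1$observed_signed_root)) / 200)
  expect_gte(e1$p_empirical, 1 / 200)
  expect_lte(e1$p_empirical, 1)
  # a depletion-direction observation lands in the upper half of p values
  if (e1$observed_signed_root < 0) expect_gte(e1$p_empirical, 0.5)
  expect_error(empirical_p(gb, co$samples$case, co$samples$stratum,
                           co$gene_sets$s, B = 0), "positive")
  expect_error(empirical_p(gb, co$samples$case, co$samples$stratum,
                           paste0("g", seq_len(length(uni) + 1)),
                           B = 10, gene_universe = uni), "exceeds")
})

test_that("vectorized null statistics equal the per-set computation", {
  co <- tiny_cohort(scale = 0.05, n_genes = 80, gene_sets = c(s = 20L), seed = 17)
  gb <- gene_burden_matrix(co)
  y <- co$samples$case
  strata <- co$samples$stratum
  set.seed(2)
  for (i in 1:5) {
    genes <- sample(colnames(gb), 10)
    b <- rowSums(gb[, genes, drop = FALSE])
    direct <- cmh_chisq(build_tables(b, y, strata))$signed_root
    vec <- raresetburden:::null_signed_roots(matrix(b, ncol = 1), y, strata,
                                             "carrier", "cochran")
    expect_equal(vec, direct, tolerance = 1e-12)
  }
})

test_that("CMH and Firth-meta orderings agree across gene sets", {
  sets <- setNames(rep(40L, 20), paste0("gs", sprintf("%02d", 1:20)))
  co <- simulate_cohort(cohort_config(
    strata = bsc_strata(scale = 0.15), n_genes = 600, gene_sets = sets,
    enriched_sets = c(gs01 = 2.5, gs02 = 2.0, gs03 = 1.5), seed = 23
  ))
  gb <- gene_burden_matrix(co)
  res <- suppressWarnings(suppressMessages(
    run_discovery(co, B = 0, seed = 1)
  ))
  roots <- vapply(names(sets), function(s) {
    b <- raresetburden:::set_burden(gb, co$gene_sets[[s]])
    cmh_chisq(build_tables(b, co$samples$case, co$samples$stratum))$signed_root
  }, numeric(1))
  ok <- !is.na(res$results$combined_z)
  rho <- stats::cor(res$results$combined_z[ok], roots[ok], method = "spearman")
  expect_gte(rho, 0.8)
})
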