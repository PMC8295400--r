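test_that("weighted Z combination matches its closed form", {
  expect_equal(weighted_z(1.7, 3.2)$combined_z, 1.7)
  expect_equal(weighted_z(c(1, 1), c(1, 1))$combined_z, sqrt(2))
  r <- weighted_z(c(2, -1), c(1, 2))
  expect_equal(r$combined_z, 0)
  expect_equal(r$p_one_sided, 0.5)
  expect_error(weighted_z(numeric(0)), "at least one")
  expect_error(weighted_z(c(1, 2), c(1, -1)), "positive")
})

test_that("weighted Z with equal weights reduces to Stouffer's method", {
  set.seed(3)
  z <- rnorm(6)
  expect_equal(weighted_z(z, rep(2.5, 6))$combined_z, sum(z) / sqrt(6))
})

test_that("combined one-sided p is uniform under the null", {
  set.seed(19)
  p <- replicate(2000, weighted_z(rnorm(7), runif(7, 0.5, 2))$p_one_sided)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("inverse-variance pooling matches hand arithmetic", {
  one <- pool_or(0.3, 0.1)
  expect_equal(one$pooled_or, exp(0.3))
  expect_equal(one$ci95, exp(0.3 + c(-1, 1) * qnorm(0.975) * 0.1))
  expect_equal(pool_or(c(log(2), log(2)), c(0.2, 0.2))$pooled_or, 2)
  # weights 1/0.04 and 1/0.16: pooled log OR (0.5/0.04 + 1.0/0.16) / (25 + 6.25)
  expect_equal(pool_or(c(0.5, 1.0), c(0.2, 0.4))$log_or, 0.6)
  expect_error(pool_or(0.5, 0), "positive")
})

test_that("Holm adjustment follows the step-down formula and input order", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.5)), c(0.02, 0.5))
  set.seed(8)
  p <- runif(15)^2
  expect_equal(holm_adjust(p), oracle_holm(p))
  # permutation invariance up to reordering
  perm <- sample(15)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  # monotone in the input ordering
  o <- order(p)
  expect_true(all(diff(holm_adjust(p)[o]) >= 0))
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("effective-sample-size weights fold case:control imbalance", {
  expect_equal(neff_weights(100, 100), sqrt(200))
  expect_equal(neff_weights(50, 200), sqrt(4 / (1 / 50 + 1 / 200)))
  expect_equal(neff_weights(50, 200, type = "n"), sqrt(250))
})

test_that("burden_meta drops carrier-free strata and combines the rest", {
  y1 <- rep(c(1, 0), each = 30)
  x_carrier <- function(case_carriers, control_carriers) {
    cbind(`(Intercept)` = 1,
          burden = c(rep(1, case_carriers), rep(0, 30 - case_carriers),
                     rep(1, control_carriers), rep(0, 30 - control_carriers)))
  }
  f1 <- firth_fit(list(y = y1, x = x_carrier(8, 3), stratum = "a"))
  f2 <- firth_fit(list(y = y1, x = x_carrier(6, 4), stratum = "b"))
  f3 <- suppressWarnings(firth_fit(list(y = y1, x = x_carrier(0, 0), stratum = "c")))
  expect_message(m <- burden_meta(list(f1, f2, f3)), "Dropping 1 stratum")
  expect_equal(m$n_strata_used, 2)
  w <- neff_weights(30, 30)
  expect_equal(m$combined_z,
               weighted_z(c(f1$z, f2$z), c(w, w))$combined_z)
  manual <- pool_or(log(c(f1$or_burden, f2$or_burden)),
                    c(f1$se["burden"], f2$se["burden"]))
  expect_equal(m$pooled_or, manual$pooled_or, tolerance = 1e-10)
  expect_error(suppressMessages(burden_meta(list(f3))), "degenerate")
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(glance(m)$p_one_sided, m$p_one_sided)
})
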