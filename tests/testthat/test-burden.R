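test_that("count_burden sums selected alleles with missing-as-zero", {
  g <- rbind(c(0, 1, 2), c(2, NA, 1), c(0, 0, 0))
  colnames(g) <- paste0("v", 1:3)
  expect_equal(count_burden(g, 1:3), c(3, 3, 0))
  expect_equal(count_burden(g, integer(0)), c(0, 0, 0))
  expect_equal(count_burden(g, c("v1", "v3")), c(2, 3, 0))
  expect_error(count_burden(g, 4), "out of range")
  # mean imputation alternative fills with the observed column mean
  expect_equal(count_burden(g, 1:3, missing = "mean")[2], 2 + 0.5 + 1)
})

test_that("total non-reference burden is a straight row sum", {
  g <- matrix(c(0, 0, 0, 0,
                1, 1, 0, 0,
                2, 0, 1, 0,
                0, 2, 2, 1,
                1, 0, 0, 0), 5, 4, byrow = TRUE)
  expect_equal(total_nonref_burden(g), c(0, 2, 3, 5, 1))
})

test_that("Firth fit on a single binary predictor equals the half-cell-added 2x2 odds ratio", {
  # cases: 3 carriers / 7 non-carriers; controls: 1 carrier / 9 non-carriers
  y <- c(rep(1, 10), rep(0, 10))
  carrier <- c(rep(1, 3), rep(0, 7), rep(1, 1), rep(0, 9))
  fit <- firth_fit(list(y = y, x = cbind(`(Intercept)` = 1, burden = carrier)))
  haldane <- log((3.5 * 9.5) / (7.5 * 1.5))
  expect_equal(unname(fit$beta["burden"]), haldane, tolerance = 1e-4)
  oracle <- oracle_firth_coefs(y, cbind(1, carrier))
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("complete separation still yields finite, converged estimates", {
  y <- c(rep(1, 6), rep(0, 8))
  carrier <- c(rep(1, 4), 0, 0, rep(0, 8))    # every carrier is a case
  fit <- firth_fit(list(y = y, x = cbind(`(Intercept)` = 1, burden = carrier)))
  expect_true(all(is.finite(fit$beta)))
  expect_true(fit$converged)
  oracle <- oracle_firth_coefs(y, cbind(1, carrier))
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-3)
})

test_that("penalized likelihood at the optimum is no worse than at zero", {
  set.seed(42)
  x <- cbind(1, rbinom(40, 1, 0.3), rnorm(40))
  colnames(x) <- c("(Intercept)", "burden", "z")
  y <- rbinom(40, 1, plogis(0.5 * x[, 2]))
  if (sum(y) %in% c(0, 40)) y[1:2] <- c(0, 1)
  fit <- firth_fit(list(y = y, x = x))
  expect_gte(fit$penalized_loglik, oracle_penalized_loglik(numeric(3), y, x))
})

test_that("degenerate all-zero burden is flagged and the rest still fits", {
  y <- rep(c(1, 0), each = 10)
  x <- cbind(`(Intercept)` = 1, burden = 0, sex = rep(c(0, 1), 10))
  expect_warning(fit <- firth_fit(list(y = y, x = x)), "zero-variance")
  expect_true(fit$burden_degenerate)
  expect_identical(fit$or_burden, 1)
  expect_identical(fit$ci95, c(0, Inf))
  expect_equal(fit$p_one_sided, 0.5)
})

test_that("rank-deficient covariates raise an error naming the collinear column", {
  y <- rep(c(1, 0), each = 10)
  s <- rep(c(0, 1), 10)
  x <- cbind(`(Intercept)` = 1, burden = rbinom(20, 1, 0.4), sex = s, sex2 = 2 * s)
  expect_error(firth_fit(list(y = y, x = x)), "sex2")
})

test_that("with ample balanced data Firth matches unpenalized ML within 2%", {
  set.seed(7)
  n <- 1000
  x <- cbind(`(Intercept)` = 1, burden = rbinom(n, 2, 0.3), z = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.5 * x[, "burden"] + 0.3 * x[, "z"]))
  fit <- firth_fit(list(y = y, x = x))
  ml <- stats::glm.fit(x, y, family = stats::binomial())$coefficients
  expect_equal(unname(fit$beta), unname(ml), tolerance = 0.02)
})

test_that("one-sided p is upper-tail: case enrichment gives p below one half", {
  y <- c(rep(1, 10), rep(0, 10))
  carrier <- c(rep(1, 5), rep(0, 5), rep(1, 1), rep(0, 9))
  fit <- firth_fit(list(y = y, x = cbind(`(Intercept)` = 1, burden = carrier)))
  expect_lt(fit$p_one_sided, 0.5)
  expect_gt(fit$z, 0)
})

test_that("burden_design subsets a stratum and respects the PC budget", {
  co <- tiny_cohort(scale = 0.05, n_genes = 60, gene_sets = c(s = 10L))
  b <- count_burden(co$genotypes, select_plp(co$variants))
  d <- burden_design(co$samples, b, "Sweden", n_pcs = 5)
  expect_equal(ncol(d$x), 2 + 1 + 5)
  expect_equal(nrow(d$x), sum(co$samples$stratum == "Sweden"))
  expect_error(burden_design(co$samples, b, "nope"), "Unknown stratum")
  d2 <- burden_design(co$samples, b, "Sweden",
                      total_burden = total_nonref_burden(co$genotypes))
  expect_true("total_burden" %in% colnames(d2$x))
})
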