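#' Weighted Z-score (Stouffer) combination of per-stratum tests
#'
#' Combines per-stratum Z statistics as
#' `Z = sum(w_k z_k) / sqrt(sum(w_k^2))` and converts the combined Z into an
#' upper-tail one-sided p value for case enrichment. With equal weights this
#' reduces to Stouffer's method.
#'
#' @param z Numeric vector of per-stratum Z statistics.
#' @param weights Positive per-stratum weights (same length as `z`). The
#'   conventional choice for unbalanced case-control strata is the square
#'   root of effective sample size, `sqrt(4 / (1/n_cases + 1/n_controls))`;
#'   see [neff_weights()].
#' @return A list with `combined_z` and `p_one_sided`.
#' @export
#' @examples
#' weighted_z(c(1, 1), c(1, 1))        # sqrt(2)
#' weighted_z(c(2, -1), c(1, 2))       # exactly 0, p = 0.5
weighted_z <- function(z, weights = rep(1, length(z))) {
  if (!length(z)) abort("Need at least one stratum.")
  if (length(weights) != length(z)) abort("`z` and `weights` lengths differ.")
  if (anyNA(z) || anyNA(weights)) abort("Missing values in `z` or `weights`.")
  if (any(weights <= 0)) abort("Weights must be positive.")
  cz <- sum(weights * z) / sqrt(sum(weights^2))
  list(combined_z = cz, p_one_sided = pnorm(cz, lower.tail = FALSE))
}

#' Effective-sample-size meta-analysis weights
#'
#' @param n_cases,n_controls Per-stratum counts.
#' @param type `"neff"` (default): `sqrt(4 / (1/n_cases + 1/n_controls))`;
#'   `"n"`: `sqrt(n_cases + n_controls)`.
#' @return Numeric weights.
#' @export
neff_weights <- function(n_cases, n_controls, type = c("neff", "n")) {
  type <- match.arg(type)
  if (type == "neff") {
    sqrt(4 / (1 / n_cases + 1 / n_controls))
  } else {
    sqrt(n_cases + n_controls)
  }
}

#' Inverse-variance pooled odds ratio
#'
#' Pools per-stratum log odds ratios with weights `1/se^2` and returns the
#' exponentiated pooled estimate with a Wald 95% confidence interval.
#'
#' @param log_or Per-stratum log odds ratios.
#' @param se Per-stratum standard errors (positive).
#' @return A list with `pooled_or`, `ci95` (length-2), `log_or`, `se`.
#' @export
#' @examples
#' pool_or(c(0.5, 1.0), c(0.2, 0.4))   # pooled log OR 0.6
pool_or <- function(log_or, se) {
  if (!length(log_or)) abort("Need at least one stratum.")
  if (length(se) != length(log_or)) abort("`log_or` and `se` lengths differ.")
  if (anyNA(log_or) || anyNA(se) || any(!is.finite(log_or)) || any(!is.finite(se))) {
    abort("`log_or` and `se` must be finite.")
  }
  if (any(se <= 0)) abort("Standard errors must be positive.")
  w <- 1 / se^2
  lo <- sum(w * log_or) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  list(
    pooled_or = exp(lo),
    ci95 = exp(lo + c(-1, 1) * qnorm(0.975) * se_pool),
    log_or = lo,
    se = se_pool
  )
}

#' Holm step-down multiplicity adjustment
#'
#' Step-down familywise-error control: with the p values sorted ascending,
#' the adjusted value at rank k is `max_{j <= k} (m - j + 1) p_(j)`, capped
#' at 1, returned in the original input order. Delegates to
#' [stats::p.adjust()] after validation.
#'
#' @param p Numeric vector of p values in (0, 1].
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.5))   # c(0.02, 0.5)
holm_adjust <- function(p) {
  if (!is.numeric(p) || !length(p)) abort("`p` must be a non-empty numeric vector.")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) abort("p values must lie in (0, 1].")
  stats::p.adjust(p, method = "holm")
}

#' Meta-analyze per-stratum Firth burden fits
#'
#' Combines a list of [firth_fit()] objects for one gene or gene set across
#' strata: weighted-Z one-sided p for case enrichment, inverse-variance
#' pooled odds ratio with Wald 95% CI, plus a descriptive Cochran Q.
#' Strata whose burden term is degenerate (no qualifying-allele carriers)
#' carry no evidence and are dropped from the combination with a message.
#'
#' @param fits List of `firth_fit` objects (one per stratum).
#' @param weights `"neff"` (default) or `"n"`, passed to [neff_weights()].
#' @return An object of class `burden_meta` with per-stratum and combined
#'   results; `tidy()` gives the per-stratum table and `glance()` the
#'   combined one-row summary.
#' @export
burden_meta <- function(fits, weights = c("neff", "n")) {
  weights <- match.arg(weights)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "firth_fit")))
  per <- purrr::map_dfr(fits, glance)
  usable <- !per$burden_degenerate
  if (!any(usable)) {
    abort("All strata are degenerate: no qualifying-allele carriers anywhere.")
  }
  if (any(!usable)) {
    inform(sprintf("Dropping %d stratum/strata without qualifying carriers: %s",
                   sum(!usable), paste(per$stratum[!usable], collapse = ", ")))
  }
  use <- per[usable, ]
  w <- neff_weights(use$n_cases, use$n_controls, type = weights)
  comb <- weighted_z(use$z, w)
  log_or <- log(use$or_burden)
  se <- (log(use$ci_high) - log(use$ci_low)) / (2 * qnorm(0.975))
  pooled <- pool_or(log_or, se)
  q <- sum((log_or - pooled$log_or)^2 / se^2)
  inform(sprintf("Heterogeneity Q = %.2f on %d df.", q, max(nrow(use) - 1L, 0L)))
  structure(
    list(
      per_stratum = per,
      weights_type = weights,
      combined_z = comb$combined_z,
      p_one_sided = comb$p_one_sided,
      pooled_or = pooled$pooled_or,
      ci95 = pooled$ci95,
      pooled_log_or = pooled$log_or,
      pooled_se = pooled$se,
      q_heterogeneity = q,
      n_strata_used = nrow(use)
    ),
    class = "burden_meta"
  )
}

#' @export
print.burden_meta <- function(x, ...) {
  cat(sprintf("<burden_meta> %d stratum/strata combined (weights: %s)\n",
              x$n_strata_used, x$weights_type))
  cat(sprintf("  pooled OR %.3f (95%% CI %.3f-%.3f)\n",
              x$pooled_or, x$ci95[1], x$ci95[2]))
  cat(sprintf("  combined Z = %.3f, one-sided p = %.3g\n",
              x$combined_z, x$p_one_sided))
  invisible(x)
}

#' @rdname burden_meta
#' @param x A `burden_meta` object.
#' @param ... Unused.
#' @method tidy burden_meta
#' @export
tidy.burden_meta <- function(x, ...) x$per_stratum

#' @rdname burden_meta
#' @method glance burden_meta
#' @export
glance.burden_meta <- function(x, ...) {
  tibble(
    pooled_or = x$pooled_or,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    combined_z = x$combined_z,
    p_one_sided = x$p_one_sided,
    q_heterogeneity = x$q_heterogeneity,
    n_strata_used = x$n_strata_used
  )
}
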