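#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_vline geom_col geom_histogram labs theme_minimal scale_x_log10
NULL

#' @export
ggplot2::autoplot

#' Forest plot of a stratified burden meta-analysis
#'
#' Per-stratum odds ratios with 95% confidence intervals and the pooled
#' estimate, on a log OR axis. Strata without qualifying carriers are shown
#' without a point estimate.
#'
#' @param object A [burden_meta()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_meta
#' @export
autoplot.burden_meta <- function(object, ...) {
  per <- object$per_stratum
  df <- dplyr::bind_rows(
    tibble(stratum = per$stratum, or = ifelse(per$burden_degenerate, NA, per$or_burden),
           lo = ifelse(per$burden_degenerate, NA, per$ci_low),
           hi = ifelse(per$burden_degenerate, NA, per$ci_high), what = "stratum"),
    tibble(stratum = "META", or = object$pooled_or,
           lo = object$ci95[1], hi = object$ci95[2], what = "meta")
  )
  df$stratum <- factor(df$stratum, levels = rev(df$stratum))
  ggplot(df, aes(x = .data$or, y = .data$stratum, colour = .data$what)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2,
                   na.rm = TRUE) +
    geom_point(size = 2, na.rm = TRUE) +
    scale_x_log10() +
    labs(x = "Odds ratio per qualifying allele (log scale)", y = NULL,
         colour = NULL) +
    theme_minimal()
}

#' Allele-count spectrum of qualifying P-LP variants
#'
#' @param cohort A `rare_cohort` or a [descriptive_report()] result.
#' @return A ggplot bar chart (counts of 10+ pooled).
#' @export
plot_mac_spectrum <- function(cohort) {
  rep <- if (inherits(cohort, "cohort_report")) cohort else descriptive_report(cohort)
  df <- rep$mac_spectrum
  df$mac <- factor(df$mac, levels = 1:10, labels = c(1:9, "10+"))
  ggplot(df, aes(x = .data$mac, y = .data$n_variants)) +
    geom_col(fill = "steelblue") +
    labs(x = "Minor allele count", y = "P-LP variants") +
    theme_minimal()
}

#' Null distribution of the empirical gene-set CMH calibration
#'
#' @param object A [empirical_p()] result.
#' @param ... Unused.
#' @return A ggplot histogram of the signed null roots with the observed
#'   value marked.
#' @method autoplot cmh_empirical
#' @export
autoplot.cmh_empirical <- function(object, ...) {
  ggplot(tibble(stat = object$null_stats), aes(x = .data$stat)) +
    geom_histogram(bins = 50, fill = "grey70") +
    geom_vline(xintercept = object$observed_signed_root, colour = "firebrick") +
    labs(x = "Signed CMH root (random gene sets)", y = "Count",
         subtitle = sprintf("one-sided empirical p = %.4g", object$p_empirical)) +
    theme_minimal()
}
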