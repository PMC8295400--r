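#' Stratified 2x2 tables of qualifying burden
#'
#' Tallies, per stratum, individuals (or alleles) with and without
#' qualifying burden among cases and controls. In `"carrier"` mode (the
#' default) an individual is "with burden" when their qualifying-allele
#' count is at least one; in `"allele"` mode the table counts alleles
#' against total allele slots (2 per individual).
#'
#' @param burden Per-individual qualifying-allele count.
#' @param y Binary case status (case = 1), aligned with `burden`.
#' @param strata Stratum label per individual.
#' @param mode `"carrier"` or `"allele"`.
#' @return A tibble with one row per stratum: `stratum`, `case_with`,
#'   `case_without`, `control_with`, `control_without`.
#' @export
#' @examples
#' build_tables(c(1, 2, 0, 0, 0, 0, 0, 0, 0, 0, 1, rep(0, 9)),
#'              c(rep(1, 10), rep(0, 10)), rep("s1", 20))
build_tables <- function(burden, y, strata, mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  n <- length(burden)
  if (length(y) != n || length(strata) != n) {
    abort("`burden`, `y` and `strata` must be aligned.")
  }
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("`y` must be binary.")
  burden[is.na(burden)] <- 0
  df <- tibble(stratum = as.character(strata), y = y, burden = burden)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$stratum),
    case_with = if (mode == "carrier") sum(.data$y == 1 & .data$burden >= 1)
                else sum(.data$burden[.data$y == 1]),
    case_without = if (mode == "carrier") sum(.data$y == 1 & .data$burden < 1)
                   else 2 * sum(.data$y == 1) - sum(.data$burden[.data$y == 1]),
    control_with = if (mode == "carrier") sum(.data$y == 0 & .data$burden >= 1)
                   else sum(.data$burden[.data$y == 0]),
    control_without = if (mode == "carrier") sum(.data$y == 0 & .data$burden < 1)
                      else 2 * sum(.data$y == 0) - sum(.data$burden[.data$y == 0]),
    .groups = "drop"
  )
  out
}

#' Cochran-Mantel-Haenszel chi-square for stratified 2x2 tables
#'
#' Computes the stratified common-association chi-square
#' `(sum_k (a_k - E a_k))^2 / sum_k Var(a_k)` without continuity
#' correction, together with its signed square root (positive = case
#' enrichment). Two variance conventions are supported: `"cochran"`
#' (binomial, `n1 n2 m1 m2 / T^3`; the single-stratum statistic then equals
#' the Pearson chi-square without continuity correction exactly) and
#' `"mh"` (hypergeometric, `n1 n2 m1 m2 / (T^2 (T - 1))`, as in
#' [stats::mantelhaen.test()]). Strata with a zero row or column margin
#' carry no information and are skipped.
#'
#' @param tables Tibble from [build_tables()] (columns `case_with`,
#'   `case_without`, `control_with`, `control_without`).
#' @param variance `"cochran"` (default) or `"mh"`.
#' @return A list with `statistic`, `signed_root`, `df` (= 1) and
#'   `n_strata_used`.
#' @export
cmh_chisq <- function(tables, variance = c("cochran", "mh")) {
  variance <- match.arg(variance)
  a <- as.numeric(tables$case_with)
  b <- as.numeric(tables$case_without)
  c_ <- as.numeric(tables$control_with)
  d <- as.numeric(tables$control_without)
  if (any(c(a, b, c_, d) < 0)) abort("Table counts must be non-negative.")
  n1 <- a + b          # cases
  n2 <- c_ + d         # controls
  m1 <- a + c_         # with burden
  m2 <- b + d          # without
  tt <- n1 + n2
  ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
  if (!any(ok)) abort("All strata are degenerate (zero margin).")
  ea <- n1[ok] * m1[ok] / tt[ok]
  va <- if (variance == "cochran") {
    n1[ok] * n2[ok] * m1[ok] * m2[ok] / tt[ok]^3
  } else {
    n1[ok] * n2[ok] * m1[ok] * m2[ok] / (tt[ok]^2 * (tt[ok] - 1))
  }
  num <- sum(a[ok] - ea)
  stat <- num^2 / sum(va)
  list(
    statistic = stat,
    signed_root = sign(num) * sqrt(stat),
    df = 1L,
    n_strata_used = sum(ok)
  )
}

#' Empirical gene-set null for the CMH statistic
#'
#' Calibrates an observed gene-set CMH statistic against a null
#' distribution built from random gene sets of the same size: `B` uniform
#' draws without replacement from the gene universe, recomputing set burden
#' and the CMH statistic for each. The one-sided empirical p (case-enriched
#' direction, via the signed root) uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (B + 1)`; statistics in the depletion
#' direction count as below any case-enriched observation.
#'
#' @param gene_burden Individuals x genes matrix of qualifying-allele counts
#'   (see [gene_burden_matrix()]).
#' @param y Binary case status per individual.
#' @param strata Stratum label per individual.
#' @param gene_set Character vector of gene names (columns of
#'   `gene_burden`) forming the observed set; genes absent from the matrix
#'   carry no qualifying variants and contribute zero burden.
#' @param B Number of random sets (default 10000).
#' @param seed Integer seed for the random draws.
#' @param mode Table construction mode, see [build_tables()].
#' @param gene_universe Sampling frame: every gene eligible to enter a
#'   random set. Defaults to the columns of `gene_burden`, but should be
#'   the full annotated gene list when available (genes without qualifying
#'   variants belong to the frame and contribute zero burden), so that
#'   random sets and the observed set contain comparable numbers of
#'   non-contributing genes.
#' @param variance Variance convention, see [cmh_chisq()].
#' @return An object of class `cmh_empirical`: `observed_stat`,
#'   `observed_signed_root`, `null_stats` (length `B`, signed roots),
#'   `p_empirical`, `geneset_size`, `B`, `seed`.
#' @export
empirical_p <- function(gene_burden, y, strata, gene_set, B = 10000L,
                        seed = 1L, mode = c("carrier", "allele"),
                        gene_universe = colnames(gene_burden),
                        variance = c("cochran", "mh")) {
  mode <- match.arg(mode)
  variance <- match.arg(variance)
  B <- stop_if_not_count(B, "B")
  gene_universe <- unique(gene_universe)
  size <- length(unique(gene_set))
  if (size > length(gene_universe)) {
    abort("Gene-set size exceeds the gene universe.")
  }
  y <- as.numeric(y)
  strata <- as.character(strata)

  observed_burden <- set_burden(gene_burden, gene_set)
  obs <- cmh_chisq(build_tables(observed_burden, y, strata, mode), variance)

  # one signed root per random set, computed in bulk: burden for all B sets
  # at once via gene_burden %*% (gene x B indicator), then per-stratum
  # carrier/allele tallies with column sums
  null_roots <- with_seed_local(derive_seed(seed, "cmh_null"), {
    # genes sampled from the full frame; only those with qualifying
    # variants (columns of gene_burden) contribute burden
    col_of <- match(gene_universe, colnames(gene_burden))
    gi <- matrix(0, ncol(gene_burden), B)
    for (b in seq_len(B)) {
      cols <- col_of[sample.int(length(gene_universe), size)]
      gi[cols[!is.na(cols)], b] <- 1
    }
    bmat <- gene_burden %*% gi                    # individuals x B
    null_signed_roots(bmat, y, strata, mode, variance)
  })

  n_ge <- sum(null_roots >= obs$signed_root)
  structure(
    list(
      observed_stat = obs$statistic,
      observed_signed_root = obs$signed_root,
      null_stats = null_roots,
      p_empirical = (1 + n_ge) / (B + 1),
      geneset_size = size,
      B = B,
      seed = as.integer(seed),
      mode = mode
    ),
    class = "cmh_empirical"
  )
}

#' @export
print.cmh_empirical <- function(x, ...) {
  cat(sprintf("<cmh_empirical> set of %d gene(s), B = %d\n", x$geneset_size, x$B))
  cat(sprintf("  observed CMH = %.3f (signed root %.3f)\n",
              x$observed_stat, x$observed_signed_root))
  cat(sprintf("  one-sided empirical p = %.4g\n", x$p_empirical))
  invisible(x)
}

set_burden <- function(gene_burden, gene_set) {
  idx <- match(unique(gene_set), colnames(gene_burden))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(numeric(nrow(gene_burden)))
  rowSums(gene_burden[, idx, drop = FALSE])
}

# Vectorized signed CMH roots for many burden columns at once.
null_signed_roots <- function(bmat, y, strata, mode, variance) {
  bmat <- as.matrix(bmat)
  stratum_levels <- unique(strata)
  num <- numeric(ncol(bmat))
  den <- numeric(ncol(bmat))
  for (s in stratum_levels) {
    rows <- strata == s
    ys <- y[rows]
    n_case <- sum(ys == 1)
    n_ctrl <- sum(ys == 0)
    bs <- bmat[rows, , drop = FALSE]
    if (mode == "carrier") {
      withb <- bs >= 1
      a <- colSums(withb[ys == 1, , drop = FALSE])
      m1 <- colSums(withb)
      n1 <- n_case; n2 <- n_ctrl
      tt <- n_case + n_ctrl
    } else {
      a <- colSums(bs[ys == 1, , drop = FALSE])
      m1 <- colSums(bs)
      n1 <- 2 * n_case; n2 <- 2 * n_ctrl
      tt <- 2 * (n_case + n_ctrl)
    }
    m2 <- tt - m1
    ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
    ea <- n1 * m1 / tt
    va <- if (variance == "cochran") {
      n1 * n2 * m1 * m2 / tt^3
    } else {
      n1 * n2 * m1 * m2 / (tt^2 * (tt - 1))
    }
    num <- num + ifelse(ok, a - ea, 0)
    den <- den + ifelse(ok, va, 0)
  }
  out <- ifelse(den > 0, num / sqrt(den), 0)
  as.numeric(out)
}
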