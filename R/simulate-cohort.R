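#' Draw minor allele counts from the singleton-dominated P-LP spectrum
#'
#' The site frequency spectrum of pathogenic/likely-pathogenic coding
#' variants in large exome cohorts is dominated by singletons. The generator
#' models the total cohort minor allele count of each P-LP variant as a
#' two-component mixture: a point mass at 1 with probability
#' `singleton_fraction`, and a shifted geometric tail (support 2, 3, ...)
#' with mean `nonsingleton_mean_mac` otherwise.
#'
#' @param n Number of variants to draw.
#' @param singleton_fraction Probability of minor allele count 1.
#' @param nonsingleton_mean_mac Mean count of the non-singleton tail
#'   (must exceed 2).
#' @param seed_local Optional integer seed applied locally (the caller's
#'   random-number state is restored afterwards).
#' @return Integer vector of minor allele counts (all >= 1).
#' @export
#' @examples
#' mac <- draw_mac_spectrum(1000, seed_local = 1)
#' mean(mac == 1)
draw_mac_spectrum <- function(n, singleton_fraction = 0.81,
                              nonsingleton_mean_mac = 5.26,
                              seed_local = NULL) {
  stop_if_not_prob(singleton_fraction, "singleton_fraction")
  stopifnot(nonsingleton_mean_mac > 2)
  draw <- function() {
    singleton <- runif(n) < singleton_fraction
    tail <- 2L + rgeom(n, prob = 1 / (nonsingleton_mean_mac - 1))
    ifelse(singleton, 1L, tail)
  }
  if (is.null(seed_local)) draw() else with_seed_local(seed_local, draw())
}

#' Exact fixed-size weighted (conditional Bernoulli) sampling
#'
#' Samples a subset S of fixed size `n` from `length(weights)` items with
#' probability proportional to the product of the selected items' weights.
#' This is the conditional distribution of independent Bernoulli indicators
#' with odds `weights` given that exactly `n` succeed, computed exactly by
#' the elementary-symmetric-polynomial recursion in log space. When the
#' weights are logistic-model odds, sampling case labels this way preserves
#' the model's odds ratios exactly while hitting the design's case count.
#'
#' @param weights Positive odds, one per item.
#' @param n Subset size.
#' @return Sorted integer indices of the selected items.
#' @export
sample_conditional_bernoulli <- function(weights, n) {
  N <- length(weights)
  stop_if_not_count(n, "n", positive = FALSE)
  if (n > N) abort("Cannot select more items than available.")
  if (!all(is.finite(weights)) || any(weights <= 0)) {
    abort("`weights` must be positive and finite.")
  }
  if (n == 0L) return(integer(0))
  if (n == N) return(seq_len(N))
  lw <- log(weights)
  logaddexp <- function(a, b) {
    m <- pmax(a, b)
    out <- m + log1p(exp(-abs(a - b)))
    out[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- -Inf
    out[is.infinite(a) & a < 0 & is.finite(b)] <- b[is.infinite(a) & a < 0 & is.finite(b)]
    out[is.infinite(b) & b < 0 & is.finite(a)] <- a[is.infinite(b) & b < 0 & is.finite(a)]
    out
  }
  # logT[k, j + 1] = log sum over size-j subsets of items k..N of weight products
  logT <- matrix(-Inf, N + 1L, n + 1L)
  logT[N + 1L, 1L] <- 0
  for (k in N:1) {
    prev <- logT[k + 1L, ]
    logT[k, ] <- logaddexp(prev, c(-Inf, prev[seq_len(n)] + lw[k]))
  }
  sel <- integer(n)
  got <- 0L
  j <- n
  for (k in seq_len(N)) {
    if (j == 0L) break
    if (N - k + 1L == j) {           # must take everything that remains
      sel[(got + 1L):n] <- k:N
      got <- n
      break
    }
    p_inc <- exp(lw[k] + logT[k + 1L, j] - logT[k, j + 1L])
    if (runif(1) < p_inc) {
      got <- got + 1L
      sel[got] <- k
      j <- j - 1L
    }
  }
  sel
}

# consequence class mix of simulated exonic SNVs, and the target consequence
# composition of the P-LP subset (LOF-heavy, as evidence-based classifiers
# mostly promote stopgain/splice variants)
CONSEQ_PROBS <- c(missense = 0.50, splice_site = 0.03, stopgain = 0.02,
                  startloss = 0.002, stoploss = 0.001, synonymous = 0.40,
                  other = 0.047)
PLP_COMPOSITION <- c(stopgain = 0.31, splice_site = 0.20, missense = 0.47,
                     startloss = 0.015, stoploss = 0.005)

#' Simulate a multi-stratum case-control exome cohort
#'
#' Generates a seeded synthetic dataset with the structure a stratified
#' rare-variant burden analysis consumes: a variant table with consequence
#' classes, reference-population frequencies, ACMG evidence codes and
#' classes; a sparse genotype matrix of minor-allele counts; a sample table
#' with case status, sex, principal components and stratum; a gene-variant
#' map; and named gene sets. Case labels are assigned within each stratum by
#' exact conditional-Bernoulli sampling with weights equal to the odds of a
#' logistic disease model whose linear predictor contains sex, principal
#' components and the per-individual P-LP allele count in each enriched gene
#' set (coefficient `log(OR)`), so configured odds ratios are recovered by
#' retrospective logistic regression.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `rare_cohort` with elements `variants`,
#'   `genotypes` (sparse [Matrix::dgCMatrix] of minor-allele counts, `NA`
#'   for missing), `samples`, `gene_map`, `gene_sets` and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(strata = bsc_strata(scale = 0.02), n_genes = 50,
#'                      gene_sets = c(setA = 10L), seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$samples
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().")
  }
  strata <- config$strata
  n_by_stratum <- strata$n_cases + strata$n_controls
  n_total <- sum(n_by_stratum)

  ## ---- variant scaffold ----------------------------------------------------
  variants <- with_seed_local(derive_seed(config$seed, "variants"), {
    n_var_per_gene <- 1L + rpois(config$n_genes,
                                 max(config$mean_variants_per_gene - 1, 0))
    genes <- sprintf("GENE%05d", seq_len(config$n_genes))
    gene_chrom <- rep_len(1:22, config$n_genes)
    v_gene <- rep.int(genes, n_var_per_gene)
    n_var <- length(v_gene)
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, n_var, replace = TRUE)
    alt <- nt[(match(ref, nt) + sample(1:3, n_var, replace = TRUE) - 1L) %% 4L + 1L]
    conseq <- sample(names(CONSEQ_PROBS), n_var, replace = TRUE,
                     prob = CONSEQ_PROBS)
    # consequence-conditional P-LP probability chosen so that the marginal
    # P-LP rate is plp_fraction and the P-LP consequence mix is LOF-heavy
    p_plp_by_class <- setNames(numeric(length(CONSEQ_PROBS)), names(CONSEQ_PROBS))
    p_plp_by_class[names(PLP_COMPOSITION)] <-
      pmin(1, config$plp_fraction * PLP_COMPOSITION /
             CONSEQ_PROBS[names(PLP_COMPOSITION)])
    is_plp <- runif(n_var) < p_plp_by_class[conseq]
    tibble(
      variant_id = sprintf("VAR%07d", seq_len(n_var)),
      chrom = rep.int(gene_chrom, n_var_per_gene),
      pos = unlist(lapply(n_var_per_gene, function(k) sort(sample.int(5e4, k))), use.names = FALSE) +
        rep.int(seq_len(config$n_genes) * 100000L, n_var_per_gene),
      ref = ref, alt = alt, gene = v_gene,
      consequence = conseq, is_plp_truth = is_plp
    )
  })
  n_var <- nrow(variants)

  ## ---- samples (labels assigned later) ------------------------------------
  anc_offsets <- list(EUR = c(0, 0), AFR = c(3, 1), LAT = c(1.5, -1),
                      EAS = c(-1, 3))
  samples <- with_seed_local(derive_seed(config$seed, "samples"), {
    stratum <- rep.int(strata$stratum, n_by_stratum)
    ancestry <- rep.int(strata$ancestry, n_by_stratum)
    pcs <- matrix(rnorm(n_total * config$n_pcs), n_total, config$n_pcs)
    off <- t(vapply(ancestry, function(a) {
      o <- anc_offsets[[a]] %||% c(0, 0)
      c(o, numeric(config$n_pcs))[seq_len(config$n_pcs)]
    }, numeric(config$n_pcs)))
    colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
    out <- tibble(
      sample_id = sprintf("S%06d", seq_len(n_total)),
      stratum = stratum,
      sex = rbinom(n_total, 1L, 0.5)
    )
    dplyr::bind_cols(out, as_tibble(pcs + off))
  })

  ## ---- allele counts and genotype placement --------------------------------
  geno <- with_seed_local(derive_seed(config$seed, "genotypes"), {
    is_plp <- variants$is_plp_truth
    mac <- integer(n_var)
    mac[is_plp] <- draw_mac_spectrum(sum(is_plp), config$singleton_fraction,
                                     config$nonsingleton_mean_mac)
    n_other <- sum(!is_plp)
    common <- !is_plp & (runif(n_var) < config$common_fraction)
    rare_other <- !is_plp & !common
    mac[rare_other] <- draw_mac_spectrum(sum(rare_other),
                                         singleton_fraction = 0.5,
                                         nonsingleton_mean_mac = 11)
    mac[common] <- pmax(1L, rbinom(sum(common), 2L * n_total,
                                   runif(sum(common), 0.01, 0.10)))
    mac <- pmin(mac, 2L * n_total)
    common_freq <- rep(NA_real_, n_var)
    common_freq[common] <- mac[common] / (2 * n_total)

    home <- rep(NA_character_, n_var)
    structured <- runif(n_var) < config$structured_fraction
    home[structured] <- sample(strata$stratum, sum(structured), replace = TRUE)

    # place alleles individual-by-individual; a variant's home stratum gets
    # 3x placement weight, emulating stratum-level frequency shifts
    ii <- vector("list", nrow(strata) + 1L)
    jj <- vector("list", nrow(strata) + 1L)
    groups <- c(list(which(!structured)),
                lapply(strata$stratum, function(s) which(home == s)))
    for (g in seq_along(groups)) {
      vs <- groups[[g]]
      if (!length(vs)) next
      w <- rep(1, n_total)
      if (g > 1L) w[samples$stratum == strata$stratum[g - 1L]] <- 3
      alleles <- rep.int(vs, mac[vs])
      ii[[g]] <- sample.int(n_total, length(alleles), replace = TRUE, prob = w)
      jj[[g]] <- alleles
    }
    gm <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = 1,
      dims = c(n_total, n_var),
      dimnames = list(samples$sample_id, variants$variant_id)
    )
    gm@x <- pmin(gm@x, 2)
    list(gm = gm, common = common, common_freq = common_freq)
  })
  gm <- geno$gm

  ## ---- annotations: frequencies, orientation, evidence ---------------------
  variants <- with_seed_local(derive_seed(config$seed, "annotation"), {
    is_plp <- variants$is_plp_truth
    cohort_freq <- Matrix::colSums(gm) / (2 * n_total)
    base_freq <- ifelse(geno$common, geno$common_freq, pmax(cohort_freq, 2e-5))
    novel <- runif(n_var) < ifelse(is_plp, config$novel_plp_fraction, 0.15)
    pops <- c("nfe", "afr", "eas", "amr")
    fr <- matrix(NA_real_, n_var, length(pops),
                 dimnames = list(NULL, paste0("af_", pops)))
    for (p in seq_along(pops)) {
      seen <- !novel & (runif(n_var) < 0.9)
      f <- base_freq * exp(rnorm(n_var, 0, 0.5))
      f[is_plp] <- pmin(f[is_plp], 0.009)   # classified P-LP variants stay rare
      fr[seen, p] <- pmin(f[seen], 0.5)
    }
    minor_is_alt <- rep(TRUE, n_var)
    minor_is_alt[!is_plp] <- runif(sum(!is_plp)) >= config$minor_ref_fraction

    ev <- character(n_var)
    cq <- variants$consequence
    lof_p <- is_plp & (cq == "splice_site" |
                         (cq == "stopgain" & runif(n_var) < 0.85))
    lp_lof <- is_plp & cq %in% c("startloss", "stoploss", "stopgain") & !lof_p
    lp_mis <- is_plp & cq == "missense"
    ev[lof_p] <- "PVS1;PS1"
    ev[lp_lof] <- "PVS1;PM2"
    ev[lp_mis] <- "PS1;PM2"
    ev[!is_plp & geno$common] <- "BA1"
    syn_bp <- !is_plp & cq == "synonymous" & runif(n_var) < 0.10
    ev[syn_bp] <- "BP4;BP7"

    out <- dplyr::bind_cols(variants, as_tibble(fr))
    out$minor_is_alt <- minor_is_alt
    out$evidence <- ev
    out$acmg_class <- classify_acmg(ev)
    out
  })

  ## ---- genotype missingness -------------------------------------------------
  if (config$missing_rate > 0) {
    gm <- with_seed_local(derive_seed(config$seed, "missing"), {
      drop <- runif(length(gm@x)) < config$missing_rate
      gm@x[drop] <- NA_real_
      gm
    })
  }
  variants$cohort_mac <- unname(Matrix::colSums(gm, na.rm = TRUE))

  ## ---- gene sets ------------------------------------------------------------
  genes <- unique(variants$gene)
  gene_sets <- with_seed_local(derive_seed(config$seed, "genesets"), {
    if (is.list(config$gene_sets)) {
      unknown <- setdiff(unlist(config$gene_sets), genes)
      if (length(unknown)) {
        abort(sprintf("Gene set references unknown gene(s): %s",
                      paste(utils::head(unknown, 5), collapse = ", ")))
      }
      config$gene_sets
    } else {
      lapply(config$gene_sets, function(k) sort(sample(genes, k)))
    }
  })

  ## ---- case-status assignment ----------------------------------------------
  samples <- with_seed_local(derive_seed(config$seed, "case_assignment"), {
    beta_pc <- c(config$beta_pc, numeric(config$n_pcs))[seq_len(config$n_pcs)]
    pcs <- as.matrix(samples[paste0("PC", seq_len(config$n_pcs))])
    eta <- config$beta_sex * samples$sex + drop(pcs %*% beta_pc)
    if (length(config$enriched_sets)) {
      plp_idx <- which(variants$is_plp_truth)
      for (s in names(config$enriched_sets)) {
        idx <- plp_idx[variants$gene[plp_idx] %in% gene_sets[[s]]]
        burden <- count_burden(gm, idx)
        eta <- eta + log(config$enriched_sets[[s]]) * burden
      }
    }
    case <- integer(n_total)
    for (k in seq_len(nrow(strata))) {
      members <- which(samples$stratum == strata$stratum[k])
      w <- exp(eta[members] - max(eta[members]))
      case[members[sample_conditional_bernoulli(w, strata$n_cases[k])]] <- 1L
    }
    dplyr::relocate(dplyr::mutate(samples, case = case),
                    "sample_id", "stratum", "case", "sex")
  })

  structure(
    list(
      variants = variants,
      genotypes = gm,
      samples = samples,
      gene_map = dplyr::distinct(variants[c("gene", "variant_id")]),
      gene_sets = gene_sets,
      config = config
    ),
    class = "rare_cohort"
  )
}

#' @export
print.rare_cohort <- function(x, ...) {
  cat("<rare_cohort>\n")
  cat(sprintf("  %s samples (%s cases / %s controls) in %d strata\n",
              format(nrow(x$samples), big.mark = ","),
              format(sum(x$samples$case), big.mark = ","),
              format(sum(1 - x$samples$case), big.mark = ","),
              length(unique(x$samples$stratum))))
  cat(sprintf("  %s variants in %s genes; %s classified P-LP\n",
              format(nrow(x$variants), big.mark = ","),
              format(length(unique(x$variants$gene)), big.mark = ","),
              format(sum(x$variants$acmg_class %in% c("P", "LP")), big.mark = ",")))
  cat(sprintf("  %d gene sets\n", length(x$gene_sets)))
  invisible(x)
}
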