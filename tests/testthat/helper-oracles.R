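# Independent oracles used to cross-check the package's own implementations.
# These deliberately re-derive each quantity from its definition by a
# different route (rule tables, direct formulas, generic optimization) and
# never call the code paths they validate.

# --- ACMG combining rules as a literal rule table ---------------------------
# Each rule lists the minimum tier counts that trigger it.
oracle_acmg_class <- function(pvs, ps, pm, pp, ba, bs, bp) {
  have <- c(pvs = pvs, ps = ps, pm = pm, pp = pp, ba = ba, bs = bs, bp = bp)
  fires <- function(rule) all(have[names(rule)] >= rule)
  p_rules <- list(
    c(pvs = 1, ps = 1), c(pvs = 1, pm = 2), c(pvs = 1, pm = 1, pp = 1),
    c(pvs = 1, pp = 2),
    c(ps = 2),
    c(ps = 1, pm = 3), c(ps = 1, pm = 2, pp = 2), c(ps = 1, pm = 1, pp = 4)
  )
  lp_rules <- list(
    c(pvs = 1, pm = 1),
    c(ps = 1, pm = 1), c(ps = 1, pp = 2),
    c(pm = 3), c(pm = 2, pp = 2), c(pm = 1, pp = 4)
  )
  b_rules <- list(c(ba = 1), c(bs = 2))
  lb_rules <- list(c(bs = 1, bp = 1), c(bp = 2))
  is_p <- any(vapply(p_rules, fires, logical(1)))
  is_lp <- any(vapply(lp_rules, fires, logical(1)))
  is_b <- any(vapply(b_rules, fires, logical(1)))
  is_lb <- any(vapply(lb_rules, fires, logical(1)))
  if ((is_p || is_lp) && (is_b || is_lb)) return("VUS")
  if (is_p) return("P")
  if (is_lp) return("LP")
  if (is_b) return("B")
  if (is_lb) return("LB")
  "VUS"
}

# --- Firth regression by generic optimization of the penalized likelihood ---
oracle_penalized_loglik <- function(beta, y, x) {
  eta <- as.vector(x %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- t(x) %*% (x * (p * (1 - p)))
  sum(y * eta - log(1 + exp(eta))) + 0.5 * log(det(info))
}

oracle_firth_coefs <- function(y, x) {
  nll <- function(b) -oracle_penalized_loglik(b, y, x)
  o1 <- stats::optim(rep(0, ncol(x)), nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  o2 <- stats::optim(o1$par, nll, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  o2$par
}

# --- Holm step-down adjustment from its definition --------------------------
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(running, 1)
  }
  adj
}

# --- Greedy LD clumping re-simulated with explicit set bookkeeping ----------
oracle_clump <- function(stats, r2, window_bp = 1e6, r2_threshold = 0.1) {
  remaining <- stats
  index <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining$p, remaining$pos, remaining$snp)
    top <- remaining[o[1], ]
    index <- c(index, top$snp)
    claimed <- abs(remaining$pos - top$pos) <= window_bp &
      r2[top$snp, remaining$snp] > r2_threshold
    claimed[o[1]] <- TRUE
    remaining <- remaining[!claimed, , drop = FALSE]
  }
  index
}

# --- shared fixtures ---------------------------------------------------------

# Small simulated cohort reused across tests.
tiny_cohort <- function(scale = 0.1, n_genes = 400L,
                        gene_sets = c(setA = 60L, setB = 60L),
                        enriched_sets = numeric(), seed = 101) {
  simulate_cohort(cohort_config(
    strata = bsc_strata(scale = scale), n_genes = n_genes,
    gene_sets = gene_sets, enriched_sets = enriched_sets, seed = seed
  ))
}

# Twenty hand-built variant records with seven known-qualifying rows
# (1, 4, 5, 7, 9, 12, 13): rare, protein-altering, minor-is-alt, and P/LP
# under the combining rules. Each other row breaks exactly one requirement.
handbuilt_variants <- function() {
  tibble::tibble(
    chrom = 1L, pos = 1000L + seq_len(20), ref = "A", alt = "G",
    gene = paste0("G", seq_len(20)),
    consequence = c("missense", "missense", "synonymous", "stopgain",
                    "splice_site", "missense", "stoploss", "missense",
                    "startloss", "missense", "other", "stopgain",
                    "missense", "missense", "synonymous", "missense",
                    "splice_site", "missense", "stopgain", "missense"),
    af_nfe = c(0.004, 0.02, 0, NA, 0.001, 0.004, 5e-4, 0.004, 0.996,
               0.004, 1e-4, 1e-4, 0.009, 0.011, 0.2, 0.001, 0.004,
               1e-4, 0.004, NA),
    minor_is_alt = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                     TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     TRUE, TRUE, TRUE, TRUE),
    evidence = c("PS1;PM2", "PS1;PM2", "PVS1;PS1", "PVS1;PS1",
                 "PVS1;PM2", "PS1;PM2", "PVS1;PM1", "",
                 "PVS1;PS2", "BA1", "PVS1;PS1", "PM1;PM2;PM4",
                 "PM1;PM2;PP1;PP2", "PVS1;PS1", "", "PP1;PP2;PP3",
                 "BS1;BS2", "PVS1;BA1", "PS1", "PM2;PP1;PP2;PP3")
  )
}
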