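---
title: "Rare-variant gene-set burden testing in stratified case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene-set burden testing in stratified case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raresetburden)
```

## The analysis problem

Large psychiatric and other complex-trait sequencing consortia ask whether
cases carry more rare, functionally damaging coding variants than controls,
either exome-wide or inside candidate gene sets (GWAS-implicated genes,
synaptic gene classes, loss-of-function-intolerant genes). Three features
make this statistically delicate:

* **Sparsity.** Qualifying variants are dominated by singletons, so
  per-gene and even per-set carrier counts are tiny, and ordinary logistic
  regression diverges under the complete separation this produces.
* **Heterogeneous strata.** Cohorts are assembled from studies that differ
  in ancestry, capture platform, depth and case:control ratio; pooling
  individuals naively confounds study with phenotype.
* **Many correlated hypotheses.** Several overlapping gene sets are tested
  at once.

`raresetburden` implements the corresponding analysis recipe end to end:

1. **Variant selection.** Keep biallelic SNVs whose minor allele is the
   alternative allele, with maximum folded population MAF below 1%, a
   protein-altering consequence (missense, splice site, stopgain,
   startloss, stoploss), and an ACMG 2015 class of pathogenic (P) or
   likely pathogenic (LP) derived from evidence codes by the published
   combining rules (`classify_acmg()`, `select_plp()`). Evidence codes are
   inputs: full evidence assignment needs curated databases and is out of
   scope, though `assign_auto_evidence()` derives the two codes
   (PVS1, PM2) that follow from annotations the package already consumes.
2. **Per-stratum burden model.** For a gene or gene set, each individual's
   burden is their summed qualifying-allele count (`count_burden()`).
   Within each stratum, case status is regressed on burden, sex and
   principal components by Firth penalized logistic regression
   (`firth_fit()`), which maximizes
   $\ell(\beta) + \tfrac12 \log \det I(\beta)$ and so stays finite under
   separation.
3. **Meta-analysis.** Stratum Z statistics combine by the weighted Z-score
   method, $Z = \sum_k w_k z_k / \sqrt{\sum_k w_k^2}$, with an upper-tail
   one-sided p for case enrichment; log odds ratios pool by inverse
   variance (`burden_meta()`); the gene-set family is Holm-adjusted
   (`holm_adjust()`).
4. **Design-based validation.** Each set's stratified
   Cochran–Mantel–Haenszel statistic (`cmh_chisq()`) is calibrated against
   an empirical null of random gene sets of equal size drawn from the
   annotated gene universe (`empirical_p()`), which absorbs residual
   case-control imbalances that covariates miss.
5. **Polygenic scores.** A separate common-variant module filters GWAS
   summary statistics across studies, LD-clumps them (1 Mb windows,
   $r^2 > 0.1$, p-value thresholds), scores dosages and meta-analyzes the
   score-phenotype association (`filter_snps()`, `ld_clump()`,
   `score_individuals()`, `prs_association()`).

Because individual-level consortium data cannot be redistributed, the
package ships a fully seeded synthetic cohort generator whose defaults
mirror the consortium structure the method targets, so every stage is
testable end to end without any external download.

## A worked run

```{r worked, eval = FALSE}
cfg <- cohort_config(
  strata = bsc_strata(scale = 0.25),
  n_genes = 1000,
  gene_sets = c(enriched = 165L, null_a = 165L, null_b = 165L),
  enriched_sets = c(enriched = 2.0),
  seed = 1
)
cohort <- simulate_cohort(cfg)
descriptive_report(cohort)
disc <- run_discovery(cohort, B = 999, seed = 1)
disc$results
synonymous_calibration(cohort)
```

## The generator: what it emulates, and how

`simulate_cohort()` produces a variant table, a sparse genotype matrix, a
sample table, a gene-variant map and named gene sets. Its defaults are the
study conditions the package is built around:

* **Seven strata** with fixed case/control counts (three large
  European-ancestry studies at roughly 1:1 or 1:2 case:control ratio plus
  four small ancestry-specific strata; `bsc_strata()`), 3,987 cases and
  5,322 controls at full scale. A single `scale` argument shrinks every
  stratum proportionally for desk-scale experiments.
* **A singleton-dominated P-LP spectrum.** Each P-LP variant's cohort
  minor allele count is drawn from a two-component mixture: probability
  0.81 of a singleton, otherwise a shifted geometric tail with mean 5.26.
  The tail mean makes the average P-LP allele load per individual match
  what large exome studies report (≈1.8 alleles per variant). Other rare
  variants use a flatter mixture (50% singletons, heavier tail), and 5%
  of non-P-LP variants are given common frequencies so the MAF filter has
  real work to do.
* **0.7% of exonic SNVs classified P-LP**, with a consequence-conditional
  classification probability so the P-LP subset is LOF-heavy
  (≈31% stopgain, 20% splice, 47% missense) as evidence-based classifiers
  produce in practice; 38% of P-LP variants are absent from every
  reference population.
* **About 53 variants per gene** (1 + Poisson), which combined with the
  0.7% rate reproduces the empirical density of ≈0.37 P-LP variants per
  gene. This density — not the total exome size — is what drives carrier
  counts per gene set, so a reduced gene universe (the default is 2,000
  genes) preserves realistic per-set sparsity.
* **Population structure** as stratum-level allele-frequency shifts (20%
  of variants concentrate threefold in a random "home" stratum) plus
  ancestry-shifted principal components; sex and the two leading PCs also
  carry disease effects (log-odds 0.25, 0.15, −0.1) that the covariate
  adjustment must absorb. These effect sizes are package choices: the
  consortium literature offers no generative values for them.

**Case-status assignment.** Case labels within a stratum are sampled by
exact conditional-Bernoulli (fixed-size weighted) sampling with weights
equal to the odds $\exp(x_i'\beta)$ of the generating logistic model,
where $x_i$ contains sex, PCs, and the individual's P-LP allele count in
each enriched set with coefficient $\log(\mathrm{OR})$
(`sample_conditional_bernoulli()`). Conditioning a logistic model on the
number of successes leaves its odds ratios untouched, so a configured
enrichment OR is recovered by retrospective regression without
approximation, exact per-stratum counts are hit deterministically, and —
unlike pool-and-subsample schemes — the allele-count spectrum is never
thinned. The implementation uses the elementary-symmetric-polynomial
recursion in log space, $O(Nn)$ per stratum.

All randomness derives from one seed through labelled substreams, so
adding a consumer never perturbs another's draws and identical
configurations are bit-reproducible.

**What the generator does not emulate.** There is no haplotype or
coalescent structure (variants are placed independently), no indels, no
within-stratum correlation between principal components and genotypes, no
genotype-quality or depth model (missingness, when enabled, is applied to
carrier genotypes only, because downstream counting treats missing as
zero), and gene "sets" are uniform draws rather than functionally
coherent groups. Passing tests therefore demonstrate the statistical
machinery — finite-sample behaviour of the Firth fits, calibration of the
empirical null, recovery of configured odds ratios — not robustness to
every artefact of real sequencing data.

## Numerical and design choices

* **Firth fits** use Newton iteration with the hat-diagonal-corrected
  score, step-halving whenever a step would decrease the penalized
  likelihood, and stop when both the largest score component and the
  largest coefficient move fall below 1e-6 (at most 50 iterations).
  Standard errors come from the inverse penalized information and
  confidence intervals are Wald on the log-odds scale — cheaper and
  deterministic, but narrower than the profile-penalized-likelihood
  intervals some Firth implementations default to; this is a known,
  documented divergence risk. Zero-variance columns are dropped with a
  warning before fitting; an all-zero burden column sets a
  `burden_degenerate` flag (OR 1, infinite SE) rather than failing.
* **Meta-analysis weights** default to the square root of effective
  sample size, $\sqrt{4/(1/n_\text{cases} + 1/n_\text{controls})}$, the
  standard convention for unbalanced case-control strata;
  $\sqrt{n}$ weighting is available because the convention is not
  universal. Carrier-free strata contribute no evidence and are dropped
  from the combination, with a log message.
* **The CMH statistic** defaults to Cochran's binomial variance
  ($n_1 n_2 m_1 m_2 / T^3$), under which the single-stratum statistic
  equals the Pearson chi-square without continuity correction exactly;
  the Mantel–Haenszel hypergeometric variance
  ($n_1 n_2 m_1 m_2 / (T^2(T-1))$, as in `stats::mantelhaen.test`) is
  available via `variance = "mh"`. Tables default to carrier
  dichotomization (count ≥ 1): with singleton-dominated variants carrier
  and allele counts nearly coincide, and a 2×2 table needs categorical
  columns; an allele-counting mode (alleles against 2n chromosomes) is
  retained as an option.
* **The empirical null** samples gene sets uniformly without replacement
  from the full annotated gene universe — including genes that happen to
  carry no qualifying variant, so random sets and the observed set
  contain comparable numbers of non-contributing genes. Sampling is not
  matched on gene length or variant count; matching hooks can be added
  via the `gene_universe` argument. The one-sided empirical p uses the
  add-one correction $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ on
  the signed root, so enrichment and depletion are distinguished.
* **LD clumping** anchors windows at each index SNP (closed ±window
  interval, 1-based positions), the standard clumping semantics; ties on
  p break by position then SNP id, making index sets invariant to row
  order. The reference r² panel is supplied or simulated — managing real
  reference panels is out of scope.
* **Nagelkerke pseudo-R²** is the reported variance-explained measure for
  polygenic scores, labelled as such since conventions differ.
* **Multiallelic sites** are excluded wholesale at ingest (all records
  sharing a coordinate with different alternative alleles). A minor-allele
  frequency of exactly 0.5 counts as minor-is-alternative.

## Problem sizes used by the test suite

The packaged checks run the full machinery at reduced scale: null
calibration uses 200 replicate cohorts at one quarter of the full stratum
sizes with a 400-gene universe and 999 random sets per replicate;
odds-ratio recovery uses 50 replicates at the same scale with a
1,000-gene universe and a 165-gene enriched set (matching the carrier
density of a GWAS-loci-sized set); spectrum fidelity uses a 14,000-gene
universe so that more than 5,000 P-LP variants pin the singleton fraction
to ±2%. These sizes are the package's choices for routine verification;
all of them scale up by changing the configuration only.

## Known limitations

Wald rather than profile intervals for Firth fits; no SKAT-style
variance-component or dominance models; no X-chromosome handling; the
empirical null treats gene identity as exchangeable (no length matching);
the PRS module assumes pre-imputed dosages and performs no imputation of
its own. The synonymous-variant negative control (`synonymous_calibration()`)
is the recommended first check on any new dataset: its pooled odds ratio
should sit at 1, and deviations flag confounding before any gene-set
result is interpreted.
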