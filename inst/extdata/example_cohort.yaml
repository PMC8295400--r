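# Example configuration for the synthetic cohort generator: a small
# two-study design with one enriched gene set. Used by the CLI wrapper:
#   Rscript inst/cli/raresetburden.R run-all --config example_cohort.yaml --out out/
strata:
  - {stratum: studyA, n_cases: 120, n_controls: 130, ancestry: EUR}
  - {stratum: studyB, n_cases: 60, n_controls: 120, ancestry: EUR}
n_genes: 200
gene_sets: {candidate: 40, control_set: 40}
enriched_sets: {candidate: 2.0}
n_pcs: 5
seed: 1
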