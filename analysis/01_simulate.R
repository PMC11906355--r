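#!/usr/bin/env Rscript
# Stage 1: simulate the discovery cohort, an independent replication cohort
# drawn from the same population, and an outcome GWAS for the MR stage.
# Run from the repository root: Rscript analysis/01_simulate.R [--seed N]
source("analysis/00_common.R")

seed <- parse_seed()
cfg <- study_config(substream_seed(seed, "discovery"))
disc <- simulate_cohort(cfg)
cat("discovery cohort:", nrow(disc$dosage), "children,",
    ncol(disc$dosage), "variants,", ncol(disc$protein), "proteins;",
    sprintf("%.1f%% protein completeness\n", 100 * mean(!is.na(disc$protein))))
write_cohort(disc, results_dir("cohort_discovery"))

cfg_rep <- study_config(substream_seed(seed, "replication"))
cfg_rep$maf_fixed <- disc$variants$maf  # same population allele frequencies
repl <- simulate_cohort(cfg_rep)
write_cohort(repl, results_dir("cohort_replication"))
cat("replication cohort written (", nrow(repl$dosage), "children )\n")

outcome <- simulate_outcome_gwas(cfg, theta = 0.4, protein_index = 1L,
                                 noise_sd = 0.5, variants = disc$variants)
write_summary_stats(outcome, results_dir("outcome_gwas.tsv"),
                    header = paste0("config_hash: ", config_hash(cfg)))
cat("outcome GWAS simulated with causal effect 0.4 through PROT0001\n")
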