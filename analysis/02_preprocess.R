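#!/usr/bin/env Rscript
# Stage 2: completeness filter, downshifted-normal imputation, inverse normal
# transformation and covariate residualization for proteins and peptides.
source("analysis/00_common.R")

seed <- parse_seed()
bundle <- read_cohort("results/cohort_discovery")
for (kind in c("protein", "peptide")) {
  ph <- prepare_phenotypes(bundle, kind,
                           seed = substream_seed(seed, paste0("impute-", kind)))
  kept <- ncol(ph)
  total <- ncol(bundle[[kind]])
  cat(sprintf("%s: %d of %d features pass the 60%% completeness filter\n",
              kind, kept, total))
  write_matrix_tsv(ph, results_dir(paste0("phenotype_", kind, ".tsv")),
                   header = "standardized association phenotypes (INT residuals)")
}
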