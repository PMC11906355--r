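#!/usr/bin/env Rscript
# Stage 7: predict age and BMI-SDS from protein levels with correlation-
# ranked incremental feature selection.
source("analysis/00_common.R")

seed <- parse_seed()
bundle <- read_cohort("results/cohort_discovery")
prot <- int_matrix(impute_downshifted(filter_completeness(bundle$protein),
                                      seed = substream_seed(seed, "impute-pred")))
cov <- bundle$covariates[match(rownames(prot), bundle$covariates$sample_id), ]

for (outcome in c("age", "bmi_sds")) {
  rep <- train_predictor(prot, cov[[outcome]], k_max = min(200L, ncol(prot)),
                         seed = substream_seed(seed, paste0("predict-", outcome)))
  cat(sprintf("%s: %d features selected, held-out MAE %.2f, Pearson r %.2f (n_test %d)\n",
              outcome, rep$k_selected, rep$test_mae, rep$test_r, rep$n_test))
  data.table::fwrite(rep$mse_curve,
                     results_dir(paste0("predict_", outcome, "_mse_curve.tsv")), sep = "\t")
  data.table::fwrite(data.frame(rank = seq_along(rep$selected_features),
                                feature = rep$selected_features),
                     results_dir(paste0("predict_", outcome, "_features.tsv")), sep = "\t")
}
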