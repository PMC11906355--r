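#!/usr/bin/env Rscript
# Stage 3: multiple-regression association of protein levels with age, sex,
# BMI-SDS and obesity, with BH correction and model diagnostics.
source("analysis/00_common.R")

seed <- parse_seed()
bundle <- read_cohort("results/cohort_discovery")
prot <- int_matrix(impute_downshifted(filter_completeness(bundle$protein),
                                      seed = substream_seed(seed, "impute-pheno")))
res <- fit_pheno_model(prot, bundle$covariates)
data.table::fwrite(res, results_dir("pheno_associations.tsv"), sep = "\t")

sig <- res[res$p_adj < 0.05, ]
cat("significant (BH < 0.05) protein-term associations by term:\n")
print(table(sig$term))

diag <- pheno_diagnostics(prot, bundle$covariates,
                          seed = substream_seed(seed, "diagnostics"))
cat(sprintf("max VIF %.2f; residuals normal (Shapiro-Wilk p > 0.05) for %.0f%% of proteins\n",
            max(diag$vif$vif), 100 * diag$fraction_normal))
data.table::fwrite(diag$vif, results_dir("vif.tsv"), sep = "\t")
data.table::fwrite(diag$normality, results_dir("residual_normality.tsv"), sep = "\t")
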