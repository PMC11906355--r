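#!/usr/bin/env Rscript
# Stage 6: variance decomposition of protein levels and pQTL effect sizes
# (allelic fold changes on the untransformed scale).
source("analysis/00_common.R")

bundle <- read_cohort("results/cohort_discovery")
ph <- read_matrix_tsv("results/phenotype_protein.tsv")
pq <- as.data.frame(data.table::fread("results/primary_pqtls.tsv"))
cond <- as.data.frame(data.table::fread("results/conditional_signals.tsv"))
cov <- bundle$covariates[match(rownames(ph), bundle$covariates$sample_id), ]

vex <- do.call(rbind, lapply(unique(pq$protein_id), function(prot) {
  leads <- unique(c(pq$variant_id[pq$protein_id == prot],
                    cond$variant_id[cond$protein_id == prot]))
  dec <- decompose_variance(ph[, prot], bundle$dosage[rownames(ph), leads, drop = FALSE], cov)
  data.frame(protein_id = prot, t(dec$fractions), total_r2 = dec$total_r2)
}))
cat(sprintf("independent pQTLs explain %.0f%% to %.0f%% of protein variance (mean %.0f%%)\n",
            100 * min(vex$pqtl), 100 * max(vex$pqtl), 100 * mean(vex$pqtl)))
data.table::fwrite(vex, results_dir("variance_decomposition.tsv"), sep = "\t")

leads_by_prot <- lapply(stats::setNames(unique(pq$protein_id), unique(pq$protein_id)),
                        function(prot) {
  v <- unique(c(pq$variant_id[pq$protein_id == prot],
                cond$variant_id[cond$protein_id == prot]))
  bundle$dosage[rownames(ph), v, drop = FALSE]
})
st <- age_group_stability(ph[, unique(pq$protein_id), drop = FALSE],
                          leads_by_prot, cov, min_n = 50L)
cat("stability of genetic variance fractions across age groups:\n")
print(st$correlations)
data.table::fwrite(st$correlations, results_dir("age_group_stability.tsv"), sep = "\t")

afc <- do.call(rbind, lapply(seq_len(nrow(pq)), function(i) {
  raw <- 2^bundle$protein[rownames(ph), pq$protein_id[i]]
  a <- allelic_fold_change(raw, bundle$dosage[rownames(ph), pq$variant_id[i]])
  data.frame(protein_id = pq$protein_id[i], variant_id = pq$variant_id[i],
             afc_het = a$afc_het, afc_hom = a$afc_hom, log2_fc_hom = a$log2_fc_hom)
}))
big <- sum(abs(afc$log2_fc_hom) > 1, na.rm = TRUE)
cat(sprintf("%d pQTLs exceed two-fold protein differences between homozygotes\n", big))
data.table::fwrite(afc, results_dir("allelic_fold_changes.tsv"), sep = "\t")
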