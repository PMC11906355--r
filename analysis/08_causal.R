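#!/usr/bin/env Rscript
# Stage 8: two-sample Mendelian randomization (Wald ratio at the top
# cis-pQTL) and approximate-Bayes-factor colocalization against the
# simulated outcome GWAS.
source("analysis/00_common.R")

bundle <- read_cohort("results/cohort_discovery")
ph <- read_matrix_tsv("results/phenotype_protein.tsv")
pq <- as.data.frame(data.table::fread("results/primary_pqtls.tsv"))
outcome <- read_summary_stats("results/outcome_gwas.tsv")

cis <- pq[pq$cis %in% TRUE, ]
rows <- list()
for (prot in unique(cis$protein_id)) {
  top <- cis[cis$protein_id == prot, ][which.min(cis$p_lead[cis$protein_id == prot]), ]
  scan <- assoc_scan(bundle$dosage[rownames(ph), ], ph[, prot])
  vt <- bundle$variants
  expo <- data.frame(variant_id = scan$variant_id, chrom = vt$chrom, pos = vt$pos,
                     effect_allele = vt$alt, other_allele = vt$ref,
                     eaf = colMeans(bundle$dosage[rownames(ph), ]) / 2,
                     beta = scan$beta, se = scan$se, pval = scan$p, n = scan$n)
  res <- tryCatch(causal_test(expo, outcome, top$variant_id),
                  error = function(e) NULL)
  if (is.null(res)) next
  rows[[prot]] <- data.frame(protein_id = prot, instrument = top$variant_id,
                             wald_beta = res$wald_beta, wald_se = res$wald_se,
                             wald_p = res$wald_p, mr_significant = res$significant,
                             pp4 = res$posteriors["PP4"],
                             regional_probability = res$regional_probability,
                             colocalized = res$colocalized)
}
causal <- do.call(rbind, rows)
rownames(causal) <- NULL
# the exposure phenotype is standardized, so wald_beta is the trait effect
# per SD of protein level, not per log2 unit
print(causal)
cat(sprintf("%d of %d cis proteins show both MR support and colocalization\n",
            sum(causal$mr_significant & causal$colocalized), nrow(causal)))
data.table::fwrite(causal, results_dir("causal_results.tsv"), sep = "\t")
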