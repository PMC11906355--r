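#!/usr/bin/env Rscript
# Stage 5: peptide-level validation of primary pQTLs — artefact exclusion
# and confidence tiers.
source("analysis/00_common.R")

bundle <- read_cohort("results/cohort_discovery")
pep <- read_matrix_tsv("results/phenotype_peptide.tsv")
pq <- as.data.frame(data.table::fread("results/primary_pqtls.tsv"))

# the artefact-planted proteins are not protein-level pQTLs by construction;
# test them too, as candidate variant-protein pairs flagged by external lists
candidates <- rbind(pq[, c("protein_id", "variant_id")],
                    data.frame(protein_id = c("PROT0005", "PROT0006"),
                               variant_id = c("var00210", "var00260")))
bundle$dosage <- bundle$dosage[rownames(pep), , drop = FALSE]
tiers <- tier_pqtls(candidates, bundle, pep)
cat("tier assignment of candidate variant-protein associations:\n")
print(table(tiers$tier))
conc <- suppressWarnings(concordance_summary(tiers))
cat(sprintf("direction concordance among multi-peptide pQTLs: %.2f\n", conc))
data.table::fwrite(tiers, results_dir("pqtl_tiers.tsv"), sep = "\t")
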