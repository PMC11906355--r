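#!/usr/bin/env Rscript
# Stage 4: genotype QC, per-protein association scans, LD clumping into
# primary pQTLs, cis/trans classification and conditional analysis.
source("analysis/00_common.R")

bundle <- read_cohort("results/cohort_discovery")
ph <- read_matrix_tsv("results/phenotype_protein.tsv")

qc <- qc_genotypes(bundle$dosage, bundle$variants)
cat(sprintf("QC: dropped %d variants (call rate %d, MAF %d, HWE %d), %d samples\n",
            qc$report$variants_dropped_callrate + qc$report$variants_dropped_maf +
              qc$report$variants_dropped_hwe,
            qc$report$variants_dropped_callrate, qc$report$variants_dropped_maf,
            qc$report$variants_dropped_hwe,
            qc$report$samples_dropped_callrate + qc$report$samples_dropped_heterozygosity))
keep <- intersect(rownames(qc$dosage), rownames(ph))
dosage <- qc$dosage[keep, ]
ph <- ph[keep, ]

scans <- assoc_scan_multi(dosage, ph)
lambda <- apply(scans$p, 2, lambda_gc)
cat(sprintf("median lambda_GC across %d proteins: %.3f\n", ncol(ph), median(lambda)))

pq <- map_pqtls(dosage, qc$variants, ph, bundle$gene_map)
cat(sprintf("%d primary pQTLs for %d proteins at P < 5e-8 (%d cis, %d trans)\n",
            nrow(pq), length(unique(pq$protein_id)),
            sum(pq$cis %in% TRUE), sum(pq$cis %in% FALSE)))
sw <- study_wide_threshold(5e-8, ncol(ph))
cat(sprintf("study-wide threshold %.2e: %d pQTLs pass\n", sw, sum(pq$p_lead < sw)))

cond <- do.call(rbind, lapply(unique(pq$protein_id), function(prot) {
  vars <- unique(unlist(strsplit(pq$members[pq$protein_id == prot], ";")))
  cs <- conditional_scan(dosage[, vars, drop = FALSE], ph[, prot])
  if (nrow(cs) > 0) cbind(protein_id = prot, cs) else NULL
}))
cat(sprintf("%d conditionally independent signals\n", nrow(cond)))

data.table::fwrite(pq, results_dir("primary_pqtls.tsv"), sep = "\t")
data.table::fwrite(cond, results_dir("conditional_signals.tsv"), sep = "\t")
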