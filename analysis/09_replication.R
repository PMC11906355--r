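#!/usr/bin/env Rscript
# Stage 9: replication of the discovered pQTLs in the independent cohort and
# novelty assessment against a published-pQTL list.
source("analysis/00_common.R")

seed <- parse_seed()
repl <- read_cohort("results/cohort_replication")
pq <- as.data.frame(data.table::fread("results/primary_pqtls.tsv"))

ph_r <- prepare_phenotypes(repl, "protein",
                           seed = substream_seed(seed, "impute-replication"))
rr <- replicate_pqtls(pq, repl$dosage[rownames(ph_r), ], ph_r)
cat(sprintf("replication: %.0f%% of %d eligible pQTLs at nominal P < 0.05 with concordant direction\n",
            100 * rr$summary$rate_overall, rr$summary$n_eligible))
cat(sprintf("  cis %.0f%%, trans %s; discovery-vs-replication beta r = %.2f\n",
            100 * rr$summary$rate_cis,
            ifelse(is.na(rr$summary$rate_trans), "n/a",
                   sprintf("%.0f%%", 100 * rr$summary$rate_trans)),
            rr$summary$beta_r))
data.table::fwrite(rr$records, results_dir("replication.tsv"), sep = "\t")

# a small published list: one known locus for PROT0001 at its lead position,
# nothing for the remaining proteins
published <- data.frame(protein_id = "PROT0001",
                        chrom = pq$chrom[pq$protein_id == "PROT0001"][1],
                        pos = pq$pos[pq$protein_id == "PROT0001"][1])
nov <- assess_novelty(pq, published)
cat(sprintf("novelty: %d of %d pQTLs have no published variant within 1 Mb for the same protein\n",
            sum(nov$novel), nrow(nov)))
data.table::fwrite(nov, results_dir("novelty.tsv"), sep = "\t")
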