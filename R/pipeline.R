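#' Run the full analysis pipeline on a cohort bundle
#'
#' Chains preprocessing, phenotype association, genotype QC, pQTL mapping,
#' conditional analysis, peptide-level tiering, variance decomposition,
#' allelic fold changes, age/BMI prediction and (when an outcome GWAS is
#' supplied) Wald-ratio MR plus colocalization for the top cis-pQTLs.
#' Returns all stage results in memory; the numbered analysis scripts are
#' thin wrappers that call this and write tables.
#'
#' @param bundle a `cohort_bundle`.
#' @param p_max genome-wide significance threshold (default 5e-8).
#' @param alpha_pep peptide-level threshold (default 2.4e-5).
#' @param outcome_stats optional outcome-GWAS summary statistics for MR and
#'   colocalization.
#' @param predict_outcomes character subset of c("age", "bmi_sds").
#' @param seed root seed for stage substreams (defaults to the bundle's).
#' @return named list of stage outputs plus a run manifest.
#' @export
run_pipeline <- function(bundle, p_max = 5e-8, alpha_pep = 2.4e-5,
                         outcome_stats = NULL,
                         predict_outcomes = c("age", "bmi_sds"),
                         seed = NULL) {
  if (is.null(seed)) seed <- bundle$config$seed
  if (is.na(seed)) seed <- 1L
  out <- list()

  log_msg("preprocess: protein and peptide phenotypes")
  protein_pheno <- prepare_phenotypes(bundle, "protein",
                                      seed = substream_seed(seed, "impute-protein"))
  peptide_pheno <- prepare_phenotypes(bundle, "peptide",
                                      seed = substream_seed(seed, "impute-peptide"))

  log_msg("phenotype association: age, sex, BMI-SDS, obesity")
  protein_imp <- int_matrix(impute_downshifted(
    filter_completeness(bundle$protein), seed = substream_seed(seed, "impute-pheno")))
  out$pheno <- fit_pheno_model(protein_imp, bundle$covariates)
  out$diagnostics <- pheno_diagnostics(protein_imp, bundle$covariates)

  log_msg("genotype QC")
  qc <- qc_genotypes(bundle$dosage, bundle$variants)
  out$qc_report <- qc$report
  keep_samples <- intersect(rownames(qc$dosage), rownames(protein_pheno))
  dosage <- qc$dosage[keep_samples, , drop = FALSE]
  protein_pheno <- protein_pheno[keep_samples, , drop = FALSE]
  peptide_pheno <- peptide_pheno[keep_samples, , drop = FALSE]

  log_msg("pQTL mapping: scan + clump + cis/trans")
  out$pqtls <- map_pqtls(dosage, qc$variants, protein_pheno, bundle$gene_map,
                         p_max = p_max)

  log_msg("conditional analysis per protein")
  cond <- list()
  for (prot in unique(out$pqtls$protein_id)) {
    leads <- out$pqtls[out$pqtls$protein_id == prot, ]
    region_vars <- unique(unlist(strsplit(leads$members, ";")))
    cs <- conditional_scan(dosage[, region_vars, drop = FALSE],
                           protein_pheno[, prot], p_max = p_max)
    if (nrow(cs) > 0) { cs$protein_id <- prot; cond[[prot]] <- cs }
  }
  out$conditional <- if (length(cond) > 0) do.call(rbind, cond) else NULL

  if (nrow(out$pqtls) > 0) {
    log_msg("peptide-level tiers for ", nrow(out$pqtls), " primary pQTLs")
    out$tiers <- tier_pqtls(out$pqtls, bundle, peptide_pheno, alpha_pep = alpha_pep)
    out$concordance <- suppressWarnings(concordance_summary(out$tiers))

    log_msg("variance decomposition and allelic fold change")
    out$varexp <- lapply(unique(out$pqtls$protein_id), function(prot) {
      leads <- unique(c(out$pqtls$variant_id[out$pqtls$protein_id == prot],
                        if (!is.null(out$conditional))
                          out$conditional$variant_id[out$conditional$protein_id == prot]))
      dec <- decompose_variance(protein_pheno[, prot],
                                dosage[, leads, drop = FALSE],
                                bundle$covariates[match(keep_samples, bundle$covariates$sample_id), ])
      c(list(protein_id = prot), dec$fractions, total_r2 = dec$total_r2)
    })
    out$afc <- do.call(rbind, lapply(seq_len(nrow(out$pqtls)), function(i) {
      raw <- 2^bundle$protein[keep_samples, out$pqtls$protein_id[i]]
      a <- allelic_fold_change(raw, dosage[, out$pqtls$variant_id[i]])
      data.frame(protein_id = out$pqtls$protein_id[i],
                 variant_id = out$pqtls$variant_id[i],
                 afc_het = a$afc_het, afc_hom = a$afc_hom,
                 log2_fc_hom = a$log2_fc_hom, stringsAsFactors = FALSE)
    }))
  }

  log_msg("protein-based prediction")
  out$prediction <- list()
  cov <- bundle$covariates[match(rownames(protein_imp), bundle$covariates$sample_id), ]
  if ("age" %in% predict_outcomes) {
    out$prediction$age <- train_predictor(protein_imp, cov$age,
                                          k_max = min(200L, ncol(protein_imp)),
                                          seed = substream_seed(seed, "predict-age"))
  }
  if ("bmi_sds" %in% predict_outcomes) {
    out$prediction$bmi_sds <- train_predictor(protein_imp, cov$bmi_sds,
                                              k_max = min(200L, ncol(protein_imp)),
                                              seed = substream_seed(seed, "predict-bmi"))
  }

  if (!is.null(outcome_stats) && nrow(out$pqtls) > 0) {
    log_msg("Mendelian randomization + colocalization for top cis-pQTLs")
    cis <- out$pqtls[out$pqtls$cis %in% TRUE, ]
    out$causal <- list()
    for (prot in unique(cis$protein_id)) {
      rows <- cis[cis$protein_id == prot, ]
      top <- rows[which.min(rows$p_lead), ]
      scan <- assoc_scan(dosage, protein_pheno[, prot])
      expo <- data.frame(variant_id = scan$variant_id,
                         chrom = qc$variants$chrom, pos = qc$variants$pos,
                         effect_allele = qc$variants$alt,
                         other_allele = qc$variants$ref,
                         eaf = colMeans(dosage) / 2,
                         beta = scan$beta, se = scan$se, pval = scan$p,
                         n = scan$n, stringsAsFactors = FALSE)
      out$causal[[prot]] <- tryCatch(
        causal_test(expo, outcome_stats, top$variant_id),
        error = function(e) list(error = conditionMessage(e)))
    }
  }

  out$manifest <- list(seed = seed, config_hash = config_hash(bundle$config),
                       n_samples = nrow(bundle$dosage),
                       n_variants_post_qc = ncol(dosage),
                       n_proteins = ncol(protein_pheno),
                       package_version = as.character(utils::packageVersion("pedpqtl")))
  out
}
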