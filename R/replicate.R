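#' Replicate discovered pQTLs in an independent cohort
#'
#' For every discovery pQTL whose lead variant and protein survive the
#' replication cohort's own QC and preprocessing, re-runs the association of
#' the same lead variant (no re-clumping) and flags replication at nominal
#' significance with a concordant direction of effect.
#'
#' @param discovery data.frame of primary pQTLs (protein_id, variant_id,
#'   beta_lead, se_lead, p_lead, cis).
#' @param rep_dosage replication-cohort dosage matrix (post-QC).
#' @param rep_phenotypes replication-cohort standardized protein phenotypes
#'   (preprocessed with the identical pipeline).
#' @param alpha replication significance level (default 0.05).
#' @return list with `records` (per-pQTL data.frame including replicated and
#'   eligible flags) and `summary` (replication rate overall and by
#'   cis/trans, Pearson r of discovery vs replication betas among replicated
#'   pQTLs).
#' @export
replicate_pqtls <- function(discovery, rep_dosage, rep_phenotypes, alpha = 0.05) {
  eligible <- discovery$variant_id %in% colnames(rep_dosage) &
    discovery$protein_id %in% colnames(rep_phenotypes)
  if (!any(eligible)) stop("no pQTLs eligible for replication")
  rec <- discovery
  rec$eligible <- eligible
  rec$rep_beta <- rec$rep_se <- rec$rep_p <- NA_real_
  for (i in which(eligible)) {
    scan <- assoc_scan(rep_dosage[, rec$variant_id[i], drop = FALSE],
                       rep_phenotypes[, rec$protein_id[i]])
    rec$rep_beta[i] <- scan$beta[1]
    rec$rep_se[i] <- scan$se[1]
    rec$rep_p[i] <- scan$p[1]
  }
  rec$replicated <- rec$eligible & !is.na(rec$rep_p) & rec$rep_p < alpha &
    sign(rec$rep_beta) == sign(rec$beta_lead)
  el <- rec[rec$eligible, , drop = FALSE]
  rate_by <- function(mask) if (!any(mask)) NA_real_ else mean(el$replicated[mask])
  repl <- el[el$replicated, , drop = FALSE]
  summary <- list(
    n_eligible = nrow(el),
    rate_overall = mean(el$replicated),
    rate_cis = rate_by(el$cis %in% TRUE),
    rate_trans = rate_by(el$cis %in% FALSE),
    beta_r = if (nrow(repl) >= 3) stats::cor(repl$beta_lead, repl$rep_beta) else NA_real_)
  list(records = rec, summary = summary)
}

#' Flag novel pQTLs against previously published associations
#'
#' A primary pQTL is novel when no published variant for the same protein
#' lies within `window_bp` of its lead position (on the same chromosome).
#' LD between variants is deliberately not considered.
#'
#' @param pqtls data.frame with protein_id, chrom, pos.
#' @param published data.frame of published associations with protein_id,
#'   chrom, pos.
#' @param window_bp matching window (default 1 Mb, inclusive).
#' @return `pqtls` with added logical column `novel`; proteins absent from
#'   the published list entirely count as novel, and published rows whose
#'   protein identifier matches nothing in `pqtls` are counted in the
#'   `unmatched_published` attribute.
#' @export
assess_novelty <- function(pqtls, published, window_bp = 1e6) {
  novel <- vapply(seq_len(nrow(pqtls)), function(i) {
    hits <- published[published$protein_id == pqtls$protein_id[i] &
                        published$chrom == pqtls$chrom[i] &
                        abs(published$pos - pqtls$pos[i]) <= window_bp, , drop = FALSE]
    nrow(hits) == 0L
  }, logical(1))
  pqtls$novel <- novel
  attr(pqtls, "unmatched_published") <-
    sum(!published$protein_id %in% pqtls$protein_id)
  pqtls
}
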