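#' Does a peptide span a variant amino-acid position?
#'
#' True when the 1-based substitution position falls inside the peptide's
#' residue span extended by `flank` residues on each side; the flank captures
#' cleavage-site artefacts, where a substitution adjacent to a tryptic
#' peptide alters its detectability without being part of it.
#'
#' @param aa_start,aa_end 1-based inclusive peptide coordinates.
#' @param aa_pos 1-based substitution position; must be non-missing.
#' @param flank flank margin in residues (default 1).
#' @return logical.
#' @export
spans_variant <- function(aa_start, aa_end, aa_pos, flank = 1L) {
  if (any(is.na(aa_pos))) stop("aa_pos missing for a coding variant")
  aa_pos >= aa_start - flank & aa_pos <= aa_end + flank
}

#' Peptide-level support for one primary pQTL
#'
#' Tests every protein-group-specific peptide of the pQTL's protein against
#' the lead variant dosage and records how many pass the peptide-level
#' significance threshold, the signs of their effects, and whether each
#' significant peptide spans the variant residue.
#'
#' @param peptide_pheno samples x peptides matrix preprocessed identically to
#'   the protein phenotypes (filter, impute, INT, residualize).
#' @param peptide_map peptide_id, protein_id, aa_start, aa_end.
#' @param dosage_lead dosage vector of the lead variant.
#' @param protein_id the pQTL's protein.
#' @param variant row of the variant table for the lead (consequence, gene_id,
#'   aa_pos used).
#' @param gene_map protein-to-gene map (to decide whether the variant resides
#'   within the protein-coding gene).
#' @param alpha_pep peptide significance threshold (default 2.4e-5).
#' @param flank flank margin for [spans_variant()].
#' @return a `tier_record` list (pre-tier; pass to [assign_tier()]).
#' @export
peptide_support <- function(peptide_pheno, peptide_map, dosage_lead,
                            protein_id, variant, gene_map,
                            alpha_pep = 2.4e-5, flank = 1L) {
  peps <- peptide_map[peptide_map$protein_id == protein_id, , drop = FALSE]
  peps <- peps[peps$peptide_id %in% colnames(peptide_pheno), , drop = FALSE]
  rec <- list(variant_id = variant$variant_id, protein_id = protein_id,
              n_peptides_total = nrow(peps), n_peptides_significant = 0L,
              directions = integer(0), significant_peptides = character(0),
              consequence = variant$consequence,
              in_gene = identical(variant$gene_id, gene_map$gene_id[
                match(protein_id, gene_map$protein_id)]),
              aa_pos = variant$aa_pos, spanning = FALSE,
              tier = "unclassified", reason = NA_character_)
  class(rec) <- "tier_record"
  if (nrow(peps) == 0L) {
    rec$reason <- "no testable peptides"
    return(rec)
  }
  res <- assoc_scan_multi(matrix(as.numeric(dosage_lead), ncol = 1,
                                 dimnames = list(NULL, "lead")),
                          peptide_pheno[, peps$peptide_id, drop = FALSE])
  sig <- which(res$p[1, ] < alpha_pep)
  rec$n_peptides_significant <- length(sig)
  rec$directions <- sign(res$beta[1, sig])
  rec$significant_peptides <- peps$peptide_id[sig]
  if (length(sig) == 1L && !is.na(rec$aa_pos)) {
    rec$spanning <- spans_variant(peps$aa_start[sig], peps$aa_end[sig],
                                  rec$aa_pos, flank = flank)
  }
  rec
}

#' Assign a confidence tier to a pQTL from its peptide-level evidence
#'
#' Decision tree:
#' \itemize{
#'   \item Tier 1: at least two significant peptides, all with the same
#'     direction of effect.
#'   \item Tiers 2-4 require exactly one significant peptide and at most
#'     three testable peptides in total.
#'   \item Tier 2: the variant is non-synonymous (missense) and does not
#'     reside within the protein-coding gene.
#'   \item Tier 3: non-synonymous inside the protein-coding gene, and the
#'     supporting peptide does not span the substituted residue.
#'   \item Excluded artefact: non-synonymous inside the gene and the single
#'     supporting peptide spans the substituted residue — the association is
#'     a detectability artefact, not a protein-level effect. Exclusion
#'     applies regardless of the total peptide count.
#'   \item Tier 4: the variant is synonymous.
#' }
#' Records matching no rule (discordant multi-peptide support; one
#' significant peptide of more than three; no significant peptides) are
#' labelled unclassified with a reason, never dropped.
#'
#' @param rec a `tier_record` from [peptide_support()].
#' @return the record with `tier` set.
#' @export
assign_tier <- function(rec) {
  ns <- rec$n_peptides_significant
  if (ns >= 2L) {
    if (length(unique(rec$directions)) == 1L) {
      rec$tier <- "tier1"
    } else {
      rec$tier <- "unclassified"
      rec$reason <- "multiple significant peptides with discordant directions"
    }
    return(rec)
  }
  if (ns == 0L) {
    rec$tier <- "unclassified"
    if (is.na(rec$reason)) rec$reason <- "no significant peptides"
    return(rec)
  }
  # exactly one significant peptide; a spanning non-synonymous variant is an
  # artefact no matter how many peptides were testable, while the genuine
  # tiers 2-4 additionally require at most three testable peptides
  nonsyn <- rec$consequence %in% c("missense", "stop_gained", "nonsynonymous")
  if (nonsyn && isTRUE(rec$in_gene) && isTRUE(rec$spanning)) {
    rec$tier <- "excluded_artefact"
    return(rec)
  }
  if (rec$n_peptides_total > 3L) {
    rec$tier <- "unclassified"
    rec$reason <- "single supporting peptide but more than three testable peptides"
    return(rec)
  }
  if (rec$consequence == "synonymous") {
    rec$tier <- "tier4"
  } else if (nonsyn) {
    if (!isTRUE(rec$in_gene)) {
      rec$tier <- "tier2"
    } else {
      rec$tier <- "tier3"
    }
  } else {
    rec$tier <- "unclassified"
    rec$reason <- "single supporting peptide, non-coding variant"
  }
  rec
}

#' Tier every primary pQTL in a cohort
#'
#' Convenience driver: computes peptide support and assigns a tier for each
#' row of a primary-pQTL table.
#'
#' @param pqtls data.frame from [map_pqtls()].
#' @param bundle the `cohort_bundle`.
#' @param peptide_pheno preprocessed peptide phenotypes (see
#'   [prepare_phenotypes()]).
#' @param alpha_pep peptide threshold (default 2.4e-5).
#' @param flank flank margin.
#' @return data.frame with one row per pQTL: tier and evidence fields.
#' @export
tier_pqtls <- function(pqtls, bundle, peptide_pheno, alpha_pep = 2.4e-5,
                       flank = 1L) {
  rows <- lapply(seq_len(nrow(pqtls)), function(i) {
    v <- bundle$variants[match(pqtls$variant_id[i], bundle$variants$variant_id), ]
    rec <- peptide_support(peptide_pheno, bundle$peptide_map,
                                bundle$dosage[, pqtls$variant_id[i]],
                                pqtls$protein_id[i], v, bundle$gene_map,
                                alpha_pep = alpha_pep, flank = flank)
    rec <- assign_tier(rec)
    data.frame(variant_id = rec$variant_id, protein_id = rec$protein_id,
               n_peptides_total = rec$n_peptides_total,
               n_peptides_significant = rec$n_peptides_significant,
               concordant = length(rec$directions) > 0 &&
                 length(unique(rec$directions)) == 1L,
               consequence = rec$consequence, in_gene = rec$in_gene,
               spanning = rec$spanning, tier = rec$tier,
               reason = rec$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of multi-peptide pQTLs with directionally concordant support
#'
#' @param tiers data.frame from [tier_pqtls()].
#' @return fraction in [0, 1] over records with at least two significant
#'   peptides; NA (with a warning) when there are none.
#' @export
concordance_summary <- function(tiers) {
  multi <- tiers[tiers$n_peptides_significant >= 2L, , drop = FALSE]
  if (nrow(multi) == 0L) {
    warning("no pQTLs with two or more significant peptides")
    return(NA_real_)
  }
  mean(multi$concordant)
}
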