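#' Squared Pearson correlation between two dosage vectors
#'
#' @param a,b dosage vectors over the same samples; pairwise-complete
#'   observations are used.
#' @return r-squared scalar.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("constant dosage vector: LD undefined")
  }
  stats::cor(a[ok], b[ok])^2
}

#' Greedy LD clumping of association results for one protein
#'
#' Repeatedly takes the smallest-p unassigned variant passing `p_max` as a
#' clump lead and assigns to it every unassigned variant with r-squared above
#' `r2_min` AND within `window_bp` of the lead. Ties on p are broken by
#' smaller genomic position. Each lead is one primary pQTL.
#'
#' @param assoc data.frame with variant_id, beta, se, p (one protein's scan).
#' @param variants variant table with variant_id, chrom, pos.
#' @param dosage samples x variants matrix covering all variants in `assoc`.
#' @param r2_min LD threshold (default 0.2, exclusive: members need r2 >
#'   r2_min).
#' @param window_bp clump window around the lead (default 1 Mb, inclusive).
#' @param p_max significance threshold (default 5e-8, exclusive: p < p_max).
#' @return data.frame, one row per clump: lead variant_id, chrom, pos,
#'   beta_lead, se_lead, p_lead, n_members, members (semicolon-joined).
#' @export
clump <- function(assoc, variants, dosage, r2_min = 0.2, window_bp = 1e6,
                  p_max = 5e-8) {
  missing_geno <- setdiff(assoc$variant_id, colnames(dosage))
  if (length(missing_geno) > 0) {
    stop("genotypes missing for variants: ", paste(utils::head(missing_geno), collapse = ", "))
  }
  vmap <- variants[match(assoc$variant_id, variants$variant_id), ]
  sig <- which(!is.na(assoc$p) & assoc$p < p_max)
  assigned <- rep(FALSE, nrow(assoc))
  out <- list()
  while (length(rem <- sig[!assigned[sig]]) > 0) {
    # smallest p, ties broken by smaller genomic position
    ord <- rem[order(assoc$p[rem], vmap$pos[rem])]
    lead <- ord[1]
    g_lead <- dosage[, assoc$variant_id[lead]]
    cand <- which(!assigned &
                    vmap$chrom == vmap$chrom[lead] &
                    abs(vmap$pos - vmap$pos[lead]) <= window_bp)
    cand <- setdiff(cand, lead)
    in_ld <- vapply(cand, function(j) {
      g <- dosage[, assoc$variant_id[j]]
      ok <- !is.na(g) & !is.na(g_lead)
      if (stats::sd(g[ok]) == 0 || stats::sd(g_lead[ok]) == 0) return(FALSE)
      stats::cor(g[ok], g_lead[ok])^2 > r2_min
    }, logical(1))
    members <- cand[in_ld]
    assigned[c(lead, members)] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      variant_id = assoc$variant_id[lead],
      chrom = vmap$chrom[lead], pos = vmap$pos[lead],
      beta_lead = assoc$beta[lead], se_lead = assoc$se[lead],
      p_lead = assoc$p[lead], n_members = length(members) + 1L,
      members = paste(assoc$variant_id[c(lead, members)], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), beta_lead = numeric(), se_lead = numeric(),
                      p_lead = numeric(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify primary pQTLs as cis or trans
#'
#' A pQTL is cis when its lead variant lies within `window_bp` (inclusive) of
#' the transcription start site of the gene encoding the protein, on the same
#' chromosome; otherwise trans. The signed distance is reported in TSS-strand
#' orientation (negative = upstream of the TSS).
#'
#' @param pqtls data.frame with protein_id, chrom, pos (lead position).
#' @param gene_map data.frame with protein_id, chrom, tss, strand.
#' @param window_bp cis window (default 1 Mb).
#' @return `pqtls` with added columns cis (logical; NA when the protein has
#'   no mapped gene) and tss_distance.
#' @export
classify_cis_trans <- function(pqtls, gene_map, window_bp = 1e6) {
  idx <- match(pqtls$protein_id, gene_map$protein_id)
  gm <- gene_map[idx, ]
  same_chrom <- !is.na(idx) & pqtls$chrom == gm$chrom
  raw_dist <- pqtls$pos - gm$tss
  dist <- ifelse(gm$strand == "-", -raw_dist, raw_dist)
  pqtls$cis <- ifelse(is.na(idx), NA,
                      same_chrom & abs(raw_dist) <= window_bp)
  pqtls$tss_distance <- ifelse(same_chrom, dist, NA_real_)
  pqtls
}

#' Forward-selection conditional analysis within a region
#'
#' Starting from the unconditional scan, repeatedly adds the most significant
#' variant as a covariate and rescans the remaining variants conditional on
#' all selected leads, while the smallest conditional p-value stays below
#' `p_max`. Stops early if the selected dosages become collinear.
#'
#' @param dosage samples x variants complete dosage matrix for the region.
#' @param y standardized phenotype vector.
#' @param p_max significance threshold (default 5e-8).
#' @param max_iter maximum number of conditionally independent signals.
#' @return data.frame with variant_id, conditional_rank, beta, se, p
#'   (estimates from the scan in which each variant was selected).
#' @export
conditional_scan <- function(dosage, y, p_max = 5e-8, max_iter = 10L) {
  stopifnot(is.matrix(dosage))
  selected <- integer(0)
  rows <- list()
  for (iter in seq_len(max_iter)) {
    if (length(selected) == 0) {
      scan <- assoc_scan(dosage, y)
    } else {
      Z <- cbind(1, dosage[, selected, drop = FALSE])
      if (qr(Z)$rank < ncol(Z)) {
        warning("selected dosages collinear; stopping conditional analysis")
        break
      }
      scan <- conditional_assoc(dosage, y, dosage[, selected, drop = FALSE])
    }
    scan$p[selected] <- NA_real_
    best <- which.min(scan$p)
    if (length(best) == 0 || is.na(scan$p[best]) || scan$p[best] >= p_max) break
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = scan$variant_id[best], conditional_rank = length(selected) + 1L,
      beta = scan$beta[best], se = scan$se[best], p = scan$p[best],
      stringsAsFactors = FALSE)
    selected <- c(selected, best)
  }
  if (length(rows) == 0) {
    return(data.frame(variant_id = character(), conditional_rank = integer(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Association of y with each variant, adjusting for a matrix of selected
# dosages; exact multiple regression per candidate variant.
conditional_assoc <- function(dosage, y, covar) {
  m <- ncol(dosage)
  beta <- se <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    X <- cbind(1, dosage[, j], covar)
    if (qr(X)$rank < ncol(X)) next  # candidate collinear with selected leads
    fit <- tryCatch(ols_multi(X, y), error = function(e) NULL)
    if (is.null(fit)) next
    beta[j] <- fit$coef[2, 1]; se[j] <- fit$se[2, 1]; p[j] <- fit$p[2, 1]
  }
  data.frame(variant_id = colnames(dosage) %||% sprintf("v%d", seq_len(m)),
             beta = beta, se = se, p = p, stringsAsFactors = FALSE)
}

#' Study-wide significance threshold
#'
#' Bonferroni adjustment of a genome-wide threshold for the number of
#' proteins (or protein-coding genes) tested.
#'
#' @param alpha_gw genome-wide alpha (default 5e-8).
#' @param n_proteins number of proteins tested.
#' @return adjusted threshold.
#' @export
study_wide_threshold <- function(alpha_gw = 5e-8, n_proteins) {
  stopifnot(n_proteins >= 1)
  alpha_gw / n_proteins
}

#' Map primary pQTLs for every protein in a cohort
#'
#' Runs the association scan and greedy clumping per protein and attaches
#' cis/trans labels. The workhorse behind the pQTL discovery stage.
#'
#' @param dosage QC'd samples x variants dosage matrix.
#' @param variants variant table.
#' @param phenotypes samples x proteins matrix of standardized residuals.
#' @param gene_map protein-to-gene map with TSS.
#' @param p_max genome-wide threshold (default 5e-8).
#' @param r2_min,window_bp clumping parameters.
#' @return data.frame of primary pQTLs across proteins (adds protein_id).
#' @export
map_pqtls <- function(dosage, variants, phenotypes, gene_map,
                      p_max = 5e-8, r2_min = 0.2, window_bp = 1e6) {
  scans <- assoc_scan_multi(dosage, phenotypes)
  out <- list()
  for (prot in colnames(phenotypes)) {
    assoc <- data.frame(variant_id = rownames(scans$beta),
                        beta = scans$beta[, prot], se = scans$se[, prot],
                        p = scans$p[, prot], stringsAsFactors = FALSE)
    if (!any(assoc$p < p_max, na.rm = TRUE)) next
    cl <- clump(assoc, variants, dosage, r2_min = r2_min,
                window_bp = window_bp, p_max = p_max)
    if (nrow(cl) == 0) next
    cl$protein_id <- prot
    out[[prot]] <- cl
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(), variant_id = character(),
                      chrom = character(), pos = integer(), beta_lead = numeric(),
                      se_lead = numeric(), p_lead = numeric(), n_members = integer(),
                      members = character(), cis = logical(),
                      tss_distance = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- classify_cis_trans(res, gene_map, window_bp = window_bp)
  res[, c("protein_id", "variant_id", "chrom", "pos", "beta_lead", "se_lead",
          "p_lead", "n_members", "members", "cis", "tss_distance")]
}
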