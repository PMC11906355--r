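#' Decompose protein-level variance by sequential sums of squares
#'
#' Predictor blocks are added in a fixed order — independent pQTL dosages,
#' sex, age, obesity status, BMI-SDS, and the BMI-SDS x obesity interaction —
#' and each block's variance fraction is the increase in explained sum of
#' squares over the total sum of squares (type-I decomposition; the stated
#' order makes it well-defined). Tiny negative increments from floating-point
#' cancellation are clipped to zero.
#'
#' @param y protein phenotype vector (INT scale).
#' @param pqtl_dosage samples x leads matrix of conditionally independent
#'   lead dosages (NULL or 0 columns for none).
#' @param covariates data.frame with sex ("male"/"female" or 0/1), age,
#'   obesity, bmi_sds.
#' @return a `variance_decomposition`: list with `fractions` (named numeric:
#'   pqtl, sex, age, obesity, bmi_sds, bmi_sds_x_obesity), `total_r2`.
#' @export
decompose_variance <- function(y, pqtl_dosage, covariates) {
  if (stats::sd(y) == 0) stop("zero-variance protein")
  n <- length(y)
  sex_num <- if (is.character(covariates$sex)) {
    as.integer(covariates$sex == "female")
  } else as.numeric(covariates$sex)
  blocks <- list(
    pqtl = if (is.null(pqtl_dosage) || NCOL(pqtl_dosage) == 0) NULL else as.matrix(pqtl_dosage),
    sex = matrix(sex_num, ncol = 1),
    age = matrix(covariates$age, ncol = 1),
    obesity = matrix(covariates$obesity, ncol = 1),
    bmi_sds = matrix(covariates$bmi_sds, ncol = 1),
    bmi_sds_x_obesity = matrix(covariates$bmi_sds * covariates$obesity, ncol = 1))
  tss <- sum((y - mean(y))^2)
  X <- matrix(1, n, 1)
  rss <- tss
  fractions <- numeric(0)
  for (nm in names(blocks)) {
    if (is.null(blocks[[nm]])) { fractions[nm] <- 0; next }
    X <- cbind(X, blocks[[nm]])
    fit <- stats::lm.fit(X, y)
    rss_new <- sum(fit$residuals^2)
    inc <- (rss - rss_new) / tss
    if (inc < 0) {
      if (inc < -1e-8) log_msg("decompose_variance: clipping negative increment ", inc)
      inc <- 0
    }
    fractions[nm] <- inc
    rss <- rss_new
  }
  structure(list(fractions = fractions, total_r2 = 1 - rss / tss),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition (sequential sums of squares)\n")
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-18s %6.3f\n", nm, x$fractions[nm]))
  }
  cat(sprintf("  total R-squared    %6.3f\n", x$total_r2))
  invisible(x)
}

#' Stability of genetic variance fractions across age groups
#'
#' Splits the cohort into age strata, re-runs the variance decomposition per
#' stratum, and reports the Pearson correlation of per-protein pQTL variance
#' fractions between every pair of strata.
#'
#' @param phenotypes samples x proteins matrix.
#' @param pqtl_leads named list: per protein, a samples x leads dosage matrix
#'   (or NULL).
#' @param covariates covariate data.frame with an `age` column.
#' @param breaks age-group boundaries as a list of c(lo, hi) (inclusive).
#' @param min_n minimum samples per group.
#' @return list with `fractions` (proteins x groups matrix of pQTL variance
#'   fractions) and `correlations` (data.frame group_a, group_b, r).
#' @export
age_group_stability <- function(phenotypes, pqtl_leads, covariates,
                                breaks = list(c(5, 9), c(10, 14), c(15, 20)),
                                min_n = 50L) {
  groups <- lapply(breaks, function(b) {
    which(covariates$age >= b[1] & covariates$age <= b[2])
  })
  names(groups) <- vapply(breaks, function(b) sprintf("%g-%g", b[1], b[2]), character(1))
  empty <- names(groups)[vapply(groups, length, integer(1)) < min_n]
  if (length(empty) > 0) stop("age groups below minimum size: ", paste(empty, collapse = ", "))
  prots <- colnames(phenotypes)
  fr <- matrix(NA_real_, length(prots), length(groups),
               dimnames = list(prots, names(groups)))
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (prot in prots) {
      leads <- pqtl_leads[[prot]]
      dec <- decompose_variance(phenotypes[idx, prot],
                                if (is.null(leads)) NULL else leads[idx, , drop = FALSE],
                                covariates[idx, , drop = FALSE])
      fr[prot, g] <- dec$fractions["pqtl"]
    }
  }
  pairs <- utils::combn(names(groups), 2)
  cors <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     r = apply(pairs, 2, function(pr) stats::cor(fr[, pr[1]], fr[, pr[2]])),
                     stringsAsFactors = FALSE)
  list(fractions = fr, correlations = cors)
}

#' Allelic fold change of a pQTL on the untransformed scale
#'
#' Ratio of mean linear-scale protein abundance in heterozygotes (dosage 1)
#' and homozygous-alternate carriers (dosage 2) relative to homozygous
#' reference (dosage 0), computed without any data transformation.
#'
#' @param abundance linear-scale (untransformed) protein abundance vector;
#'   all values must be positive. NA (missing measurements) are dropped.
#' @param dosage dosage vector in {0,1,2}.
#' @return list with group_means (length 3), afc_het, afc_hom, log2_fc_hom;
#'   empty genotype groups yield NA ratios with a `missing_groups` flag.
#' @export
allelic_fold_change <- function(abundance, dosage) {
  ok <- !is.na(abundance) & !is.na(dosage)
  abundance <- abundance[ok]; dosage <- dosage[ok]
  if (any(abundance < 0)) stop("abundances must be non-negative (linear scale)")
  m <- vapply(0:2, function(d) {
    if (!any(dosage == d)) NA_real_ else mean(abundance[dosage == d])
  }, numeric(1))
  names(m) <- c("hom_ref", "het", "hom_alt")
  afc_het <- m["het"] / m["hom_ref"]
  afc_hom <- m["hom_alt"] / m["hom_ref"]
  list(group_means = m,
       afc_het = unname(afc_het), afc_hom = unname(afc_hom),
       log2_fc_hom = unname(log2(afc_hom)),
       missing_groups = names(m)[is.na(m)])
}
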