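#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against expectations at the sample allele frequency.
#'
#' @param n0,n1,n2 counts of homozygous-reference, heterozygous and
#'   homozygous-alternate genotypes.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) stop("no genotype observations")
  q <- (n1 + 2 * n2) / (2 * n)  # alternate allele frequency
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  o <- c(n0, n1, n2)
  nz <- e > 0
  chisq <- sum((o[nz] - e[nz])^2 / e[nz])
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Applies, in order: variant call-rate, minor allele frequency,
#' Hardy-Weinberg equilibrium, sample call-rate, and sample heterozygosity
#' (mean +/- `het_sd` SD) filters. Variants with MAF below `maf_min` are
#' removed (a variant at exactly the threshold is retained).
#'
#' @param dosage samples x variants matrix in {0,1,2}, NA = missing.
#' @param variants optional variant table aligned with columns.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @param var_call minimum variant call rate (default 0.95).
#' @param sample_call minimum sample call rate (default 0.95).
#' @param het_sd heterozygosity-rate SD window (default 3).
#' @return list with filtered `dosage`, filtered `variants` (if given) and a
#'   `report` of counts dropped per filter.
#' @export
qc_genotypes <- function(dosage, variants = NULL, maf_min = 0.05,
                         hwe_p_min = 1e-6, var_call = 0.95,
                         sample_call = 0.95, het_sd = 3) {
  stopifnot(is.matrix(dosage))
  report <- list(thresholds = list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                                   var_call = var_call, sample_call = sample_call,
                                   het_sd = het_sd))

  call_rate_v <- colMeans(!is.na(dosage))
  keep <- call_rate_v >= var_call
  report$variants_dropped_callrate <- sum(!keep)
  dosage <- dosage[, keep, drop = FALSE]
  if (!is.null(variants)) variants <- variants[keep, , drop = FALSE]

  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min
  report$variants_dropped_maf <- sum(!keep)
  dosage <- dosage[, keep, drop = FALSE]
  if (!is.null(variants)) variants <- variants[keep, , drop = FALSE]

  hwe_p <- apply(dosage, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))$p
  })
  keep <- hwe_p >= hwe_p_min
  report$variants_dropped_hwe <- sum(!keep)
  dosage <- dosage[, keep, drop = FALSE]
  if (!is.null(variants)) variants <- variants[keep, , drop = FALSE]
  if (ncol(dosage) == 0L) stop("all variants removed by QC")

  call_rate_s <- rowMeans(!is.na(dosage))
  keep_s <- call_rate_s >= sample_call
  report$samples_dropped_callrate <- sum(!keep_s)
  dosage <- dosage[keep_s, , drop = FALSE]

  het <- rowMeans(dosage == 1L, na.rm = TRUE)
  mu <- mean(het); sdv <- stats::sd(het)
  keep_s <- if (is.na(sdv) || sdv == 0) rep(TRUE, nrow(dosage)) else abs(het - mu) <= het_sd * sdv
  report$samples_dropped_heterozygosity <- sum(!keep_s)
  dosage <- dosage[keep_s, , drop = FALSE]

  list(dosage = dosage, variants = variants, report = report)
}

#' Per-variant association scan of one phenotype
#'
#' For every variant, OLS of the phenotype on alternate-allele dosage plus an
#' intercept; two-sided t-test p-values on n - 2 degrees of freedom.
#' Vectorized across variants; variants that are monomorphic in-sample are
#' skipped (NA results). Missing dosages are handled per variant
#' (pairwise-complete).
#'
#' @param dosage samples x variants matrix.
#' @param y phenotype vector (standardized residuals; no missing values).
#' @return data.frame with variant_id, beta, se, t, p, n, maf.
#' @export
assoc_scan <- function(dosage, y) {
  stopifnot(is.matrix(dosage), length(y) == nrow(dosage))
  if (anyNA(y)) stop("phenotype contains missing values; residualize first")
  if (stats::sd(y) == 0) stop("constant phenotype")
  W <- !is.na(dosage)
  G0 <- dosage; G0[!W] <- 0
  storage.mode(G0) <- "double"
  nj <- colSums(W)
  Sx <- colSums(G0)
  Sy <- as.vector(crossprod(W, y))
  Sxy <- as.vector(crossprod(G0, y))
  Sxx <- colSums(G0^2)
  Syy <- as.vector(crossprod(W, y^2))
  Sxx_c <- Sxx - Sx^2 / nj
  Syy_c <- Syy - Sy^2 / nj
  Sxy_c <- Sxy - Sx * Sy / nj
  beta <- Sxy_c / Sxx_c
  sse <- pmax(Syy_c - beta * Sxy_c, 0)
  df <- nj - 2
  se <- sqrt(sse / df / Sxx_c)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)  # underflow guard for perfect fits
  mono <- Sxx_c <= .Machine$double.eps * nj
  beta[mono] <- se[mono] <- p[mono] <- NA_real_
  af <- Sx / (2 * nj)
  data.frame(variant_id = colnames(dosage) %||% sprintf("v%d", seq_len(ncol(dosage))),
             beta = beta, se = se, t = tval, p = p, n = nj,
             maf = pmin(af, 1 - af), stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association scan of many phenotypes against many variants
#'
#' Simple-regression beta/SE/p for every (variant, phenotype) pair at once;
#' used for peptide-level scans and calibration studies. Requires a complete
#' dosage matrix (run QC/imputation first).
#'
#' @param dosage samples x variants complete matrix.
#' @param Y samples x phenotypes complete matrix.
#' @return list of m x k matrices `beta`, `se`, `p`.
#' @export
assoc_scan_multi <- function(dosage, Y) {
  stopifnot(is.matrix(dosage), is.matrix(Y), nrow(dosage) == nrow(Y))
  if (anyNA(dosage) || anyNA(Y)) stop("assoc_scan_multi requires complete matrices")
  n <- nrow(dosage)
  Gc <- scale(dosage, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- colSums(Gc^2)
  Syy <- colSums(Yc^2)
  Sxy <- crossprod(Gc, Yc)            # m x k
  beta <- Sxy / Sxx
  sse <- outer(rep(1, length(Sxx)), Syy) - beta * Sxy
  sse[sse < 0] <- 0
  se <- sqrt(sse / (n - 2) / Sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[] <- pmax(p, .Machine$double.xmin)
  dimnames(beta) <- dimnames(se) <- dimnames(p) <- list(colnames(dosage), colnames(Y))
  list(beta = beta, se = se, p = p)
}

#' Genomic-control inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median by
#' the 1-df chi-square median (about 0.4549). 1.0 indicates a well-calibrated
#' scan.
#'
#' @param p vector of p-values.
#' @return lambda_GC scalar.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
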