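#' Filter features on data completeness
#'
#' Keeps features (columns) quantified in at least `min_valid_fraction` of
#' samples; the boundary is inclusive, so with 10 samples a feature with 6
#' valid values is retained. Column order is preserved.
#'
#' @param mat samples x features numeric matrix, NA = missing.
#' @param min_valid_fraction minimum fraction of valid values, in (0, 1].
#' @return the filtered matrix with attribute `dropped` listing removed
#'   feature names.
#' @export
filter_completeness <- function(mat, min_valid_fraction = 0.6) {
  stopifnot(is.matrix(mat))
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop("min_valid_fraction must lie in (0, 1]")
  }
  frac <- colMeans(!is.na(mat))
  keep <- frac >= min_valid_fraction
  if (!any(keep)) warning("no features pass the completeness filter")
  out <- mat[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(mat)[!keep]
  out
}

#' Impute missing log2 intensities from a downshifted normal distribution
#'
#' Left-censored imputation for intensity data: for each sample (row), the
#' observed mean and SD across features define a Normal with mean shifted
#' down by `shift` SDs and SD scaled by `width`, from which that sample's
#' missing values are drawn. Models the fact that missing measurements tend
#' to sit below the detection limit.
#'
#' @param mat samples x features log2 matrix.
#' @param shift downshift in sample SD units (default 1.8).
#' @param width SD scale factor (default 0.3).
#' @param seed integer seed; imputation is reproducible.
#' @return matrix with no missing values.
#' @export
impute_downshifted <- function(mat, shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(is.matrix(mat))
  set.seed(seed)
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs < 2L)) {
    stop("samples with fewer than 2 observed values (SD undefined): ",
         paste(utils::head(rownames(mat)[n_obs < 2L]), collapse = ", "))
  }
  mu <- rowMeans(mat, na.rm = TRUE)
  sd_s <- apply(mat, 1, stats::sd, na.rm = TRUE)
  miss <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    rows <- miss[, 1]
    mat[miss] <- stats::rnorm(nrow(miss),
                              mean = mu[rows] - shift * sd_s[rows],
                              sd = width * sd_s[rows])
  }
  mat
}

#' Rank-based inverse normal transformation with Blom offset
#'
#' Maps each non-missing value through Phi^-1((r - c) / (N - 2c + 1)) where r
#' is its rank among the N non-missing values and c is the Blom offset
#' (default 3/8). Ties receive average ranks before transformation, making
#' the result deterministic. Missing values stay missing and do not count
#' toward N.
#'
#' @param x numeric vector.
#' @param c Blom offset (default 3/8).
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x, c = 3/8) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n == 0L) stop("all values missing: nothing to transform")
  r <- rank(x[obs], ties.method = "average")
  out <- x
  out[obs] <- stats::qnorm((r - c) / (n - 2 * c + 1))
  out
}

#' Apply the inverse normal transformation to every column of a matrix
#'
#' @param mat samples x features matrix.
#' @param c Blom offset.
#' @return matrix of the same shape.
#' @export
int_matrix <- function(mat, c = 3/8) {
  apply(mat, 2, inverse_normal_transform, c = c)
}

#' Residualize protein levels on covariates, with optional re-standardization
#'
#' Per protein: fit OLS of the (already INT-transformed) level on the
#' covariate design and keep the residuals; optionally re-apply the inverse
#' normal transformation to the residuals so the association phenotype is
#' standard normal. Samples with missing covariates are dropped with a logged
#' count.
#'
#' @param mat samples x proteins matrix (no missing values; impute first).
#' @param covariates data.frame aligned with rows of `mat`; all columns used.
#' @param re_int logical, re-apply INT to the residuals (default TRUE).
#' @return samples x proteins residual matrix (rows with missing covariates
#'   are removed).
#' @export
residualize <- function(mat, covariates, re_int = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(covariates))
  cc <- stats::complete.cases(covariates)
  if (!all(cc)) {
    log_msg("residualize: dropping ", sum(!cc), " samples with missing covariates")
    mat <- mat[cc, , drop = FALSE]
    covariates <- covariates[cc, , drop = FALSE]
  }
  X <- stats::model.matrix(~ ., data = covariates)
  fit <- ols_multi(X, mat)
  res <- fit$residuals
  dimnames(res) <- dimnames(mat)
  if (re_int) res <- int_matrix(res)
  res
}

#' Build the standard association phenotype from a cohort bundle
#'
#' Applies the full preprocessing contract used before genetic association:
#' completeness filter, downshifted-normal imputation, inverse normal
#' transformation, residualization on age, sex, BMI-SDS, obesity,
#' obesity x BMI-SDS, puberty, storage time and PC1, and re-INT of the
#' residuals. Works for the protein or the peptide matrix.
#'
#' @param bundle a `cohort_bundle`.
#' @param kind "protein" or "peptide".
#' @param min_valid_fraction completeness threshold.
#' @param seed seed for imputation (defaults to a substream of the bundle's
#'   configuration seed).
#' @return samples x features matrix of standardized association phenotypes.
#' @export
prepare_phenotypes <- function(bundle, kind = c("protein", "peptide"),
                               min_valid_fraction = 0.6, seed = NULL) {
  kind <- match.arg(kind)
  mat <- bundle[[kind]]
  if (is.null(seed)) seed <- substream_seed(bundle$config$seed, paste0("impute-", kind))
  mat <- filter_completeness(mat, min_valid_fraction)
  mat <- impute_downshifted(mat, seed = seed)
  mat <- int_matrix(mat)
  cov <- bundle$covariates
  design <- data.frame(age = cov$age,
                       sex = as.integer(cov$sex == "female"),
                       bmi_sds = cov$bmi_sds,
                       obesity = cov$obesity,
                       obesity_bmi = cov$obesity * cov$bmi_sds,
                       puberty = cov$puberty,
                       storage = cov$storage,
                       pc1 = cov$pc1)
  residualize(mat, design, re_int = TRUE)
}
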