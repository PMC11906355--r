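#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin validated wrapper around the standard step-up procedure
#' (`p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in [0, 1]; NA allowed.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Associate protein levels with age, sex, BMI-SDS and obesity
#'
#' Fits, per protein, an OLS model of the INT-transformed level on age, sex
#' (female = 1), BMI-SDS, obesity status (clinic group = 1), the
#' obesity x BMI-SDS interaction, pubertal status, plasma storage time and
#' PC1; optionally also age x BMI-SDS, sex x BMI-SDS and age x sex
#' interactions. P-values are two-sided t-tests; the BH adjustment is applied
#' per term across proteins.
#'
#' @param protein_int samples x proteins matrix, already INT-transformed and
#'   imputed.
#' @param covariates covariate data.frame with columns age, sex
#'   ("male"/"female"), bmi_sds, obesity, puberty, storage, pc1. Samples with
#'   missing covariates are excluded (complete-case analysis).
#' @param extra_interactions also fit age x BMI-SDS, sex x BMI-SDS and
#'   age x sex terms.
#' @return data.frame with protein_id, term, beta, se, p, p_adj, n.
#' @export
fit_pheno_model <- function(protein_int, covariates, extra_interactions = FALSE) {
  stopifnot(is.matrix(protein_int), nrow(protein_int) == nrow(covariates))
  cc <- stats::complete.cases(covariates)
  if (!all(cc)) {
    log_msg("fit_pheno_model: excluding ", sum(!cc), " samples with missing covariates")
    protein_int <- protein_int[cc, , drop = FALSE]
    covariates <- covariates[cc, , drop = FALSE]
  }
  sex_num <- as.integer(covariates$sex == "female")
  X <- cbind(`(Intercept)` = 1,
             age = covariates$age,
             sex = sex_num,
             `BMI-SDS` = covariates$bmi_sds,
             obesity = covariates$obesity,
             `obesity:BMI-SDS` = covariates$obesity * covariates$bmi_sds,
             puberty = covariates$puberty,
             storage = covariates$storage,
             pc1 = covariates$pc1)
  if (extra_interactions) {
    X <- cbind(X,
               `age:BMI-SDS` = covariates$age * covariates$bmi_sds,
               `sex:BMI-SDS` = sex_num * covariates$bmi_sds,
               `age:sex` = covariates$age * sex_num)
  }
  fit <- ols_multi(X, protein_int)
  terms <- setdiff(colnames(X), "(Intercept)")
  n <- nrow(X)
  out <- do.call(rbind, lapply(terms, function(tm) {
    data.frame(protein_id = colnames(protein_int), term = tm,
               beta = fit$coef[tm, ], se = fit$se[tm, ], p = fit$p[tm, ],
               n = n, stringsAsFactors = FALSE, row.names = NULL)
  }))
  # BH family: all proteins tested for one term
  out$p_adj <- stats::ave(out$p, out$term, FUN = bh_adjust)
  out[order(out$term, out$p), c("protein_id", "term", "beta", "se", "p", "p_adj", "n")]
}

#' Variance inflation factors for an association design
#'
#' VIF_j = 1 / (1 - R^2) of predictor j regressed on all other predictors.
#' Predictors that are exact linear combinations of the others are flagged
#' with infinite VIF.
#'
#' @param covariates data.frame or numeric matrix of predictors (no
#'   intercept column).
#' @return data.frame with predictor and vif.
#' @export
vif_table <- function(covariates) {
  X <- as.matrix(covariates)
  stopifnot(ncol(X) >= 2L)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(X), vif = vif, stringsAsFactors = FALSE)
}

#' Model diagnostics: multicollinearity and residual normality
#'
#' Computes the VIF of every predictor in the standard association design
#' and, per protein, a Shapiro-Wilk test on the OLS residuals (subsampled to
#' 5000 observations when larger, the test's limit).
#'
#' @param protein_int samples x proteins INT matrix.
#' @param covariates covariate data.frame as in [fit_pheno_model()].
#' @param seed seed for residual subsampling at large n.
#' @return list with `vif` (data.frame) and `normality` (protein_id, p,
#'   normal at 0.05), plus `fraction_normal`.
#' @export
pheno_diagnostics <- function(protein_int, covariates, seed = 1L) {
  cc <- stats::complete.cases(covariates)
  protein_int <- protein_int[cc, , drop = FALSE]
  covariates <- covariates[cc, , drop = FALSE]
  sex_num <- as.integer(covariates$sex == "female")
  pred <- cbind(age = covariates$age, sex = sex_num,
                `BMI-SDS` = covariates$bmi_sds, obesity = covariates$obesity,
                puberty = covariates$puberty, storage = covariates$storage,
                pc1 = covariates$pc1)
  vif <- vif_table(pred)
  X <- cbind(1, pred, `obesity:BMI-SDS` = covariates$obesity * covariates$bmi_sds)
  fit <- ols_multi(X, protein_int)
  set.seed(seed)
  idx <- if (nrow(protein_int) > 5000L) sample(nrow(protein_int), 5000L) else seq_len(nrow(protein_int))
  norm_p <- apply(fit$residuals[idx, , drop = FALSE], 2,
                  function(r) stats::shapiro.test(r)$p.value)
  normality <- data.frame(protein_id = colnames(protein_int), p = norm_p,
                          normal = norm_p > 0.05, stringsAsFactors = FALSE,
                          row.names = NULL)
  list(vif = vif, normality = normality,
       fraction_normal = mean(normality$normal))
}
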