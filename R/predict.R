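#' Predict age or BMI from plasma protein levels
#'
#' Implements a correlation-ranked incremental feature-selection protocol:
#' an outer train/test split, an inner train/validation split of the training
#' set, feature ranking by absolute Pearson correlation with the outcome on
#' the inner training set only, OLS models with the top k features for
#' k = 1..k_max evaluated on the validation set, selection of the smallest k
#' whose validation MSE is within `mse_tol` of the curve minimum, refit on
#' the full training set, and evaluation on the held-out test set.
#'
#' Neither ranking nor model selection ever sees a test sample.
#'
#' @param X samples x proteins predictor matrix (complete).
#' @param outcome numeric outcome vector (age in years, or raw BMI).
#' @param k_max maximum number of features considered (default 200; capped
#'   at the number of available features with a warning).
#' @param split outer train fraction (default 0.7).
#' @param inner_split inner train fraction of the training set (default 0.7).
#' @param mse_tol relative tolerance for the parsimonious-k rule (default
#'   0.01: smallest k within 1% of the minimum validation MSE).
#' @param seed integer seed controlling both splits.
#' @return a `prediction_report`: list with selected_features (ordered),
#'   k_selected, mse_curve (data.frame k, mse), test_mae, test_r, n_test.
#' @export
train_predictor <- function(X, outcome, k_max = 200L, split = 0.7,
                            inner_split = 0.7, mse_tol = 0.01, seed = 1L) {
  stopifnot(is.matrix(X), length(outcome) == nrow(X), !anyNA(outcome))
  if (k_max > ncol(X)) {
    warning("k_max exceeds available features; capping at ", ncol(X))
    k_max <- ncol(X)
  }
  set.seed(seed)
  n <- nrow(X)
  idx_train <- sort(sample(n, round(split * n)))
  idx_test <- setdiff(seq_len(n), idx_train)
  inner <- sort(sample(idx_train, round(inner_split * length(idx_train))))
  valid <- setdiff(idx_train, inner)

  # rank features on the inner training set only
  cors <- abs(suppressWarnings(stats::cor(X[inner, , drop = FALSE], outcome[inner])))
  cors[is.na(cors)] <- 0
  ranking <- order(cors, decreasing = TRUE)

  mse <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    feats <- ranking[seq_len(k)]
    fit <- stats::lm.fit(cbind(1, X[inner, feats, drop = FALSE]), outcome[inner])
    pred <- cbind(1, X[valid, feats, drop = FALSE]) %*% fit$coefficients
    mse[k] <- mean((outcome[valid] - pred)^2)
  }
  k_sel <- min(which(mse <= min(mse) * (1 + mse_tol)))

  feats <- ranking[seq_len(k_sel)]
  fit <- stats::lm.fit(cbind(1, X[idx_train, feats, drop = FALSE]), outcome[idx_train])
  pred_test <- cbind(1, X[idx_test, feats, drop = FALSE]) %*% fit$coefficients
  structure(list(
    selected_features = colnames(X)[feats],
    k_selected = k_sel,
    mse_curve = data.frame(k = seq_len(k_max), mse = mse),
    test_mae = mean(abs(outcome[idx_test] - pred_test)),
    test_r = stats::cor(outcome[idx_test], as.vector(pred_test)),
    n_test = length(idx_test)),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Protein-based prediction report\n")
  cat(sprintf("  features selected: %d (of %d considered)\n",
              x$k_selected, nrow(x$mse_curve)))
  cat(sprintf("  held-out MAE: %.3f  Pearson r: %.3f  (n_test = %d)\n",
              x$test_mae, x$test_r, x$n_test))
  invisible(x)
}
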