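#' @keywords internal
"_PACKAGE"

#' Multi-response ordinary least squares with coefficient tests
#'
#' Fits `Y ~ X` for every column of `Y` at once with a shared design matrix,
#' returning coefficients, standard errors and two-sided t-test p-values.
#' This is the numerical workhorse behind phenotype association, association
#' scans and residualization; it exists so thousands of per-protein fits stay
#' a single QR decomposition plus matrix products.
#'
#' @param X design matrix (n x p), including an intercept column if wanted.
#' @param Y response matrix (n x k) or vector; no missing values allowed.
#' @return list with `coef`, `se`, `p` (p x k matrices), `residuals` (n x k),
#'   `df` residual degrees of freedom, and `rank`.
#' @keywords internal
ols_multi <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  coef <- qr.coef(qr_x, Y)
  fitted <- X %*% coef
  res <- Y - fitted
  df <- nrow(X) - qr_x$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x)[, order(qr_x$pivot), drop = FALSE])
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tval <- coef / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  dimnames(se) <- dimnames(p) <- dimnames(coef)
  list(coef = coef, se = se, p = p, residuals = res, df = df, rank = qr_x$rank)
}

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness flows from one root seed; each stage draws from its own
#' substream so stages can be rerun in isolation without perturbing others.
#'
#' @param root_seed integer root seed.
#' @param stream stage name, e.g. "genotypes".
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stream))
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(root_seed) * 48271 + h) %% 2147483647)
}

#' Short deterministic hash of a configuration object
#'
#' Used to stamp output files so every artifact records the configuration
#' that produced it.
#'
#' @param x any serializable R object.
#' @return an 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261 %% 2147483647
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Timestamped log line to stderr
#' @param ... message parts passed to `paste0`.
#' @keywords internal
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), paste0(...))
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
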