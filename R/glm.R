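#' Ordinary least squares fit of a design to a time series
#'
#' Fits `y = X beta + e` by QR decomposition with a column-rank check and
#' returns the quantities model comparison needs: betas, residuals, residual
#' sum of squares, log residual variance `ln(rss/n)`, and the information
#' criteria
#' \deqn{AIC = n \ln(rss/n) + 2k, \quad BIC = n \ln(rss/n) + k \ln n,}
#' where `k` counts all design columns including the intercept. For models
#' of equal complexity (equal `k`, equal `n`) ranking by AIC, BIC or log
#' residual variance is therefore the same ranking.
#'
#' No degrees-of-freedom correction is applied in `log_res_var`, matching
#' the AIC/BIC forms above.
#'
#' @param y numeric response vector (e.g. one region's BOLD series).
#' @param X a [design_matrix()] or plain numeric matrix (with columns
#'   already including any intercept).
#' @return object of class `glm_fit`: list with `betas` (named), `residuals`,
#'   `fitted`, `rss`, `tss`, `n`, `k`, `log_res_var`, `aic`, `bic`,
#'   `r_squared`.
#' @export
fit_glm <- function(y, X) {
  if (inherits(X, "design_matrix")) X <- as.matrix(X)
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n)
    stop("length(y) must equal nrow(X)", call. = FALSE)
  k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))

  qx <- qr(X, tol = 1e-10)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qx, y)
  fitted <- drop(X %*% betas)
  res <- y - fitted
  rss <- sum(res^2)
  has_intercept <- any(apply(X, 2, function(col) all(col == col[1] & col[1] != 0)))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  log_res_var <- log(rss / n)
  structure(
    list(betas = betas, residuals = res, fitted = fitted, rss = rss,
         tss = tss, n = n, k = k, log_res_var = log_res_var,
         aic = n * log_res_var + 2 * k, bic = n * log_res_var + k * log(n),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_),
    class = "glm_fit"
  )
}

# A fit whose residual sum of squares is numerically zero relative to the
# total variation; log residual variance and AIC/BIC are then undefined
# in any meaningful sense (noise-free / overfitted input).
rss_degenerate <- function(fit) {
  fit$rss <= 1e-12 * max(fit$tss, .Machine$double.eps)
}

#' Information criteria of a fitted GLM
#'
#' Recomputes AIC and BIC from a [fit_glm()] result. Both are linear
#' functions of the log residual variance for fixed `n` and `k`, which is
#' why comparing equal-complexity reduced GLMs by log residual variance is
#' equivalent to comparing them by AIC or BIC.
#'
#' @param fit a `glm_fit`.
#' @return named numeric vector `c(aic = , bic = )`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  if (rss_degenerate(fit))
    stop("residual sum of squares is (numerically) zero: information ",
         "criteria are undefined; input is noise-free or overfitted",
         call. = FALSE)
  lrv <- log(fit$rss / fit$n)
  c(aic = fit$n * lrv + 2 * fit$k, bic = fit$n * lrv + fit$k * log(fit$n))
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> n =", x$n, ", k =", x$k,
      sprintf(", R^2 = %.4f, log residual variance = %.4f\n",
              x$r_squared, x$log_res_var))
  print(round(x$betas, 4))
  invisible(x)
}
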