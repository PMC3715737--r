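# Shared fixtures and small independent oracles.

# The worked reward sequence and its exact RW prediction errors (alpha 0.5,
# V1 = 0), derived by hand from the recurrence.
REWARDS7 <- c(1, 0, 0, 1, 1, 1, 0)
DELTAS7_EXACT <- c(1, -0.5, -0.25, 0.875, 0.4375, 0.21875, -0.890625)
DELTAS7_PRINTED <- c(1, -0.5, -0.25, 0.87, 0.43, 0.21, -0.89)

# A pair of smooth, z-scored random regressors with tunable correlation.
random_regressor_pair <- function(n = 200, rho = 0.7, seed = 1) {
  set.seed(seed)
  base <- stats::filter(rnorm(n + 20), rep(1, 8), sides = 1)[-(1:20)]
  indep <- stats::filter(rnorm(n + 20), rep(1, 8), sides = 1)[-(1:20)]
  a <- zscore(as.numeric(base))
  b <- zscore(rho * a + sqrt(1 - rho^2) * zscore(as.numeric(indep)))
  list(A = new_test_regressor("A", a), B = new_test_regressor("B", b))
}

new_test_regressor <- function(name, samples, dt = 1) {
  r <- structure(list(name = name, samples = samples, dt = dt,
                      standardized = FALSE,
                      orthogonalized_against = character(0)),
                 class = "regressor")
  if (abs(mean(samples)) < 1e-8 &&
      abs(sqrt(mean((samples - mean(samples))^2)) - 1) < 1e-8)
    r$standardized <- TRUE
  r
}

# Independent OLS oracle: Moore-Penrose pseudo-inverse via SVD.
pinv_betas <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  drop(s$v[, keep, drop = FALSE] %*%
         ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep]))
}

# Independent OLS oracle: normal equations.
normal_eq_betas <- function(X, y)
  unname(drop(solve(crossprod(X), crossprod(X, y))))

# Elementwise absolute-tolerance check (display rounding / truncation).
expect_abs_within <- function(actual, expected, tol) {
  expect_lte(max(abs(actual - expected)), tol + 1e-12)
}

# Hat (projection) matrix of a design.
hat_matrix <- function(X) X %*% solve(crossprod(X)) %*% t(X)
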