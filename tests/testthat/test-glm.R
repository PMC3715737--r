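test_that("exact span gives zero residuals and R^2 = 1", {
  p <- random_regressor_pair(n = 120, rho = 0.5, seed = 9)
  d <- build_designs(p$A, p$B)
  y <- 2 + 0.8 * p$A$samples + 0.2 * p$B$samples
  fit <- fit_glm(y, d$full1)
  expect_lt(fit$rss, 1e-16 * fit$n * sum(y^2))
  expect_equal(fit$r_squared, 1)
})

test_that("zero-noise mixtures recover the generating weights", {
  p <- random_regressor_pair(n = 200, rho = 0.7, seed = 4)
  y <- 0.8 * p$A$samples + 0.2 * p$B$samples
  X <- cbind(`(Intercept)` = 1, A = p$A$samples, B = p$B$samples)
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$betas), c(0, 0.8, 0.2), tolerance = 1e-10)
  # independent oracle: normal equations
  expect_equal(unname(fit$betas), normal_eq_betas(X, y), tolerance = 1e-10)
})

test_that("betas match an independent pseudo-inverse on random problems", {
  set.seed(100)
  for (i in 1:10) {
    n <- sample(40:150, 1)
    k <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    y <- rnorm(n)
    fit <- fit_glm(y, X)
    expect_equal(unname(fit$betas), pinv_betas(X, y), tolerance = 1e-8)
    # residuals orthogonal to every design column
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-6)
    expect_equal(fit$rss, sum(fit$residuals^2))
  }
})

test_that("information criteria follow their defining identities", {
  # hand-computed case: k = 2, n = 100, rss = 100 -> aic = 4
  fit <- structure(list(rss = 100, tss = 500, n = 100L, k = 2L),
                   class = "glm_fit")
  ic <- information_criteria(fit)
  expect_equal(unname(ic["aic"]), 4)
  expect_equal(unname(ic["bic"] - ic["aic"]), 2 * (log(100) - 2))

  # equal complexity: AIC order is the log-residual-variance order
  set.seed(21)
  for (i in 1:20) {
    n <- 80L
    x1 <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n)
    f1 <- fit_glm(y, cbind(1, x1))
    f2 <- fit_glm(y, cbind(1, x2))
    expect_equal(sign(f1$aic - f2$aic),
                 sign(f1$log_res_var - f2$log_res_var))
    expect_equal(f1$bic - f1$aic, f1$k * (log(n) - 2))
  }

  # noise-free fit: criteria undefined
  p <- random_regressor_pair(n = 100, seed = 2)
  f0 <- fit_glm(p$A$samples, cbind(1, p$A$samples))
  expect_error(information_criteria(f0), "zero")
})

test_that("full models never fit worse than reduced models", {
  set.seed(31)
  for (i in 1:15) {
    p <- random_regressor_pair(n = 150, rho = runif(1, -0.8, 0.8),
                               seed = 1000 + i)
    d <- build_designs(p$A, p$B)
    y <- rnorm(150)
    rss_full <- fit_glm(y, d$full1)$rss
    expect_lte(rss_full, fit_glm(y, d$reduced_A)$rss + 1e-10)
    expect_lte(rss_full, fit_glm(y, d$reduced_B)$rss + 1e-10)
  }
})

test_that("orthogonalized-last beta equals its beta in the plain full model", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_regressor_pair(n = 120, rho = runif(1, -0.7, 0.7),
                               seed = 2000 + i)
    y <- rnorm(120)
    d <- build_designs(p$A, p$B)
    fit_ortho <- fit_glm(y, d$full1)            # [1, A, B.orth]
    fit_plain <- fit_glm(y, cbind(`(Intercept)` = 1, A = p$A$samples,
                                  B = p$B$samples))
    expect_equal(unname(fit_ortho$betas["B.orth"]),
                 unname(fit_plain$betas["B"]), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  set.seed(5)
  x <- rnorm(50)
  X <- cbind(`(Intercept)` = 1, a = x, b = 2 * x)
  expect_error(fit_glm(rnorm(50), X), "collinear.*\\bb\\b")
  expect_error(fit_glm(rnorm(10), X), "length\\(y\\)")
})
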