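test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)               # gamma density with shape > 1 at 0
  expect_equal(max(h), 1)             # unit-peak scaling
  peak_t <- (which.max(h) - 1) * 0.1
  expect_gte(peak_t, 4.5)
  expect_lte(peak_t, 5.5)
  expect_lt(min(h), 0)                # undershoot present
  expect_error(canonical_hrf(0), "\\(0, 2\\]")
  expect_error(canonical_hrf(-1), "\\(0, 2\\]")
})

test_that("a single unit impulse reproduces the shifted HRF", {
  dt <- 0.1
  h <- canonical_hrf(dt)
  ev <- event_spec(10, durations = 0, modulations = 1, label = "imp")
  reg <- build_regressor(ev, total_duration = 60, dt = dt,
                         center_modulations = FALSE)
  shift <- round(10 / dt)
  got <- reg$samples[(shift + 1):(shift + length(h))]
  expect_equal(got, h, tolerance = 1e-10)
  expect_true(all(abs(reg$samples[seq_len(shift)]) < 1e-12))
})

test_that("degenerate modulations and bad events are handled", {
  ev0 <- event_spec(c(5, 20), modulations = c(0, 0))
  reg0 <- build_regressor(ev0, 60, dt = 1, center_modulations = FALSE)
  expect_true(all(reg0$samples == 0))
  expect_error(build_regressor(event_spec(100), 60), "beyond")
  expect_error(event_spec(c(10, 5)), "strictly increasing")
  expect_error(event_spec(10, durations = -1), "non-negative")
})

test_that("fixture regressors correlate at 0.89 before orthogonalization", {
  ds <- two_region_fixture(seed = 1)
  r <- cor(ds$regressors$RO$samples, ds$regressors$RPE$samples)
  expect_equal(round(r, 2), 0.89)
  # well-separated events: time-series correlation tracks the correlation
  # of the modulation vectors (independent oracle on the 7-element vectors)
  r_mod <- cor(REWARDS7, DELTAS7_EXACT)
  expect_lt(abs(r - r_mod), 0.01)
})

test_that("zscore uses the population convention and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(round(z, 4), c(-1.2247, 0, 1.2247))
  set.seed(3)
  x <- rnorm(100)
  expect_equal(zscore(zscore(x)), zscore(x))
  expect_equal(zscore(2.5 * x - 7), zscore(x))       # affine invariance
  expect_error(zscore(rep(4, 10)), "constant")
  ds <- two_region_fixture(seed = 1)
  expect_true(ds$regressors$RO$standardized)
  expect_lt(abs(mean(ds$regressors$RO$samples)), 1e-10)
  expect_lt(abs(sqrt(mean(ds$regressors$RO$samples^2)) - 1), 1e-10)
})

test_that("orthogonalization removes correlation with the base", {
  ds <- two_region_fixture(seed = 1)
  ro <- ds$regressors$RO
  rpe <- ds$regressors$RPE
  rpe_o <- orthogonalize(rpe, ro)
  expect_lt(abs(cor(rpe_o$samples, ro$samples)), 1e-8)
  expect_lt(abs(sum(rpe_o$samples *
                      (ro$samples - mean(ro$samples)))), 1e-8)
  expect_identical(rpe_o$orthogonalized_against, "RO")
  ro_o <- orthogonalize(ro, rpe)
  expect_lt(abs(cor(ro_o$samples, rpe$samples)), 1e-8)

  # an already-orthogonal target passes through unchanged (both centered)
  set.seed(11)
  a <- zscore(rnorm(100))
  b <- zscore(as.numeric(stats::lm.fit(cbind(1, a), rnorm(100))$residuals))
  regA <- new_test_regressor("a", a)
  regB <- new_test_regressor("b", b)
  expect_equal(orthogonalize(regB, regA)$samples, b, tolerance = 1e-10)

  # target in the span of the base is degenerate
  expect_error(orthogonalize(ro, ro), "degenerate")
})

test_that("the four comparison designs are built correctly", {
  p <- random_regressor_pair(n = 150, rho = 0.6, seed = 5)
  d <- build_designs(p$A, p$B)
  expect_named(d, c("full1", "full2", "reduced_A", "reduced_B"))
  M1 <- as.matrix(d$full1)
  M2 <- as.matrix(d$full2)
  expect_identical(colnames(M1), c("(Intercept)", "A", "B.orth"))
  expect_identical(colnames(M2), c("(Intercept)", "B", "A.orth"))
  expect_true(all(M1[, 1] == 1))
  # span preservation: both full designs project onto the same space
  expect_lt(norm(hat_matrix(M1) - hat_matrix(M2), "F"), 1e-8)

  # orthogonal pair: orthogonalization leaves columns unchanged
  set.seed(2)
  a <- zscore(rnorm(120))
  b <- zscore(as.numeric(stats::lm.fit(cbind(1, a), rnorm(120))$residuals))
  d2 <- build_designs(new_test_regressor("a", a), new_test_regressor("b", b))
  expect_equal(as.matrix(d2$full1)[, "b.orth"],
               as.matrix(d2$full2)[, "b"],
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(build_designs(p$A, new_test_regressor("c", rnorm(150))),
               "standardized")
})
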