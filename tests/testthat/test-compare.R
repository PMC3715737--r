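test_that("the fixture's regions are attributed to their majority model", {
  ds <- two_region_fixture(seed = 1)
  ro <- ds$regressors$RO
  rpe <- ds$regressors$RPE
  repA <- run_report(ds$series$RegionA, ro, rpe, region = "RegionA")
  repB <- run_report(ds$series$RegionB, ro, rpe, region = "RegionB")
  for (res in repA$results) expect_identical(res$winner, "A")
  for (res in repB$results) expect_identical(res$winner, "B")
  expect_true(repA$agreement)
  expect_true(repB$agreement)
  expect_equal(round(repA$diagnostics$r, 2), 0.89)
  expect_true(repA$diagnostics$shared_variance_warning)
  # non-orthogonalized betas are all positive: either model "activates"
  # against baseline in both regions, so only the comparison is informative
  nb <- repA$results$nonorthogonalized_betas
  expect_gt(nb$statistic_A, 0)
  expect_gt(nb$statistic_B, 0)
})

test_that("pure-signal series give a clean unique-variance verdict", {
  p <- random_regressor_pair(n = 200, rho = 0.6, seed = 8)
  res <- compare_orthogonalized(p$A$samples, p$A, p$B)
  expect_lt(abs(res$statistic_B), 1e-8)
  expect_identical(res$winner, "A")
  # identical candidates cannot be orthogonalized
  dup <- p$A; dup$name <- "A2"
  expect_error(compare_orthogonalized(p$A$samples, p$A, dup), "degenerate")
  expect_error(compare_residuals(p$A$samples, p$A, dup), "degenerate")
  # same name is rejected up front
  expect_error(run_report(p$A$samples, p$A, p$A), "distinct")
})

test_that("a symmetric mixture is declared a tie", {
  p <- random_regressor_pair(n = 200, rho = 0.5, seed = 13)
  y <- 0.5 * p$A$samples + 0.5 * p$B$samples
  res <- compare_nonorthogonalized(y, p$A, p$B, tie_tolerance = 1e-6)
  expect_lt(abs(res$margin), 1e-6)
  expect_identical(res$winner, "tie")
  res_o <- compare_orthogonalized(y, p$A, p$B, tie_tolerance = 1e-6)
  expect_identical(res_o$winner, "tie")
})

test_that("swapping the candidates negates margins and swaps winners", {
  ds <- two_region_fixture(seed = 3)
  ro <- ds$regressors$RO
  rpe <- ds$regressors$RPE
  y <- ds$series$RegionA
  fwd <- run_report(y, ro, rpe)
  rev <- run_report(y, rpe, ro)
  for (a in names(fwd$results)) {
    expect_equal(fwd$results[[a]]$margin, -rev$results[[a]]$margin,
                 tolerance = 1e-8)
    expect_identical(rev$results[[a]]$winner,
                     switch(fwd$results[[a]]$winner, A = "B", B = "A",
                            tie = "tie"))
  }
})

test_that("the three approaches agree away from ties", {
  ds <- two_region_fixture(seed = 1)
  ro <- ds$regressors$RO
  rpe <- ds$regressors$RPE
  n_agree <- 0L
  n_runs <- 40L
  for (i in seq_len(n_runs)) {
    set.seed(5000 + i)
    wA <- runif(1)
    wB <- if (wA > 0.5) runif(1, 0, wA - 0.2) else runif(1, wA + 0.2, 1)
    spec <- region_spec("r", wA, wB, noise_sd = runif(1, 0.05, 0.5),
                        seed = 5000 + i)
    rep <- run_report(simulate_region(ro, rpe, spec), ro, rpe)
    winners <- vapply(rep$results, `[[`, "", "winner")
    if (rep$agreement) n_agree <- n_agree + 1L
    else expect_true("tie" %in% winners ||
                       min(abs(vapply(rep$results, `[[`, 0, "margin"))) <
                         0.05)
  }
  expect_gte(n_agree / n_runs, 0.95)
})

test_that("orthogonal candidates make every approach pick the signal", {
  set.seed(17)
  a <- zscore(rnorm(150))
  b <- zscore(as.numeric(stats::lm.fit(cbind(1, a), rnorm(150))$residuals))
  regA <- new_test_regressor("sig", a)
  regB <- new_test_regressor("null", b)
  set.seed(18)
  y <- a + rnorm(150, sd = 0.1)
  rep <- run_report(y, regA, regB)
  expect_true(rep$agreement)
  for (res in rep$results) expect_identical(res$winner, "A")
  expect_lt(abs(rep$diagnostics$r), 0.2)
})
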