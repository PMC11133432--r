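test_that("Wald ratio is the outcome/exposure quotient with delta-method SE", {
  hs <- harmonized_set(0.1, 0.01, 0.02, 0.01)
  r <- mr_wald_ratio(hs)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.1)
  # null outcome effect
  r0 <- mr_wald_ratio(harmonized_set(0.1, 0.01, 0, 0.01))
  expect_equal(r0$estimate, 0)
  expect_equal(r0$pval, 1)
  # sign follows the ratio
  rneg <- mr_wald_ratio(harmonized_set(-0.1, 0.01, 0.02, 0.01))
  expect_equal(rneg$estimate, -0.2)
  expect_error(mr_wald_ratio(harmonized_set(0, 0.01, 0.02, 0.01)),
               class = "bimr_numerical_error")
})

test_that("IVW equals the ratio-weighted mean and floors the residual scale", {
  hs <- two_snp_fixture()
  r <- mr_ivw(hs)
  expect_equal(r$estimate, 0.16, tolerance = 1e-10)
  # regression-through-origin identity with ratio weights (bx/se_out)^2
  w <- (hs$beta_exp / hs$se_out)^2
  expect_equal(r$estimate, sum(w * hs$beta_out / hs$beta_exp) / sum(w),
               tolerance = 1e-12)

  # perfect proportionality: estimate = c, SE at the fixed-effect floor
  hsp <- harmonized_set(c(0.1, 0.2, 0.3), 0.01, c(0.03, 0.06, 0.09), 0.01)
  rp <- mr_ivw(hsp)
  expect_equal(rp$estimate, 0.3, tolerance = 1e-12)
  expect_equal(rp$aux$sigma2, 1)
  expect_equal(rp$se, 1 / sqrt(sum((hsp$beta_exp / hsp$se_out)^2)),
               tolerance = 1e-12)

  # duplicating a single SNP reproduces its Wald ratio as the IVW estimate
  one <- harmonized_set(0.1, 0.01, 0.02, 0.01)
  dup <- harmonized_set(c(0.1, 0.1), 0.01, c(0.02, 0.02), 0.01)
  expect_equal(mr_ivw(dup)$estimate, mr_wald_ratio(one)$estimate,
               tolerance = 1e-12)
  expect_error(mr_ivw(one), class = "bimr_insufficient_instruments")
})

test_that("Egger recovers an exact affine relation and ignores orientation", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  hs <- harmonized_set(bx, 0.01, 0.01 + 0.3 * bx, 0.01)
  r <- mr_egger(hs)
  expect_equal(r$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r$aux$intercept, 0.01, tolerance = 1e-10)

  # flipping the sign of both betas of one SNP leaves the fit unchanged
  hs2 <- hs
  hs2$beta_exp[2] <- -hs2$beta_exp[2]
  hs2$beta_out[2] <- -hs2$beta_out[2]
  r2 <- mr_egger(hs2)
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-12)
  expect_equal(r2$aux$intercept, r$aux$intercept, tolerance = 1e-12)

  expect_error(mr_egger(harmonized_set(rep(0.1, 3), 0.01, c(0.1, 0.2, 0.3), 0.01)),
               class = "bimr_numerical_error")
})

test_that("weighted median interpolates the ratio distribution at weight 1/2", {
  # equal weights, three ratios: the middle order statistic
  hs <- harmonized_set(c(0.1, 0.1, 0.1), 0.01, c(0.01, 0.02, 0.09), 0.01)
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 1)$estimate, 0.2)

  # hand evaluation of the cumulative-weight interpolation:
  # ratios {0.1, 0.2}, weights {0.75, 0.25} -> cw {0.375, 0.875};
  # estimate = 0.1 + 0.1 * (0.5 - 0.375) / 0.5 = 0.125
  expect_equal(bimr:::weighted_median_point(c(0.1, 0.2), c(0.75, 0.25)),
               0.125, tolerance = 1e-12)

  # determinism contract of the bootstrap SE
  h <- simulate_harmonized(sim_truth(seed = 5, k_causal = 20))
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  c <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_lt(abs(a$se - c$se), 0.5 * a$se)  # different seed: bootstrap noise only
})

test_that("maximum likelihood handles exact fits and the precise-exposure limit", {
  hsp <- harmonized_set(c(0.1, 0.2, 0.3), 0.01, c(0.03, 0.06, 0.09), 0.01)
  expect_equal(mr_max_likelihood(hsp)$estimate, 0.3, tolerance = 1e-6)

  # se_exp -> 0: the ML estimate approaches the (fixed-effect) IVW slope
  h <- simulate_harmonized(sim_truth(seed = 3, k_causal = 30, n_exp = 1e9))
  expect_equal(mr_max_likelihood(h)$estimate, mr_ivw(h)$estimate,
               tolerance = 1e-5)
})

test_that("ML recovers the causal effect over replicates", {
  ests <- vapply(1:200, function(i) {
    h <- simulate_harmonized(sim_truth(seed = i, k_causal = 50, theta = 0.1))
    mr_max_likelihood(h)$estimate
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.1), 4 * mc_se + 0.002)
})

test_that("RAPS handles exact fits, agrees with IVW absent pleiotropy, and recovers tau2", {
  hsp <- harmonized_set(c(0.1, 0.2, 0.3), 0.01, c(0.03, 0.06, 0.09), 0.01)
  rp <- mr_raps(hsp)
  expect_equal(rp$estimate, 0.3, tolerance = 1e-6)
  expect_equal(rp$aux$tau2, 0)

  diffs <- vapply(1:100, function(i) {
    h <- simulate_harmonized(sim_truth(seed = i, k_causal = 50, theta = 0.1))
    mr_raps(h)$estimate - mr_ivw(h)$estimate
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.005)

  tau2s <- vapply(1:50, function(i) {
    h <- simulate_harmonized(sim_truth(seed = i, k_causal = 100, theta = 0.1,
                                       tau2 = 0.001, outcome_binary = FALSE,
                                       n_out = 2e5))
    mr_raps(h, loss = "quadratic")$aux$tau2
  }, numeric(1))
  expect_lt(abs(mean(tau2s) - 0.001), 2.5e-4)
})

test_that("all estimators are invariant to joint per-SNP sign flips", {
  h <- simulate_harmonized(sim_truth(seed = 8, k_causal = 15))
  flip <- c(2, 5, 9)
  h2 <- h
  h2$beta_exp[flip] <- -h2$beta_exp[flip]
  h2$beta_out[flip] <- -h2$beta_out[flip]
  expect_equal(mr_ivw(h2)$estimate, mr_ivw(h)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$estimate, mr_egger(h)$estimate, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, 100, 1)$estimate,
               mr_weighted_median(h, 100, 1)$estimate, tolerance = 1e-12)
  expect_equal(mr_max_likelihood(h2)$estimate, mr_max_likelihood(h)$estimate,
               tolerance = 1e-8)
  expect_equal(mr_raps(h2)$estimate, mr_raps(h)$estimate, tolerance = 1e-6)
})

test_that("the estimator battery adapts to instrument count and reports ORs", {
  h1 <- simulate_harmonized(sim_truth(seed = 2, k_causal = 1))
  r1 <- mr_run_all(h1)
  expect_named(r1$results, "wald_ratio")

  h2 <- simulate_harmonized(sim_truth(seed = 2, k_causal = 2))
  r2 <- mr_run_all(h2)
  expect_setequal(names(r2$results), c("ivw", "max_likelihood"))

  h5 <- simulate_harmonized(sim_truth(seed = 2, k_causal = 12))
  r5 <- mr_run_all(h5, n_boot = 100)
  expect_setequal(names(r5$results),
                  c("ivw", "egger", "weighted_median", "max_likelihood", "raps"))
  # binary outcome: OR = exp(estimate), CI exponentiated
  for (r in r5$results) {
    expect_equal(r$or, exp(r$estimate), tolerance = 1e-12)
    expect_equal(r$or_ci_low, exp(r$ci_low), tolerance = 1e-12)
  }
  # no-pleiotropy data: all methods agree in sign
  signs <- vapply(r5$results, function(r) sign(r$estimate), numeric(1))
  expect_true(all(signs == signs[1]))

  # a failing method is recorded without aborting the others
  bad <- harmonized_set(rep(0.1, 4), 0.01, c(0.01, 0.02, 0.03, 0.04), 0.01)
  rb <- mr_run_all(bad, n_boot = 50)
  expect_true("egger" %in% names(rb$failures))
  expect_true("ivw" %in% names(rb$results))
})

test_that("p-values are consistent with estimate/se under the normal approximation", {
  h <- simulate_harmonized(sim_truth(seed = 12, k_causal = 10))
  res <- mr_run_all(h, n_boot = 100)$results
  for (r in res) {
    expect_equal(r$pval, 2 * pnorm(-abs(r$estimate / r$se)),
                 tolerance = 1e-6)
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
  }
})
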