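test_that("Cochran's Q matches hand arithmetic and degenerate cases", {
  # identical ratios: zero dispersion
  hs0 <- harmonized_set(c(0.1, 0.2), 0.01, c(0.02, 0.04), 0.01)
  q0 <- cochran_q(hs0)
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$q_pval, 1)

  # worked 2-SNP case: ratios {0.2, 0.15}, weights {100, 400} -> Q = 0.2
  q <- cochran_q(two_snp_fixture())
  expect_equal(q$q_stat, 0.2, tolerance = 1e-10)
  expect_equal(q$q_df, 1)
})

test_that("Q in ratio form equals the origin-regression weighted RSS", {
  h <- simulate_harmonized(sim_truth(seed = 14, k_causal = 25))
  q <- cochran_q(h)
  w <- 1 / h$se_out^2
  slope <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  rss <- sum(w * (h$beta_out - slope * h$beta_exp)^2)
  expect_equal(q$q_stat, rss, tolerance = 1e-8)
})

test_that("Q over null replicates has mean about its degrees of freedom", {
  qs <- vapply(1:300, function(i) {
    h <- simulate_harmonized(sim_truth(seed = i, k_causal = 10, theta = 0.1))
    cochran_q(h)$q_stat / 9
  }, numeric(1))
  expect_lt(abs(mean(qs) - 1), 0.1)
})

test_that("Egger intercept test recovers injected directional pleiotropy", {
  # strong-instrument regime so regression dilution is negligible
  ints <- vapply(1:200, function(i) {
    h <- simulate_harmonized(sim_truth(seed = i, k_causal = 30, theta = 0.1,
                                       pleiotropy_mode = "directional",
                                       pleiotropy_mean = 0.01,
                                       pleiotropy_sd = 0.005,
                                       n_exp = 5e5, gamma_range = c(0.05, 0.3)))
    egger_intercept_test(h)$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.01), 0.002)

  # exact affine data: intercept recovered exactly
  bx <- c(0.1, 0.15, 0.25, 0.3)
  hs <- harmonized_set(bx, 0.01, 0.02 + 0.4 * bx, 0.01)
  expect_equal(egger_intercept_test(hs)$intercept, 0.02, tolerance = 1e-10)
})

test_that("MR-PRESSO is deterministic given a seed and flags implanted outliers", {
  h <- simulate_harmonized(sim_truth(seed = 40, k_causal = 10, theta = 0.1))
  h$beta_out[3] <- h$beta_out[3] + 10 * h$se_out[3]
  a <- mr_presso(h, n_sim = 500, seed = 9)
  b <- mr_presso(h, n_sim = 500, seed = 9)
  expect_identical(a[c("global_pval", "outliers", "distortion_pval")],
                   b[c("global_pval", "outliers", "distortion_pval")])
  expect_true(h$snp_id[3] %in% a$outliers$snp_id)
  expect_lt(a$global_pval, 0.05)
  expect_error(mr_presso(h[1:3, ], n_sim = 500, seed = 1),
               class = "bimr_insufficient_instruments")
  expect_error(mr_presso(h, n_sim = 50, seed = 1), class = "bimr_config_error")
})

test_that("the distortion test runs when outliers are found", {
  h <- simulate_harmonized(sim_truth(seed = 41, k_causal = 12, theta = 0.1))
  h$beta_out[5] <- h$beta_out[5] + 12 * h$se_out[5]
  pr <- mr_presso(h, n_sim = 500, seed = 3)
  expect_gt(nrow(pr$outliers), 0)
  expect_true(is.finite(pr$distortion_pval))
  expect_true(pr$distortion_pval > 0 && pr$distortion_pval <= 1)
})

test_that("leave-one-out returns k fits bounded by the closed-form oracle", {
  h <- simulate_harmonized(sim_truth(seed = 15, k_causal = 8))
  res <- leave_one_out(h)
  expect_equal(nrow(res$loo), 8)
  # oracle: recompute each left-out estimate as the closed-form weighted mean
  w <- (h$beta_exp / h$se_out)^2
  ratios <- h$beta_out / h$beta_exp
  oracle <- vapply(1:8, function(j) sum((w * ratios)[-j]) / sum(w[-j]), numeric(1))
  expect_equal(res$loo$estimate, oracle, tolerance = 1e-10)
  expect_true(all(res$loo$estimate >= min(oracle) - 1e-12 &
                  res$loo$estimate <= max(oracle) + 1e-12))

  # exchangeability: k identical SNPs give k identical left-out estimates
  # (strong signal, so full and left-out fits share significance status)
  hd <- harmonized_set(rep(0.1, 4), 0.01, rep(0.05, 4), 0.01)
  rd <- leave_one_out(hd)
  expect_true(all(abs(rd$loo$estimate - 0.5) < 1e-12))
  expect_false(rd$loo_flag)
})

test_that("a dominant outlier moves its left-out estimate most and sets the flag", {
  # 7 concordant SNPs plus one dominant-weight discordant SNP that cancels
  # the pooled effect; only its removal restores significance
  bx <- c(rep(0.1, 7), 0.1)
  by <- c(rep(0.03, 7), -0.03)
  se_out <- c(rep(0.01, 7), 0.1 / sqrt(700))
  h <- harmonized_set(bx, 0.01, by, se_out)
  res <- leave_one_out(h, sig_level = 1e-4)
  shifts <- abs(res$loo$estimate - mr_ivw(h)$estimate)
  expect_equal(which.max(shifts), 8)
  expect_true(res$loo_flag)
})

test_that("the sensitivity battery degrades gracefully with instrument count", {
  h2 <- simulate_harmonized(sim_truth(seed = 16, k_causal = 2))
  r2 <- run_sensitivity(h2, n_sim = 200, seed = 1)
  expect_false(is.na(r2$q_pval))
  expect_true(is.na(r2$egger_intercept_pval))
  expect_true(is.na(r2$presso_global_pval))

  h6 <- simulate_harmonized(sim_truth(seed = 16, k_causal = 6))
  r6 <- run_sensitivity(h6, n_sim = 200, seed = 1)
  expect_false(is.na(r6$presso_global_pval))
  expect_equal(nrow(r6$loo), 6)
  long <- sensitivity_long(r6, "expo", "outc")
  expect_true(all(c("q_pval", "presso_global_pval") %in% long$diagnostic))
})
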