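test_that("significance filtering keeps sub-threshold records in order", {
  tab <- make_gwas(n = 2, pval = c(1e-9, 1e-7))
  expect_equal(filter_significant(tab, 5e-8)$snp_id, "rs001")
  expect_equal(nrow(filter_significant(tab, 1.0)), 2)
  # the stricter sensitivity threshold splits 4e-9 from 6e-9
  tab2 <- make_gwas(n = 2, pval = c(4e-9, 6e-9))
  expect_equal(filter_significant(tab2, 5e-9)$snp_id, "rs001")
  expect_equal(drop_log(filter_significant(tab2, 5e-9))$reason[1],
               "above_p_threshold")
  expect_error(filter_significant(tab, 0), class = "bimr_config_error")
})

test_that("clumping applies the p-value dominance, window and LD rules", {
  tab <- make_gwas(n = 2, pos = c(1e6, 1e6 + 1000), pval = c(1e-20, 1e-10))
  ld <- uniform_ld(tab, r2 = 0.9)
  expect_equal(clump(tab, ld, r2_max = 0.001, window_kb = 10000)$snp_id, "rs001")
  # 20,000 kb apart: both survive under a 10,000 kb window despite high r2
  tab2 <- make_gwas(n = 2, pos = c(1e6, 1e6 + 2e7), pval = c(1e-20, 1e-10))
  expect_equal(nrow(clump(tab2, uniform_ld(tab2, 0.9), 0.001, 10000)), 2)
  # missing SNP in the LD reference is a configuration error naming it
  expect_error(clump(tab, uniform_ld(tab[1, , drop = FALSE]), 0.001, 10000),
               class = "bimr_config_error", regexp = "rs002")
})

test_that("clumped output satisfies all pairwise constraints (greedy oracle)", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 12
    tab <- make_gwas(n = n, pos = sort(sample(1:5e7, n)),
                     pval = 10^-runif(n, 6, 30))
    m <- matrix(runif(n * n, 0, 0.5), n, n)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m[sample(length(m), 20)] <- 0.9
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(tab$snp_id, tab$snp_id)
    ld <- ld_matrix(m)
    out <- clump(tab, ld, r2_max = 0.2, window_kb = 5000)
    kept <- out$snp_id
    # no kept pair may violate (r2 >= r2_max AND distance <= window)
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i >= j) next
      pi <- tab$pos[tab$snp_id == kept[i]]; pj <- tab$pos[tab$snp_id == kept[j]]
      viol <- unclass(ld)[kept[i], kept[j]] >= 0.2 && abs(pi - pj) <= 5e6
      expect_false(viol)
    }
    # every dropped SNP is linked to a kept SNP with smaller p-value
    dropped <- setdiff(tab$snp_id, kept)
    for (d in dropped) {
      pd <- tab$pval[tab$snp_id == d]
      linked <- vapply(kept, function(k) {
        unclass(ld)[d, k] >= 0.2 &&
          abs(tab$pos[tab$snp_id == d] - tab$pos[tab$snp_id == k]) <= 5e6 &&
          tab$pval[tab$snp_id == k] <= pd
      }, logical(1))
      expect_true(any(linked))
    }
  }
})

test_that("catalog exclusion removes listed SNPs once with all reasons logged", {
  tab <- make_gwas(n = 3)
  cat <- confounder_catalog(data.frame(
    snp_id = c("rs001", "rs001", "rs002"),
    trait = c("education", "smoking", "education"),
    pval = c(1e-10, 1e-12, 1e-6)))
  out <- exclude_by_catalog(tab, cat, 5e-8)
  expect_setequal(out$snp_id, c("rs002", "rs003"))  # rs002 sub-threshold: kept
  log <- drop_log(out)
  expect_equal(sum(log$snp_id == "rs001"), 2)  # both triggering traits logged
})

test_that("region exclusion uses a closed interval on the right chromosome", {
  tab <- make_gwas(n = 3, chrom = c("6", "7", "6"),
                   pos = c(30000000, 30000000, 28477797))
  out <- exclude_region(tab, "6", 28477797, 33448354)
  expect_equal(out$snp_id, "rs002")  # chr7 kept; boundary SNP removed
  expect_error(exclude_region(tab, "6", 10, 5), class = "bimr_config_error")
})

test_that("instrument strength matches the closed formulas", {
  tab <- make_gwas(n = 1, beta = 0.1, se = 0.02, n_samp = 10000)
  st <- instrument_strength(tab)
  r2 <- 0.01 / (0.01 + 0.0004 * 10000)
  expect_equal(st$r2_total, r2, tolerance = 1e-12)
  expect_equal(st$f_stat, r2 * (10000 - 2) / (1 - r2), tolerance = 1e-12)
  expect_false(st$weak)

  # null instruments: R2 = 0, F = 0, weak flag set
  tab0 <- make_gwas(n = 3, beta = 0, pval = 0.5)
  st0 <- instrument_strength(tab0)
  expect_equal(st0$r2_total, 0)
  expect_equal(st0$f_stat, 0)
  expect_true(st0$weak)

  # exact formula evaluation at k = 2 and k = 4 with identical per-SNP R2;
  # the total R2 doubles with k, so the set-level F is nearly unchanged,
  # while doubling k at FIXED total R2 halves it
  tab1 <- make_gwas(n = 2, beta = 0.1, se = 0.02)
  tab2 <- make_gwas(n = 4, beta = 0.1, se = 0.02)
  f1 <- instrument_strength(tab1)$f_stat
  f2 <- instrument_strength(tab2)$f_stat
  r2s <- instrument_strength(tab1)$per_snp_r2[[1]]
  expect_equal(f1, 2 * r2s * (10000 - 3) / ((1 - 2 * r2s) * 2), tolerance = 1e-12)
  expect_equal(f2, 4 * r2s * (10000 - 5) / ((1 - 4 * r2s) * 4), tolerance = 1e-12)
  f_fixed <- function(r2t, k, n = 10000) r2t * (n - k - 1) / ((1 - r2t) * k)
  expect_lt(abs(f_fixed(0.05, 8) / f_fixed(0.05, 4) - 0.5), 0.01)

  # F monotone in r2_total at fixed k, n
  fs <- vapply(seq(0.001, 0.2, by = 0.01), function(r2t) {
    r2t * (10000 - 4) / ((1 - r2t) * 3)
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("filter and exclusion operations commute in the surviving set", {
  sim <- simulate_pair(sim_truth(seed = 9, k_causal = 8, n_null = 80))
  tab <- sim$exposure
  cat <- sim$catalog
  a <- exclude_region(exclude_by_catalog(filter_significant(tab, 5e-8), cat),
                      "1", 1, 5e7)
  b <- filter_significant(exclude_region(exclude_by_catalog(tab, cat), "1", 1, 5e7),
                          5e-8)
  expect_setequal(a$snp_id, b$snp_id)
})

test_that("planted confounder SNPs are removed exactly", {
  sim <- simulate_pair(sim_truth(seed = 31, k_causal = 10, n_null = 50,
                                 confounder_fraction = 0.3))
  planted <- sim$truth$planted_confounders
  expect_gt(length(planted), 0)
  out <- exclude_by_catalog(sim$exposure, sim$catalog, 5e-8)
  removed <- setdiff(sim$exposure$snp_id, out$snp_id)
  expect_setequal(removed, planted)
})
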