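test_that("write then read reproduces a table field-for-field", {
  tab <- make_gwas(n = 3, beta = c(0.1, -0.05, 0.2), eaf = c(0.1, 0.4, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_name = attr(tab, "trait_name"))
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(nrow(back), 3)
})

test_that("invalid rows are dropped with logged reasons", {
  df <- sumstats_df(n = 5)
  df$se[2] <- 0                      # nonpositive se
  df$effect_allele[3] <- "a"         # lower-case, should be accepted
  df$other_allele[3] <- "t"
  df$effect_allele[4] <- "AT"        # indel
  df$pval[5] <- 0                    # out of range
  tab <- gwas_table(df)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$effect_allele[2], "A")
  expect_equal(tab$other_allele[2], "T")
  log <- drop_log(tab)
  expect_setequal(log$reason[log$snp_id == "rs002"], "nonpositive_se")
  expect_setequal(log$reason[log$snp_id == "rs004"], "indel")
  expect_setequal(log$reason[log$snp_id == "rs005"], "bad_pval")
})

test_that("reader errors distinguish configuration from input problems", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR", path)  # header only, missing columns
  expect_error(read_sumstats(path), class = "bimr_input_error")
  df <- sumstats_df(3)
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P", "N")
  df$P <- format(df$P)
  write.table(df[-10], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), class = "bimr_config_error",
               regexp = "N")
})

test_that("standardization matches the closed formula and preserves z and p", {
  # direct evaluation of the printed formula for z = 5, f = 0.3, n = 10000
  tab <- make_gwas(n = 2, beta = c(0, 0.1), se = 0.02, eaf = 0.3)
  out <- standardize_effects(tab)
  expect_equal(out$beta[1], 0)
  oracle <- 5 / sqrt(2 * 0.3 * 0.7 * (10000 + 25))
  expect_equal(out$beta[2], oracle, tolerance = 1e-12)
  expect_equal(out$se[2], oracle / 5, tolerance = 1e-12)

  # property: z and p unchanged for random records
  set.seed(11)
  df <- sumstats_df(n = 500, beta = rnorm(500, 0, 0.05),
                    se = runif(500, 0.005, 0.05),
                    eaf = runif(500, 0.01, 0.99),
                    n_samp = sample(1000:50000, 500, TRUE))
  df$pval <- 2 * pnorm(-abs(df$beta / df$se))
  tab <- gwas_table(df)
  out <- standardize_effects(tab)
  expect_lt(max(abs(out$beta / out$se - tab$beta / tab$se)), 1e-10)
  expect_equal(out$pval, tab$pval)

  # eaf on the boundary is rejected, not propagated as Inf
  df$eaf[1] <- 1
  out2 <- standardize_effects(gwas_table(df))
  expect_equal(nrow(out2), 499)
  expect_true("degenerate_eaf" %in% drop_log(out2)$reason)
})

test_that("harmonization aligns, flips, and prunes palindromes by the MAF window", {
  exp <- make_gwas(n = 4, effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "T"),
                   beta = 0.1, eaf = c(0.3, 0.3, 0.49, 0.10))
  out_df <- sumstats_df(n = 4, effect_allele = c("A", "G", "A", "A"),
                        other_allele = c("G", "A", "T", "T"),
                        beta = 0.05, eaf = c(0.3, 0.7, 0.49, 0.10),
                        n_samp = 20000)
  out <- gwas_table(out_df, trait_name = "out")
  hs <- harmonize(exp, out, palindrome_maf_window = 0.08)
  # aligned pair kept unchanged; swapped pair sign-flipped
  expect_equal(hs$beta_out[hs$snp_id == "rs001"], 0.05)
  expect_equal(hs$beta_out[hs$snp_id == "rs002"], -0.05)
  # palindrome at MAF 0.49 removed, at MAF 0.10 kept
  expect_false("rs003" %in% hs$snp_id)
  expect_true("rs004" %in% hs$snp_id)
  expect_equal(drop_log(hs)$reason[drop_log(hs)$snp_id == "rs003"],
               "palindrome_ambiguous")
})

test_that("irreconcilable alleles are dropped and zero overlap is an error", {
  exp <- make_gwas(n = 2, effect_allele = "A", other_allele = "G")
  out <- gwas_table(sumstats_df(n = 2, effect_allele = "C", other_allele = "T"))
  disjoint <- gwas_table(sumstats_df(n = 2, snp_id = c("rs900", "rs901")))
  expect_error(harmonize(exp, disjoint), class = "bimr_empty_overlap")
  hs_empty <- harmonize(exp, out)
  expect_equal(nrow(hs_empty), 0)
  expect_true(all(drop_log(hs_empty)$reason[drop_log(hs_empty)$snp_id %in%
                                              c("rs001", "rs002")] == "allele_mismatch"))
})

test_that("harmonization is idempotent and undoes injected allele swaps exactly", {
  sim <- simulate_pair(sim_truth(seed = 21, k_causal = 6, n_null = 60,
                                 palindrome_frac = 0))
  hs <- harmonize(sim$exposure, sim$outcome)
  # the generator records which outcome records were stored swapped; after
  # harmonization the outcome effects must equal the pre-swap values
  swapped <- sim$truth$swapped_in_outcome
  out <- sim$outcome
  original <- ifelse(out$snp_id %in% swapped, -out$beta, out$beta)
  expect_equal(hs$beta_out, original[match(hs$snp_id, out$snp_id)])

  # idempotence: re-harmonizing the harmonized orientation changes nothing
  as_tab <- function(beta, se, pval, n) {
    gwas_table(data.frame(snp_id = hs$snp_id, chrom = hs$chrom, pos = hs$pos,
                          effect_allele = hs$effect_allele,
                          other_allele = hs$other_allele,
                          eaf = hs$eaf, beta = beta, se = se, pval = pval,
                          n = n, stringsAsFactors = FALSE))
  }
  e2 <- as_tab(hs$beta_exp, hs$se_exp, hs$pval_exp, attr(hs, "n_exp"))
  o2 <- as_tab(hs$beta_out, hs$se_out, hs$pval_out, attr(hs, "n_out"))
  hs2 <- harmonize(e2, o2)
  expect_equal(hs2$beta_out, hs$beta_out)
  expect_equal(hs2$beta_exp, hs$beta_exp)
  expect_equal(hs2$snp_id, hs$snp_id)
})
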