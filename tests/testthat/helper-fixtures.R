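# Shared fixture builders (all data generated in code).

# minimal well-formed summary-statistics data.frame
sumstats_df <- function(n = 3, snp_id = sprintf("rs%03d", seq_len(n)),
                        chrom = "1", pos = seq_len(n) * 1e6,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, beta = 0.1, se = 0.02,
                        pval = 2 * pnorm(-abs(beta / se)), n_samp = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n_samp,
             stringsAsFactors = FALSE)
}

make_gwas <- function(...) gwas_table(sumstats_df(...))

# the worked 2-SNP fixture: ratios 0.2 and 0.15, ratio weights 100 and 400
two_snp_fixture <- function() {
  harmonized_set(beta_exp = c(0.1, 0.2), se_exp = c(0.01, 0.01),
                 beta_out = c(0.02, 0.03), se_out = c(0.01, 0.01))
}

# dense LD matrix fixture over the ids of a gwas_table
uniform_ld <- function(tab, r2 = 0) {
  m <- matrix(r2, nrow(tab), nrow(tab))
  diag(m) <- 1
  dimnames(m) <- list(tab$snp_id, tab$snp_id)
  ld_matrix(m)
}
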