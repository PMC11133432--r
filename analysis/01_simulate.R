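#!/usr/bin/env Rscript
# Build the synthetic bidirectional study used by the rest of the workflow:
# three brain-IDP-like exposure GWASs, two disease GWASs, an LD reference,
# a confounder catalog and an IDP phenotype-correlation matrix.
#
# Planted truths:
#   idp_a -> disease_ad : theta = log(0.79) (protective, AD-scale cohort)
#   idp_b, idp_c        : null (theta = 0)
#   disease_lbd -> idp_d: theta = 0.1 (reverse-direction effect; the LBD-like
#                         GWAS is the one with genome-wide instruments)
# All GWASs share the SNP panel layout, so the single LD reference applies.

suppressPackageStartupMessages(library(bimr))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

k <- 10; n_null <- 40

# forward truth: idp_a causes the AD-like disease, OR 0.79 per SD
# all traits share a SNP panel (panel_seed) as if genotyped on one array
panel <- 20260100
simA <- simulate_pair(sim_truth(seed = 20260101, theta = log(0.79),
                                k_causal = k, n_null = n_null,
                                n_exp = 33224, n_out = 63926,
                                outcome_binary = TRUE, n_cases = 21982,
                                panel_seed = panel))
# null exposures
simB <- simulate_pair(sim_truth(seed = 20260102, theta = 0, k_causal = k,
                                n_null = n_null, panel_seed = panel))
simC <- simulate_pair(sim_truth(seed = 20260103, theta = 0, k_causal = k,
                                n_null = n_null, panel_seed = panel))
# reverse truth: an LBD-like disease (a 2,591/4,027 case-control GWAS is
# underpowered for instrument discovery, so the simulated cohort is larger)
# causally increases a diffusion IDP; its liability-scale effects are
# already standardized
simR <- simulate_pair(sim_truth(seed = 20260104, theta = 0.1, k_causal = k,
                                n_null = n_null, n_exp = 150000,
                                n_out = 33224, outcome_binary = FALSE,
                                panel_seed = panel))

write_sumstats(simA$exposure, file.path(out, "idp_a.tsv"))
write_sumstats(simB$exposure, file.path(out, "idp_b.tsv"))
write_sumstats(simC$exposure, file.path(out, "idp_c.tsv"))
write_sumstats(simR$outcome,  file.path(out, "idp_d.tsv"))
write_sumstats(simA$outcome,  file.path(out, "disease_ad.tsv"))
# the reverse-truth "exposure" table is the disease GWAS
write_sumstats(simR$exposure, file.path(out, "disease_lbd.tsv"))
write_ld_matrix(simA$ld, file.path(out, "ld.tsv"), format = "long")
write.table(as.data.frame(simA$catalog), file.path(out, "confounders.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# phenotype correlation over the four IDPs: idp_a/idp_b moderately correlated
# (same structural modality), idp_c/idp_d weakly
corr <- simulate_phenotype_corr(blocks = list(c(2, 0.6), c(2, 0.2)))
dimnames(corr) <- list(c("idp_a", "idp_b", "idp_c", "idp_d"),
                       c("idp_a", "idp_b", "idp_c", "idp_d"))
write.table(corr, file.path(out, "idp_corr.tsv"), sep = "\t", quote = FALSE,
            col.names = NA)

yaml::write_yaml(list(
  planted = list(idp_a_to_disease_ad = log(0.79),
                 disease_lbd_to_idp_d = 0.1),
  k_causal = k, n_null = n_null,
  seeds = c(20260101, 20260102, 20260103, 20260104)),
  file.path(out, "study_truth.yaml"))

cat("Simulated study written to", out, "\n")
cat(sprintf("  %d instrument loci + %d null SNPs per GWAS\n", k, n_null))
cat(sprintf("  planted forward effect: idp_a -> disease_ad, log-OR %.3f (OR 0.79)\n",
            log(0.79)))
cat("  planted reverse effect: disease_lbd -> idp_d, beta 0.10\n")
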