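# A small bidirectional study fixture: two exposure traits, one binary
# disease outcome, shared SNP panel and LD reference, written as files.

make_study <- function(dir, theta = 0.3) {
  simA <- simulate_pair(sim_truth(seed = 301, theta = theta, k_causal = 10,
                                  n_null = 60, confounder_fraction = 0.1))
  simB <- simulate_pair(sim_truth(seed = 302, theta = theta, k_causal = 10,
                                  n_null = 60, confounder_fraction = 0.1))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(simA$exposure, file.path(dir, "idp_a.tsv"))
  write_sumstats(simB$exposure, file.path(dir, "idp_b.tsv"))
  write_sumstats(simA$outcome, file.path(dir, "disease.tsv"))
  write_ld_matrix(simA$ld, file.path(dir, "ld.tsv"))
  write.table(as.data.frame(simA$catalog), file.path(dir, "confounders.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}

study_config <- function(dir, out_dir, ...) {
  mr_config(
    exposure_files = c(idp_a = file.path(dir, "idp_a.tsv"),
                       idp_b = file.path(dir, "idp_b.tsv")),
    outcome_files = c(disease = file.path(dir, "disease.tsv")),
    outcome_binary = TRUE,
    outcome_cases = c(disease = 21982),
    outcome_totals = c(disease = 63926),
    ld_file = file.path(dir, "ld.tsv"),
    confounder_file = file.path(dir, "confounders.tsv"),
    m_eff = 135.48, n_diseases = 1, n_directions = 2,
    presso_nsim = 300, wm_boot = 200, seed = 7,
    out_dir = out_dir, ...)
}
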