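# Synthetic two-sample GWAS generator with known ground truth.
#
# The generator emulates the statistical structure of real summary-statistic
# inputs: a MAF spectrum, per-SNP sampling noise on the standardized scale
# (se ~ 1/sqrt(2 f (1-f) n)), a handful of genome-wide-significant loci with
# LD blocks, pleiotropic and confounder-linked variants, and binary or
# continuous outcomes. Ground truth (true causal effect, per-SNP instrument
# and direct effects, planted confounder SNPs) is echoed for recovery tests.

#' Ground-truth parameters for a synthetic two-sample GWAS pair
#'
#' @param theta true causal effect of the exposure on the outcome (per SD).
#' @param k_causal number of true instrument loci.
#' @param n_null number of null (non-instrument) loci; every locus spans an
#'   LD block of `ld_block_size` SNPs.
#' @param pleiotropy_mode direct-effect regime: `"none"`, `"balanced"`
#'   (mean-zero), `"directional"` (nonzero mean), or `"inside_violating"`
#'   (direct effects correlated with instrument strength).
#' @param pleiotropy_frac fraction of instrument loci carrying a direct
#'   effect (default 1).
#' @param pleiotropy_mean mean direct effect (directional mode) or
#'   regression slope of the direct effect on the instrument effect
#'   (inside_violating mode).
#' @param pleiotropy_sd SD of the direct-effect distribution.
#' @param tau2 systematic overdispersion added to the outcome sampling
#'   variance.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes.
#' @param outcome_binary logical; binary outcomes scale the outcome sampling
#'   variance by the case-ratio factor.
#' @param n_cases outcome case count (binary outcomes).
#' @param maf_range minor-allele-frequency bounds, within (0, 0.5].
#' @param gamma_range magnitude range of true instrument effects on the
#'   standardized scale (oriented positive on the effect allele).
#' @param ld_block_size SNPs per instrument LD block (index SNP + tags).
#' @param within_block_r2 squared LD correlation inside a block.
#' @param palindrome_frac fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs.
#' @param confounder_fraction fraction of instrument loci planted in the
#'   confounder catalog at genome-wide significance.
#' @param seed integer seed recorded in every output artifact.
#' @param panel_seed seed for the SNP panel (positions, frequencies,
#'   alleles); defaults to `seed`. Simulating several traits with a shared
#'   `panel_seed` emulates GWASs genotyped on the same variant panel, so
#'   their tables harmonize against each other.
#' @return object of class `sim_truth` (list).
#' @export
sim_truth <- function(theta = 0.1, k_causal = 30, n_null = 300,
                      pleiotropy_mode = c("none", "balanced", "directional",
                                          "inside_violating"),
                      pleiotropy_frac = 1, pleiotropy_mean = 0,
                      pleiotropy_sd = 0, tau2 = 0,
                      n_exp = 33224, n_out = 63926,
                      outcome_binary = TRUE, n_cases = 21982,
                      maf_range = c(0.05, 0.5), gamma_range = c(0.12, 0.18),
                      ld_block_size = 5, within_block_r2 = 0.8,
                      palindrome_frac = 0.05, confounder_fraction = 0.1,
                      seed = 1, panel_seed = seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(tau2 >= 0, pleiotropy_sd >= 0, n_exp > 0, n_out > 0,
            k_causal >= 0, n_null >= 0, ld_block_size >= 1,
            within_block_r2 >= 0, within_block_r2 <= 1,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            confounder_fraction >= 0, confounder_fraction <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (k_causal == 0 && pleiotropy_mode == "none" && theta != 0) {
    warning("theta != 0 with no instruments and no pleiotropy: outcome carries no exposure signal")
  }
  structure(as.list(environment()), class = "sim_truth")
}

ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"),
                     c("G", "A"), c("C", "A"), c("T", "G"), c("T", "C"))
PALINDROME_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# exchangeable within-block noise with correlation r
block_noise <- function(block_id, r) {
  z <- stats::rnorm(length(block_id))
  if (r <= 0) return(z)
  shared <- stats::rnorm(length(unique(block_id)))
  names(shared) <- as.character(unique(block_id))
  sqrt(r) * shared[as.character(block_id)] + sqrt(1 - r) * z
}

#' Simulate a paired exposure/outcome GWAS with LD and a confounder catalog
#'
#' Per SNP j the true instrument effect gamma_j and direct effect alpha_j are
#' drawn according to the pleiotropy regime; observed effects are
#' `beta_exp_j ~ N(gamma_j, se_exp_j^2)` and
#' `beta_out_j ~ N(theta * gamma_j + alpha_j, se_out_j^2 + tau2)` with SEs
#' set by the standardization relation `se = 1/sqrt(2 f (1-f) n)` (times the
#' case-ratio factor for binary outcomes). The genome is laid out as LD
#' blocks of `ld_block_size` SNPs; a random subset of `k_causal` blocks
#' carries instrument effects, whose tag SNPs have attenuated effects
#' (`r * gamma`) and correlated sampling noise; the remaining blocks are
#' null (`gamma = 0`). A fraction of SNPs in the outcome table is stored on
#' the swapped allele orientation to exercise harmonization.
#'
#' @param truth a [sim_truth()].
#' @return list with elements `exposure`, `outcome` ([gwas_table()]s),
#'   `ld` ([ld_matrix()]), `catalog` ([confounder_catalog()]) and `truth`
#'   (the input echoed, with per-SNP `gamma`, `alpha`, instrument ids and
#'   planted confounder ids added).
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  b <- truth$ld_block_size
  k <- truth$k_causal
  # every locus is an LD block of b SNPs; which loci are causal is drawn per
  # trait (effect seed), so traits sharing a panel get distinct instruments
  n_locus <- k + truth$n_null
  n_snp <- n_locus * b
  locus <- rep(seq_len(n_locus), each = b)
  block_head <- rep(c(TRUE, rep(FALSE, b - 1)), n_locus)

  chrom <- as.character(((seq_len(n_locus) - 1L) %% 22L) + 1L)[locus]
  locus_start <- (((seq_len(n_locus) - 1L) %/% 22L) + 1L) * 2e7
  within <- stats::ave(seq_len(n_snp), locus, FUN = seq_along) - 1L
  pos <- locus_start[locus] + within * 1000
  snp_id <- sprintf("rs%07d", seq_len(n_snp))

  # the SNP panel (frequencies, alleles) is seeded separately so several
  # traits can share a genotyping panel while drawing independent effects
  panel <- with_seed(truth$panel_seed, {
    maf <- stats::runif(n_snp, truth$maf_range[1], truth$maf_range[2])
    eaf <- ifelse(stats::runif(n_snp) < 0.5, maf, 1 - maf)
    pal <- stats::runif(n_snp) < truth$palindrome_frac
    pair_idx <- sample.int(length(ALLELE_PAIRS), n_snp, replace = TRUE)
    pal_idx <- sample.int(length(PALINDROME_PAIRS), n_snp, replace = TRUE)
    list(maf = maf, eaf = eaf,
         a1 = ifelse(pal, vapply(PALINDROME_PAIRS[pal_idx], `[`, "", 1),
                     vapply(ALLELE_PAIRS[pair_idx], `[`, "", 1)),
         a2 = ifelse(pal, vapply(PALINDROME_PAIRS[pal_idx], `[`, "", 2),
                     vapply(ALLELE_PAIRS[pair_idx], `[`, "", 2)))
  })
  maf <- panel$maf; eaf <- panel$eaf; a1 <- panel$a1; a2 <- panel$a2

  with_seed(truth$seed, {
    # which loci carry true instrument effects; index SNP is the block head,
    # tags carry r * gamma
    causal_loci <- sort(sample.int(n_locus, k))
    is_causal_block <- locus %in% causal_loci
    is_index <- block_head & is_causal_block
    causal_rank <- match(locus, causal_loci)  # NA for null loci

    r <- sqrt(truth$within_block_r2)
    gamma_index <- stats::runif(k, truth$gamma_range[1], truth$gamma_range[2])
    gamma <- numeric(n_snp)
    gamma[is_causal_block] <- gamma_index[causal_rank[is_causal_block]] *
      ifelse(is_index[is_causal_block], 1, r)

    # direct (pleiotropic) effects on a fraction of instrument loci
    alpha_locus <- numeric(k)
    pleio_loci <- integer(0)
    if (truth$pleiotropy_mode != "none" && k > 0) {
      n_pleio <- round(truth$pleiotropy_frac * k)
      pleio_loci <- sort(sample.int(k, n_pleio))
      alpha_locus[pleio_loci] <- switch(
        truth$pleiotropy_mode,
        balanced = stats::rnorm(n_pleio, 0, truth$pleiotropy_sd),
        directional = stats::rnorm(n_pleio, truth$pleiotropy_mean,
                                   truth$pleiotropy_sd),
        inside_violating = truth$pleiotropy_mean * gamma_index[pleio_loci] +
          stats::rnorm(n_pleio, 0, truth$pleiotropy_sd))
    }
    alpha <- numeric(n_snp)
    alpha[is_causal_block] <- alpha_locus[causal_rank[is_causal_block]] *
      ifelse(is_index[is_causal_block], 1, r)

    f <- maf
    se_exp <- 1 / sqrt(2 * f * (1 - f) * truth$n_exp)
    vfac <- if (truth$outcome_binary) {
      cr <- truth$n_cases / truth$n_out
      cr * (1 - cr)
    } else 1
    se_out <- 1 / sqrt(2 * f * (1 - f) * truth$n_out * vfac)

    bx <- gamma + se_exp * block_noise(locus, r)
    by <- truth$theta * gamma + alpha +
      sqrt(se_out^2 + truth$tau2) * block_noise(locus, r)

    mk_table <- function(beta, se, n, trait, binary, n_cases, n_controls,
                         swap = rep(FALSE, n_snp)) {
      gwas_table(data.frame(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = ifelse(swap, a2, a1),
        other_allele = ifelse(swap, a1, a2),
        eaf = ifelse(swap, 1 - eaf, eaf),
        beta = ifelse(swap, -beta, beta),
        se = se,
        pval = 2 * stats::pnorm(-abs(beta / se)),
        n = n, stringsAsFactors = FALSE),
        trait_name = trait, is_binary = binary,
        n_cases = n_cases, n_controls = n_controls)
    }
    exposure <- mk_table(bx, se_exp, truth$n_exp, "sim_exposure", FALSE, NULL, NULL)
    swap <- stats::runif(n_snp) < 0.3
    outcome <- mk_table(by, se_out, truth$n_out, "sim_outcome",
                        truth$outcome_binary,
                        if (truth$outcome_binary) truth$n_cases else NULL,
                        if (truth$outcome_binary) truth$n_out - truth$n_cases else NULL,
                        swap = swap)

    ld <- diag(1, n_snp)
    dimnames(ld) <- list(snp_id, snp_id)
    for (l in seq_len(n_locus)) {
      idx <- which(locus == l)
      ld[idx, idx] <- truth$within_block_r2
      diag(ld)[idx] <- 1
    }
    ld <- ld_matrix(ld, positions = pos)

    index_ids <- snp_id[is_index]
    n_conf <- round(truth$confounder_fraction * k)
    planted <- if (n_conf > 0) sort(sample(index_ids, n_conf)) else character(0)
    traits <- c("education", "smoking", "alcohol_intake", "socioeconomic_status")
    cat_df <- data.frame(snp_id = character(0), trait = character(0),
                         pval = numeric(0), stringsAsFactors = FALSE)
    if (length(planted)) {
      cat_df <- rbind(cat_df, data.frame(
        snp_id = planted,
        trait = sample(traits, length(planted), replace = TRUE),
        pval = 10^-stats::runif(length(planted), 9, 20),
        stringsAsFactors = FALSE))
    }
    # decoy sub-threshold entries: listed but never removed at 5e-8
    decoys <- setdiff(index_ids, planted)
    if (length(decoys) > 2) {
      decoys <- decoys[1:2]
      cat_df <- rbind(cat_df, data.frame(
        snp_id = decoys, trait = "height",
        pval = 10^-stats::runif(length(decoys), 4, 6),
        stringsAsFactors = FALSE))
    }
    catalog <- confounder_catalog(cat_df)

    echo <- truth
    echo$snp_id <- snp_id
    echo$gamma <- gamma
    echo$alpha <- alpha
    echo$instrument_ids <- index_ids
    echo$planted_confounders <- planted
    echo$swapped_in_outcome <- snp_id[swap]

    list(exposure = exposure, outcome = outcome, ld = ld,
         catalog = catalog, truth = echo)
  })
}

#' Simulate an already-harmonized instrument set
#'
#' Fast generator for estimator-level simulation studies: draws `k`
#' independent instruments from the same two-sample model as
#' [simulate_pair()] (no LD blocks, no null SNPs, no allele bookkeeping) and
#' returns a `harmonized_set` ready for the estimators.
#'
#' @param truth a [sim_truth()] (fields `ld_block_size`, `n_null`,
#'   `palindrome_frac`, `confounder_fraction` are ignored).
#' @return a `harmonized_set` with the per-SNP truth in attributes `gamma`
#'   and `alpha`.
#' @export
simulate_harmonized <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(truth$seed, {
    k <- truth$k_causal
    maf <- stats::runif(k, truth$maf_range[1], truth$maf_range[2])
    gamma <- stats::runif(k, truth$gamma_range[1], truth$gamma_range[2])
    alpha <- numeric(k)
    if (truth$pleiotropy_mode != "none" && k > 0) {
      n_pleio <- round(truth$pleiotropy_frac * k)
      idx <- sample.int(k, n_pleio)
      alpha[idx] <- switch(
        truth$pleiotropy_mode,
        balanced = stats::rnorm(n_pleio, 0, truth$pleiotropy_sd),
        directional = stats::rnorm(n_pleio, truth$pleiotropy_mean,
                                   truth$pleiotropy_sd),
        inside_violating = truth$pleiotropy_mean * gamma[idx] +
          stats::rnorm(n_pleio, 0, truth$pleiotropy_sd))
    }
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_exp)
    vfac <- if (truth$outcome_binary) {
      cr <- truth$n_cases / truth$n_out
      cr * (1 - cr)
    } else 1
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_out * vfac)
    bx <- stats::rnorm(k, gamma, se_exp)
    by <- stats::rnorm(k, truth$theta * gamma + alpha,
                       sqrt(se_out^2 + truth$tau2))
    hs <- harmonized_set(bx, se_exp, by, se_out, eaf = maf,
                         exposure = "sim_exposure", outcome = "sim_outcome",
                         n_exp = truth$n_exp, n_out = truth$n_out,
                         outcome_binary = truth$outcome_binary,
                         n_cases_out = if (truth$outcome_binary) truth$n_cases else NULL)
    attr(hs, "gamma") <- gamma
    attr(hs, "alpha") <- alpha
    hs
  })
}

#' Block-exchangeable phenotype correlation matrix
#'
#' Builds a correlation matrix from exchangeable blocks (each block of size
#' `b` with correlation `rho` has eigenvalues `1 + (b-1) rho` once and
#' `1 - rho` with multiplicity `b - 1`, so the effective number of tests has
#' a closed form), or a random positive-definite correlation matrix when
#' `blocks` is `NULL`.
#'
#' @param m number of phenotypes (used when `blocks` is `NULL`).
#' @param blocks list of `c(size, rho)` pairs; sizes must sum to the matrix
#'   dimension.
#' @param seed RNG seed for the random variant.
#' @return a correlation matrix.
#' @export
simulate_phenotype_corr <- function(m = NULL, blocks = NULL, seed = 1) {
  if (!is.null(blocks)) {
    mats <- lapply(blocks, function(bl) {
      size <- bl[1]; rho <- bl[2]
      mat <- matrix(rho, size, size)
      diag(mat) <- 1
      mat
    })
    total <- sum(vapply(mats, nrow, 1L))
    out <- matrix(0, total, total)
    at <- 0
    for (mat in mats) {
      idx <- at + seq_len(nrow(mat))
      out[idx, idx] <- mat
      at <- at + nrow(mat)
    }
    dimnames(out) <- list(paste0("pheno", seq_len(total)),
                          paste0("pheno", seq_len(total)))
    return(out)
  }
  stopifnot(!is.null(m), m >= 1)
  with_seed(seed, {
    x <- matrix(stats::rnorm(2 * m * m), nrow = 2 * m)
    out <- stats::cov2cor(crossprod(x))
    dimnames(out) <- list(paste0("pheno", seq_len(m)), paste0("pheno", seq_len(m)))
    out
  })
}

#' Write a simulated dataset in the dialects the readers consume
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `ld_matrix.tsv`,
#' `confounders.tsv` and a `truth.yaml` sidecar (seed and ground-truth
#' parameters) under `dir`.
#'
#' @param sim result of [simulate_pair()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld_matrix.tsv"))
  utils::write.table(as.data.frame(sim$catalog), file.path(dir, "confounders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- sim$truth
  meta$gamma <- as.numeric(meta$gamma)
  meta$alpha <- as.numeric(meta$alpha)
  class(meta) <- NULL
  yaml::write_yaml(meta, file.path(dir, "truth.yaml"))
  invisible(dir)
}
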