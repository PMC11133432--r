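# GWAS summary statistics: containers, I/O, validation, standardization,
# and exposure/outcome harmonization.

REQUIRED_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

DEFAULT_COLUMN_MAP <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                        effect_allele = "A1", other_allele = "A2",
                        eaf = "EAF", beta = "BETA", se = "SE",
                        pval = "P", n = "N")

#' Construct a validated GWAS summary-statistics table
#'
#' A `gwas_table` is a data.frame with one row per SNP and canonical columns
#' `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' Rows violating the per-record invariants (alleles single A/C/G/T and
#' distinct, `se > 0`, `pval` in (0,1], `eaf` in [0,1], finite `beta`,
#' positive `n`) are dropped and recorded in the drop log (see
#' [drop_log()]); lower-case alleles are upper-cased first, and
#' multi-character (indel) alleles are dropped with reason `indel`.
#'
#' @param df data.frame carrying the canonical columns.
#' @param trait_name trait label.
#' @param is_binary logical; is the trait a case/control phenotype
#'   (`beta` on the log-odds scale)?
#' @param n_cases,n_controls case and control counts for binary traits
#'   (optional; when both given they must sum to the record-level `n` unless
#'   record-level `n` overrides).
#' @return a `gwas_table` (data.frame subclass) with the drop log attached.
#' @export
gwas_table <- function(df, trait_name = "trait", is_binary = FALSE,
                       n_cases = NULL, n_controls = NULL) {
  miss <- setdiff(REQUIRED_COLS, names(df))
  if (length(miss)) {
    bimr_stop("config_error", "missing required column(s): %s",
              paste(miss, collapse = ", "))
  }
  df <- df[REQUIRED_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  out <- df[0, ]
  out <- add_drops(out, character(), "none")

  indel <- nchar(df$effect_allele) != 1L | nchar(df$other_allele) != 1L
  bad_allele <- !indel & (!(df$effect_allele %in% c("A", "C", "G", "T")) |
                          !(df$other_allele %in% c("A", "C", "G", "T")) |
                          df$effect_allele == df$other_allele)
  bad_se  <- !is.finite(df$se) | df$se <= 0
  bad_p   <- !is.finite(df$pval) | df$pval <= 0 | df$pval > 1
  bad_eaf <- !is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1
  bad_n   <- !is.finite(df$n) | df$n <= 0
  bad_beta <- !is.finite(df$beta)

  keep <- !(indel | bad_allele | bad_se | bad_p | bad_eaf | bad_n | bad_beta)
  dup <- duplicated(df$snp_id) & keep
  keep <- keep & !dup

  res <- df[keep, , drop = FALSE]
  rownames(res) <- NULL
  res <- add_drops(res, df$snp_id[indel], "indel")
  res <- add_drops(res, df$snp_id[bad_allele], "bad_allele")
  res <- add_drops(res, df$snp_id[bad_se & !indel & !bad_allele], "nonpositive_se")
  res <- add_drops(res, df$snp_id[bad_p], "bad_pval")
  res <- add_drops(res, df$snp_id[bad_eaf], "bad_eaf")
  res <- add_drops(res, df$snp_id[bad_n], "bad_n")
  res <- add_drops(res, df$snp_id[bad_beta], "nonfinite_beta")
  res <- add_drops(res, df$snp_id[dup], "duplicate_snp_id")

  attr(res, "trait_name") <- trait_name
  attr(res, "is_binary") <- isTRUE(is_binary)
  attr(res, "n_cases") <- n_cases
  attr(res, "n_controls") <- n_controls
  class(res) <- c("gwas_table", "data.frame")
  res
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics for '%s' (%s): %d SNPs, %d dropped on read\n",
              attr(x, "trait_name"),
              if (isTRUE(attr(x, "is_binary"))) "binary" else "continuous",
              nrow(x), nrow(drop_log(x))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a headered tab- or whitespace-delimited file and maps its columns to
#' the canonical schema. Invalid rows are dropped and logged (see
#' [gwas_table()]).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names to
#'   file column names; defaults to
#'   `c(snp_id="SNP", chrom="CHR", pos="BP", effect_allele="A1",
#'   other_allele="A2", eaf="EAF", beta="BETA", se="SE", pval="P", n="N")`.
#'   Partial maps are merged over the default.
#' @inheritParams gwas_table
#' @return a validated [gwas_table()].
#' @export
read_sumstats <- function(path, column_map = DEFAULT_COLUMN_MAP,
                          trait_name = basename(path), is_binary = FALSE,
                          n_cases = NULL, n_controls = NULL) {
  if (!file.exists(path)) bimr_stop("input_error", "file not found: %s", path)
  map <- DEFAULT_COLUMN_MAP
  map[names(column_map)] <- column_map
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) bimr_stop("input_error", "cannot parse %s: %s", path,
                                  conditionMessage(e)))
  if (nrow(raw) == 0L) bimr_stop("input_error", "empty summary-statistics file: %s", path)
  miss <- map[!(map %in% names(raw))]
  if (length(miss)) {
    bimr_stop("config_error", "column(s) not found in %s: %s", path,
              paste(sprintf("%s (for %s)", miss, names(miss)), collapse = ", "))
  }
  df <- raw[, unname(map)]
  names(df) <- names(map)
  gwas_table(df, trait_name = trait_name, is_binary = is_binary,
             n_cases = n_cases, n_controls = n_controls)
}

#' Write a GWAS summary-statistics table to a tab-delimited file
#'
#' @param table a [gwas_table()].
#' @param path output path.
#' @param column_map named map from canonical to output column names (the
#'   read default is reused so write/read round-trips).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path, column_map = DEFAULT_COLUMN_MAP) {
  map <- DEFAULT_COLUMN_MAP
  map[names(column_map)] <- column_map
  df <- as.data.frame(table)[REQUIRED_COLS]
  names(df) <- unname(map[REQUIRED_COLS])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize effect sizes to the per-SD unit-variance scale
#'
#' Replaces `beta` and `se` with the MAF- and sample-size-standardized values
#' \deqn{\beta = z / \sqrt{2 f (1-f) (n + z^2)}, \quad
#'       se = 1 / \sqrt{2 f (1-f) (n + z^2)}}
#' where \eqn{z = \beta/se} from the original data and
#' \eqn{f = \min(eaf, 1-eaf)} is the minor allele frequency. The z-score, and
#' therefore the p-value, of every record is unchanged; records with
#' `eaf` of exactly 0 or 1 are dropped (the scale factor degenerates).
#'
#' @param table a [gwas_table()].
#' @return the table with standardized `beta`/`se`, drop log extended.
#' @export
standardize_effects <- function(table) {
  stopifnot(inherits(table, "gwas_table"))
  bad <- table$eaf <= 0 | table$eaf >= 1
  out <- table[!bad, , drop = FALSE]
  z <- out$beta / out$se
  f <- pmin(out$eaf, 1 - out$eaf)
  denom <- sqrt(2 * f * (1 - f) * (out$n + z^2))
  out$beta <- z / denom
  out$se <- 1 / denom
  rownames(out) <- NULL
  out <- keep_gwas_attrs(out, table)
  attr(out, "drops") <- attr(table, "drops")
  out <- add_drops(out, table$snp_id[bad], "degenerate_eaf")
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the SNPs shared by two GWAS tables onto the exposure's allele
#' orientation. Outcome records whose alleles are swapped relative to the
#' exposure are flipped (alleles exchanged, `beta` negated, `eaf` replaced by
#' `1 - eaf`); palindromic SNPs (A/T or C/G) with minor allele frequency
#' above `0.5 - palindrome_maf_window` are removed as strand-ambiguous, and
#' palindromic SNPs that are kept are oriented by effect-allele-frequency
#' concordance (if exposure and outcome frequencies fall on opposite sides of
#' 0.5 the outcome is flipped). SNPs whose allele pairs cannot be reconciled
#' by an allele swap are dropped; no frequency-based strand correction is
#' attempted for them. Every removal is logged with a reason code.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param palindrome_maf_window tolerance around MAF 0.5 within which
#'   palindromic SNPs are considered ambiguous (default 0.08: removed when
#'   MAF > 0.42).
#' @return a `harmonized_set`: data.frame with columns `snp_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta_exp, se_exp, pval_exp, eaf_out,
#'   beta_out, se_out, pval_out`, and attributes `exposure`, `outcome`,
#'   `n_exp`, `n_out`, `outcome_binary`, `n_cases_out`, `n_controls_out`.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_window = 0.08) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  if (palindrome_maf_window < 0 || palindrome_maf_window >= 0.5) {
    bimr_stop("config_error", "palindrome_maf_window must be in [0, 0.5)")
  }
  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(common) == 0L) {
    bimr_stop("empty_overlap", "no SNPs shared between '%s' and '%s'",
              attr(exposure, "trait_name"), attr(outcome, "trait_name"))
  }
  ex <- exposure[match(common, exposure$snp_id), ]
  ou <- outcome[match(common, outcome$snp_id), ]

  direct  <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  # for palindromic SNPs direct and swapped are textually distinct but strand-
  # ambiguous; ambiguity is resolved below by MAF window + EAF concordance
  mismatch <- !(direct | swapped)

  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  eaf_out <- ifelse(swapped, 1 - ou$eaf, ou$eaf)

  # palindromic handling
  maf_exp <- pmin(ex$eaf, 1 - ex$eaf)
  ambiguous <- palin & maf_exp > (0.5 - palindrome_maf_window)
  flip_pal <- palin & !ambiguous & !mismatch &
    ((ex$eaf < 0.5) != (eaf_out < 0.5))
  beta_out <- ifelse(flip_pal, -beta_out, beta_out)
  eaf_out <- ifelse(flip_pal, 1 - eaf_out, eaf_out)

  keep <- !mismatch & !ambiguous
  hs <- data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = ex$eaf, beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
    eaf_out = eaf_out, beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(hs) <- NULL

  hs <- add_drops(hs, ex$snp_id[mismatch], "allele_mismatch")
  hs <- add_drops(hs, ex$snp_id[ambiguous & !mismatch], "palindrome_ambiguous")
  dropped_exp <- setdiff(exposure$snp_id, common)
  dropped_out <- setdiff(outcome$snp_id, common)
  hs <- add_drops(hs, dropped_exp, "absent_in_outcome")
  hs <- add_drops(hs, dropped_out, "absent_in_exposure")

  attr(hs, "exposure") <- attr(exposure, "trait_name")
  attr(hs, "outcome") <- attr(outcome, "trait_name")
  attr(hs, "n_exp") <- stats::median(exposure$n)
  attr(hs, "n_out") <- stats::median(outcome$n)
  attr(hs, "outcome_binary") <- isTRUE(attr(outcome, "is_binary"))
  attr(hs, "n_cases_out") <- attr(outcome, "n_cases")
  attr(hs, "n_controls_out") <- attr(outcome, "n_controls")
  class(hs) <- c("harmonized_set", "data.frame")
  hs
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where exposure
#' and outcome effects are already on a shared allele orientation.
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned per-SNP effects and SEs.
#' @param snp_id SNP identifiers (generated when omitted).
#' @param eaf effect-allele frequency on the shared orientation.
#' @param exposure,outcome trait names.
#' @param n_exp,n_out GWAS sample sizes.
#' @param outcome_binary logical.
#' @param n_cases_out,n_controls_out case/control counts for binary outcomes.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = sprintf("rs%06d", seq_along(beta_exp)),
                           eaf = rep(0.25, length(beta_exp)),
                           exposure = "exposure", outcome = "outcome",
                           n_exp = NA_real_, n_out = NA_real_,
                           outcome_binary = FALSE,
                           n_cases_out = NULL, n_controls_out = NULL) {
  stopifnot(all(se_exp > 0), all(se_out > 0),
            length(beta_exp) == length(beta_out))
  hs <- data.frame(snp_id = snp_id, chrom = "1",
                   pos = seq_along(beta_exp) * 1e6,
                   effect_allele = "A", other_allele = "G",
                   eaf = eaf, beta_exp = beta_exp, se_exp = se_exp,
                   pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
                   eaf_out = eaf, beta_out = beta_out, se_out = se_out,
                   pval_out = 2 * stats::pnorm(-abs(beta_out / se_out)),
                   stringsAsFactors = FALSE)
  attr(hs, "exposure") <- exposure
  attr(hs, "outcome") <- outcome
  attr(hs, "n_exp") <- n_exp
  attr(hs, "n_out") <- n_out
  attr(hs, "outcome_binary") <- outcome_binary
  attr(hs, "n_cases_out") <- n_cases_out
  attr(hs, "n_controls_out") <- n_controls_out
  class(hs) <- c("harmonized_set", "data.frame")
  hs
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d SNPs\n",
              attr(x, "exposure"), attr(x, "outcome"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
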