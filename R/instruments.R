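# Instrument selection: significance filtering, greedy LD clumping,
# catalog- and region-based exclusion, and instrument-strength statistics.

#' Construct a validated LD matrix
#'
#' @param r2 square numeric matrix of squared correlations, row/column names
#'   set to SNP identifiers.
#' @param positions optional base-pair positions aligned to the SNP ids.
#' @return an `ld_matrix` (matrix subclass).
#' @export
ld_matrix <- function(r2, positions = NULL) {
  r2 <- as.matrix(r2)
  ids <- rownames(r2)
  if (is.null(ids) || is.null(colnames(r2)) || !identical(ids, colnames(r2))) {
    bimr_stop("input_error", "LD matrix must carry identical row and column SNP ids")
  }
  if (nrow(r2) != ncol(r2)) bimr_stop("input_error", "LD matrix must be square")
  if (max(abs(r2 - t(r2))) > 1e-8) bimr_stop("input_error", "LD matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) bimr_stop("input_error", "LD matrix diagonal must be 1")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) {
    bimr_stop("input_error", "LD r2 entries must lie in [0, 1]")
  }
  r2[r2 < 0] <- 0; r2[r2 > 1] <- 1
  attr(r2, "positions") <- positions
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read an LD matrix file (square or long dialect)
#'
#' Accepts either a headered square matrix whose first column holds SNP ids,
#' or a long-format table with columns `snp_a`, `snp_b`, `r2` (missing pairs
#' are taken as r2 = 0).
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) bimr_stop("input_error", "file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(raw$snp_a, ids); j <- match(raw$snp_b, ids)
    m[cbind(i, j)] <- raw$r2
    m[cbind(j, i)] <- raw$r2
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_matrix(m)
}

#' Write an LD matrix (square or long dialect)
#'
#' The long dialect stores the unit diagonal plus nonzero upper-triangle
#' entries only, which is compact for block-diagonal references; absent
#' pairs read back as r2 = 0.
#'
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @param format `"square"` (default) or `"long"`.
#' @export
write_ld_matrix <- function(ld, path, format = c("square", "long")) {
  format <- match.arg(format)
  m <- unclass(ld)
  attr(m, "positions") <- NULL
  if (format == "square") {
    df <- data.frame(snp_id = rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
  } else {
    ids <- rownames(m)
    ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    df <- rbind(
      data.frame(snp_a = ids, snp_b = ids, r2 = 1, stringsAsFactors = FALSE),
      data.frame(snp_a = ids[ut[, 1]], snp_b = ids[ut[, 2]], r2 = m[ut],
                 stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounder/outcome association catalog
#'
#' Tab-delimited file with columns `snp_id`, `trait`, `pval`; the file-based
#' stand-in for live trait-association database queries.
#'
#' @param path file path.
#' @return data.frame of class `confounder_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) bimr_stop("input_error", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  confounder_catalog(df)
}

#' Construct a confounder/outcome association catalog
#' @param df data.frame with columns `snp_id`, `trait`, `pval`.
#' @return data.frame of class `confounder_catalog`.
#' @export
confounder_catalog <- function(df) {
  miss <- setdiff(c("snp_id", "trait", "pval"), names(df))
  if (length(miss)) bimr_stop("config_error", "catalog missing column(s): %s",
                              paste(miss, collapse = ", "))
  if (any(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1)) {
    bimr_stop("input_error", "catalog p-values must lie in (0, 1]")
  }
  df <- df[c("snp_id", "trait", "pval")]
  df$snp_id <- as.character(df$snp_id)
  df$trait <- as.character(df$trait)
  class(df) <- c("confounder_catalog", "data.frame")
  df
}

#' Keep genome-wide significant records
#'
#' @param table a [gwas_table()].
#' @param p_threshold significance level; records with `pval < p_threshold`
#'   are retained in their original order (default 5e-8).
#' @return filtered `gwas_table`.
#' @export
filter_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "gwas_table"))
  if (p_threshold <= 0 || p_threshold > 1) {
    bimr_stop("config_error", "p_threshold must be in (0, 1]")
  }
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_gwas_attrs(out, table)
  attr(out, "drops") <- attr(table, "drops")
  add_drops(out, table$snp_id[!keep], "above_p_threshold",
            sprintf("threshold=%g", p_threshold))
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly promotes the remaining SNP with the smallest p-value to index
#' SNP and discards all remaining SNPs on the same chromosome within
#' `window_kb` kilobases that have squared correlation `r2 >= r2_max` with
#' it. P-value ties are broken by smaller position, then lexicographic SNP
#' id, so output is deterministic. The retained set is pairwise independent
#' under the rule.
#'
#' @param table a [gwas_table()].
#' @param ld an [ld_matrix()] covering every SNP in `table`.
#' @param r2_max LD threshold (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return clumped `gwas_table`.
#' @export
clump <- function(table, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "gwas_table"))
  if (r2_max < 0 || r2_max > 1) bimr_stop("config_error", "r2_max must be in [0, 1]")
  if (window_kb <= 0) bimr_stop("config_error", "window_kb must be positive")
  missing_ld <- setdiff(table$snp_id, rownames(ld))
  if (length(missing_ld)) {
    bimr_stop("config_error", "SNP(s) missing from LD matrix: %s",
              paste(utils::head(missing_ld, 5), collapse = ", "))
  }
  if (nrow(table) == 0L) return(table)

  ord <- order(table$pval, table$pos, table$snp_id)
  ids <- table$snp_id[ord]
  chrom <- table$chrom[ord]
  pos <- table$pos[ord]
  alive <- rep(TRUE, length(ids))
  kept <- character(0)
  dropped_by <- character(0); dropped_id <- character(0)
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    kept <- c(kept, ids[i])
    if (i < length(ids)) {
      later <- which(alive & seq_along(ids) > i)
      if (length(later)) {
        near <- chrom[later] == chrom[i] &
          abs(pos[later] - pos[i]) <= window_kb * 1000
        linked <- unclass(ld)[ids[later], ids[i]] >= r2_max
        kill <- later[near & linked]
        if (length(kill)) {
          alive[kill] <- FALSE
          dropped_id <- c(dropped_id, ids[kill])
          dropped_by <- c(dropped_by, rep(ids[i], length(kill)))
        }
      }
    }
  }
  keep <- table$snp_id %in% kept
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_gwas_attrs(out, table)
  attr(out, "drops") <- attr(table, "drops")
  add_drops(out, dropped_id, "clumped", sprintf("index=%s", dropped_by))
}

#' Remove SNPs associated with catalog traits below a p-value threshold
#'
#' Serves both confounder-associated and outcome-associated SNP removal:
#' a record is removed when its id appears in the catalog with
#' `pval < p_threshold` for any trait; each triggering trait is logged.
#'
#' @param table a [gwas_table()].
#' @param catalog a [confounder_catalog()].
#' @param p_threshold association threshold (default 5e-8).
#' @return filtered `gwas_table`.
#' @export
exclude_by_catalog <- function(table, catalog, p_threshold = 5e-8) {
  stopifnot(inherits(table, "gwas_table"))
  hits <- catalog[catalog$pval < p_threshold & catalog$snp_id %in% table$snp_id, ,
                  drop = FALSE]
  keep <- !(table$snp_id %in% hits$snp_id)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_gwas_attrs(out, table)
  attr(out, "drops") <- attr(table, "drops")
  add_drops(out, hits$snp_id, "catalog_association",
            sprintf("trait=%s;p=%g", hits$trait, hits$pval))
}

#' Remove SNPs inside a genomic region (closed interval)
#'
#' Default use is exclusion of the extended major histocompatibility complex
#' (MHC), chr6:28,477,797-33,448,354 on GRCh37.
#'
#' @param table a [gwas_table()].
#' @param chrom chromosome label.
#' @param start,end interval bounds in base pairs, inclusive.
#' @return filtered `gwas_table`.
#' @export
exclude_region <- function(table, chrom = "6", start = 28477797, end = 33448354) {
  stopifnot(inherits(table, "gwas_table"))
  if (start >= end) bimr_stop("config_error", "region start must be < end")
  inside <- table$chrom == as.character(chrom) & table$pos >= start & table$pos <= end
  out <- table[!inside, , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_gwas_attrs(out, table)
  attr(out, "drops") <- attr(table, "drops")
  add_drops(out, table$snp_id[inside], "in_excluded_region",
            sprintf("%s:%d-%d", chrom, start, end))
}

#' Instrument-strength statistics (variance explained and F)
#'
#' Per instrument, the variance in the exposure explained is
#' \deqn{R^2_j = \beta_j^2 / (\beta_j^2 + se_j^2 n)} and the set-level
#' \eqn{R^2} is the sum over instruments. The set-level F statistic is
#' \deqn{F = R^2 (n - k - 1) / ((1 - R^2) k)} with `k` instruments and `n`
#' the exposure GWAS sample size; per-SNP F statistics use the same formula
#' with `k = 1`. F below 10 flags a weak instrument set.
#'
#' @param instruments a [gwas_table()] of selected instruments (k >= 1);
#'   sample size is taken from the records, which must agree.
#' @return object of class `instrument_stats`: list with `k`, `n`,
#'   `per_snp_r2`, `per_snp_f`, `r2_total`, `f_stat`, `weak`.
#' @export
instrument_strength <- function(instruments) {
  stopifnot(inherits(instruments, "gwas_table"))
  k <- nrow(instruments)
  if (k < 1) bimr_stop("input_error", "instrument_strength needs k >= 1")
  n <- unique(instruments$n)
  if (length(n) != 1L) {
    bimr_stop("input_error", "instrument sample sizes must be identical (exposure GWAS n)")
  }
  per_snp_r2 <- instruments$beta^2 / (instruments$beta^2 + instruments$se^2 * n)
  r2_total <- sum(per_snp_r2)
  if (r2_total >= 1) {
    bimr_stop("numerical_error", "summed R^2 >= 1; instruments degenerate")
  }
  f_stat <- r2_total * (n - k - 1) / ((1 - r2_total) * k)
  per_snp_f <- per_snp_r2 * (n - 2) / (1 - per_snp_r2)
  structure(list(k = k, n = n,
                 per_snp_r2 = stats::setNames(per_snp_r2, instruments$snp_id),
                 per_snp_f = stats::setNames(per_snp_f, instruments$snp_id),
                 r2_total = r2_total, f_stat = f_stat,
                 weak = f_stat < 10),
            class = "instrument_stats")
}

#' @export
print.instrument_stats <- function(x, ...) {
  cat(sprintf("Instrument set: k = %d, R^2 = %.4g, F = %.4g%s\n",
              x$k, x$r2_total, x$f_stat,
              if (x$weak) " (WEAK: F < 10)" else ""))
  invisible(x)
}
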