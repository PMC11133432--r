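# Multiple-testing correction via matrix spectral decomposition (matSpD)
# and statistical power for two-sample MR.

#' Effective number of independent tests by matrix spectral decomposition
#'
#' Eigen-decomposes a phenotype correlation matrix and summarizes the
#' eigenvalue spectrum as an effective number of independent variables.
#' Two variants are provided: `nyholt`,
#' \deqn{M_{eff} = 1 + (M-1)(1 - Var(\lambda)/M)} (sample variance of the
#' eigenvalues, possibly non-integer), and `li_ji`,
#' \deqn{M_{eff} = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i -
#' \lfloor\lambda_i\rfloor) ].}
#'
#' @param corr symmetric correlation matrix with unit diagonal, positive
#'   semi-definite within tolerance.
#' @param method `"nyholt"` (default) or `"li_ji"`.
#' @param base_alpha familywise level to divide by M_eff (default 0.05).
#' @return object of class `correction_result`: list with `m`,
#'   `eigenvalues`, `m_eff`, `m_eff_nyholt`, `m_eff_li_ji`, `method`,
#'   `alpha_adjusted`.
#' @export
matspd_meff <- function(corr, method = c("nyholt", "li_ji"), base_alpha = 0.05) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) bimr_stop("input_error", "correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) bimr_stop("input_error", "correlation matrix must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) bimr_stop("input_error", "correlation matrix diagonal must be 1")
  m <- nrow(corr)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6 * m) {
    bimr_stop("input_error", "correlation matrix is not positive semi-definite")
  }
  lambda <- pmax(lambda, 0)
  m_eff_nyholt <- if (m == 1) 1 else 1 + (m - 1) * (1 - stats::var(lambda) / m)
  m_eff_li_ji <- sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
  m_eff <- if (method == "nyholt") m_eff_nyholt else m_eff_li_ji
  structure(list(m = m, eigenvalues = lambda, m_eff = m_eff,
                 m_eff_nyholt = m_eff_nyholt, m_eff_li_ji = m_eff_li_ji,
                 method = method, alpha_adjusted = base_alpha / m_eff),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("matSpD: M = %d, M_eff = %.2f (%s), adjusted alpha = %.3g\n",
              x$m, x$m_eff, x$method, x$alpha_adjusted))
  invisible(x)
}

#' Study-wide corrected significance thresholds
#'
#' Bonferroni threshold over the effective number of phenotypes, the number
#' of diseases, and the number of analysis directions:
#' `base_alpha / (m_eff * n_diseases * n_directions)`; the nominal
#' (suggestive) threshold is passed through unchanged.
#'
#' @param m_eff effective number of independent phenotypes (may be
#'   non-integer).
#' @param n_diseases number of disease traits tested.
#' @param n_directions number of analysis directions (2 for bidirectional).
#' @param base_alpha familywise level (default 0.05).
#' @param nominal_alpha suggestive threshold (default 1e-4).
#' @return list with `bonferroni_p` and `nominal_p`.
#' @export
corrected_thresholds <- function(m_eff, n_diseases = 7, n_directions = 2,
                                 base_alpha = 0.05, nominal_alpha = 1e-4) {
  if (any(c(m_eff, n_diseases, n_directions, base_alpha, nominal_alpha) <= 0)) {
    bimr_stop("config_error", "all threshold inputs must be positive")
  }
  list(bonferroni_p = base_alpha / (m_eff * n_diseases * n_directions),
       nominal_p = nominal_alpha)
}

#' Statistical power of a two-sample MR analysis
#'
#' Normal-approximation power for the IVW estimate. For a binary outcome,
#' \deqn{power = \Phi(\sqrt{n \cdot R^2 \cdot r(1-r)} \; |\log OR| -
#' z_{1-\alpha/2})} with `n` the outcome GWAS size, `R^2` the variance of
#' the exposure explained by the instruments and `r` the case ratio; for a
#' continuous outcome the `r(1-r)` factor is dropped and the effect is in
#' SD-per-SD units.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param r2 variance explained by the instruments, in (0,1).
#' @param effect causal effect: log-OR per SD of exposure (binary) or SD per
#'   SD (continuous).
#' @param case_ratio cases/(cases+controls) for binary outcomes; `NULL` for
#'   continuous.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in [0, 1].
#' @export
mr_power <- function(n_outcome, r2, effect, case_ratio = NULL, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) bimr_stop("config_error", "r2 must be in (0, 1)")
  if (!is.null(case_ratio) && (case_ratio <= 0 || case_ratio >= 1)) {
    bimr_stop("config_error", "case_ratio must be in (0, 1)")
  }
  zq <- stats::qnorm(1 - alpha / 2)
  ncp <- if (is.null(case_ratio)) {
    sqrt(n_outcome * r2) * abs(effect)
  } else {
    sqrt(n_outcome * r2 * case_ratio * (1 - case_ratio)) * abs(effect)
  }
  stats::pnorm(ncp - zq)
}
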