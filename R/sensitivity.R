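# Heterogeneity and pleiotropy diagnostics: Cochran's Q, Egger intercept,
# MR-PRESSO (global / outlier / distortion), leave-one-out.

#' Cochran's Q heterogeneity test
#'
#' \deqn{Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2} over per-SNP Wald
#' ratios \eqn{\hat\beta_j = beta_{out,j}/beta_{exp,j}} with first-order
#' weights \eqn{w_j = (beta_{exp,j}/se_{out,j})^2}; the p-value is the
#' chi-square upper tail with k-1 degrees of freedom. Setting
#' `second_order = TRUE` uses modified weights that also carry the exposure
#' sampling variance.
#'
#' @param data a `harmonized_set` with k >= 2.
#' @param second_order use modified second-order weights (default FALSE).
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(data, second_order = FALSE) {
  check_hs(data, 2L, "cochran_q")
  ratios <- data$beta_out / data$beta_exp
  w <- if (second_order) {
    1 / (data$se_out^2 / data$beta_exp^2 +
         data$beta_out^2 * data$se_exp^2 / data$beta_exp^4)
  } else {
    (data$beta_exp / data$se_out)^2
  }
  est <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - est)^2)
  df <- nrow(data) - 1L
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression (see [mr_egger()]) estimates the
#' average direct (pleiotropic) effect of the instruments; a two-sided
#' p-value tests whether it differs from zero.
#'
#' @param data a `harmonized_set` with k >= 3.
#' @param use_t t- rather than normal quantiles.
#' @return list with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(data, use_t = FALSE) {
  res <- mr_egger(data, use_t = use_t)
  list(intercept = res$aux$intercept, se = res$aux$intercept_se,
       pval = res$aux$intercept_pval)
}

loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed weighted residual sum of squares
#' \eqn{RSS = \sum_j w_j (beta_{out,j} - \hat\beta_{(-j)} beta_{exp,j})^2}
#' (weights `1/se_out^2`, \eqn{\hat\beta_{(-j)}} the leave-one-out IVW
#' slope) is compared against `n_sim` parametric simulations drawing
#' `beta_exp* ~ N(beta_exp, se_exp^2)` and
#' `beta_out* ~ N(beta_hat_(-j) * beta_exp, se_out^2)`; the empirical
#' p-value uses the +1 correction. Outlier test: each SNP's observed
#' weighted residual is compared to its simulated distribution,
#' Bonferroni-adjusted by k against `outlier_alpha`. Distortion test (only
#' when outliers are found): the relative change between the full-set and
#' outlier-removed IVW estimates is compared with the distribution obtained
#' by removing random inlier subsets of the same size.
#'
#' @param data a `harmonized_set` with k >= 4.
#' @param n_sim parametric simulations (>= 100, default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param outlier_alpha familywise level for the outlier test (default 0.05).
#' @return list with `global_pval`, `outliers` (data.frame snp_id, pval),
#'   `distortion_pval` (NA when no outliers), `rss_obs`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  check_hs(data, 4L, "mr_presso")
  if (n_sim < 100) bimr_stop("config_error", "mr_presso needs n_sim >= 100")
  bx <- data$beta_exp; by <- data$beta_out
  sx <- data$se_exp; sy <- data$se_out
  k <- length(bx)
  w <- 1 / sy^2
  b_loo <- loo_slopes(bx, by, w)
  resid_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(resid_obs)

  sim <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
    bys <- matrix(stats::rnorm(k * n_sim, b_loo * bx, sy), nrow = k)
    sxy <- colSums(w * bxs * bys)
    sxx <- colSums(w * bxs^2)
    b_loo_s <- (rep(sxy, each = k) - w * bxs * bys) /
               (rep(sxx, each = k) - w * bxs^2)
    resid_s <- w * (bys - b_loo_s * bxs)^2
    list(rss = colSums(resid_s), resid = resid_s)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + rowSums(sim$resid >= resid_obs)) / (n_sim + 1)
  is_out <- outlier_p < outlier_alpha / k
  outliers <- data.frame(snp_id = data$snp_id[is_out],
                         pval = outlier_p[is_out],
                         stringsAsFactors = FALSE)

  distortion_pval <- NA_real_
  distortion <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2) {
    full <- ivw_fit(bx, by, sy)$estimate
    clean <- ivw_fit(bx[!is_out], by[!is_out], sy[!is_out])$estimate
    distortion <- (clean - full) / abs(full)
    n_out <- sum(is_out)
    inl <- which(!is_out)
    if (length(inl) - n_out >= 2) {
      d_null <- with_seed(child_seed(seed, 7L), {
        vapply(seq_len(n_sim), function(b) {
          rm_idx <- sample(inl, n_out)
          sub <- setdiff(seq_len(k), rm_idx)
          (ivw_fit(bx[sub], by[sub], sy[sub])$estimate - full) / abs(full)
        }, numeric(1))
      })
      distortion_pval <- (1 + sum(abs(d_null) >= abs(distortion))) / (n_sim + 1)
    }
  }
  list(global_pval = global_pval, outliers = outliers,
       distortion = distortion, distortion_pval = distortion_pval,
       rss_obs = rss_obs, n_sim = n_sim, seed = seed)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator k times, each time excluding one SNP. The
#' significance flag is set when the all-SNP estimate and any left-out
#' estimate fall on opposite sides of the significance threshold.
#'
#' @param data a `harmonized_set` with k >= 3.
#' @param sig_level p-value threshold used for the flag (default 1e-4, the
#'   nominal level of the pipeline).
#' @return list with `loo` (data.frame: snp_left_out, estimate, se, ci_low,
#'   ci_high, pval) and `loo_flag`.
#' @export
leave_one_out <- function(data, sig_level = 1e-4) {
  check_hs(data, 3L, "leave_one_out")
  k <- nrow(data)
  full <- mr_ivw(data)
  rows <- lapply(seq_len(k), function(j) {
    fit <- ivw_fit(data$beta_exp[-j], data$beta_out[-j], data$se_out[-j])
    p <- 2 * stats::pnorm(-abs(fit$estimate / fit$se))
    data.frame(snp_left_out = data$snp_id[j], estimate = fit$estimate,
               se = fit$se, ci_low = fit$estimate - 1.96 * fit$se,
               ci_high = fit$estimate + 1.96 * fit$se, pval = p,
               stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  full_sig <- full$pval < sig_level
  loo_flag <- any((loo$pval < sig_level) != full_sig)
  list(loo = loo, loo_flag = loo_flag)
}

#' Run the full sensitivity battery for one exposure-outcome pair
#'
#' Cochran's Q (k >= 2), Egger intercept (k >= 3), MR-PRESSO (k >= 4) and
#' leave-one-out (k >= 3); diagnostics whose instrument requirement is not
#' met are reported as NA.
#'
#' @param data a `harmonized_set`.
#' @param n_sim,seed,outlier_alpha MR-PRESSO controls.
#' @param sig_level leave-one-out significance threshold.
#' @return object of class `sensitivity_report` (list).
#' @export
run_sensitivity <- function(data, n_sim = 1000, seed = 1, outlier_alpha = 0.05,
                            sig_level = 1e-4) {
  k <- nrow(data)
  report <- list(k = k,
              q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_pval = NA_real_,
              presso_global_pval = NA_real_, presso_outliers = character(0),
              presso_distortion_pval = NA_real_,
              loo = NULL, loo_flag = NA)
  if (k >= 2) {
    q <- cochran_q(data)
    report[c("q_stat", "q_df", "q_pval")] <- q
  }
  if (k >= 3) {
    eg <- egger_intercept_test(data)
    report$egger_intercept <- eg$intercept
    report$egger_intercept_se <- eg$se
    report$egger_intercept_pval <- eg$pval
    loo <- leave_one_out(data, sig_level = sig_level)
    report$loo <- loo$loo
    report$loo_flag <- loo$loo_flag
  }
  if (k >= 4) {
    pr <- mr_presso(data, n_sim = n_sim, seed = seed,
                    outlier_alpha = outlier_alpha)
    report$presso_global_pval <- pr$global_pval
    report$presso_outliers <- pr$outliers$snp_id
    report$presso_distortion_pval <- pr$distortion_pval
  }
  class(report) <- "sensitivity_report"
  report
}

#' Serialize a sensitivity report as a long table
#'
#' @param report a `sensitivity_report`.
#' @param exposure,outcome trait labels for the key columns.
#' @return data.frame with columns exposure, outcome, diagnostic, value.
#' @export
sensitivity_long <- function(report, exposure = "exposure", outcome = "outcome") {
  vals <- c(q_stat = report$q_stat, q_df = report$q_df, q_pval = report$q_pval,
            egger_intercept = report$egger_intercept,
            egger_intercept_se = report$egger_intercept_se,
            egger_intercept_pval = report$egger_intercept_pval,
            presso_global_pval = report$presso_global_pval,
            presso_n_outliers = length(report$presso_outliers),
            presso_distortion_pval = report$presso_distortion_pval,
            loo_flag = as.numeric(report$loo_flag))
  data.frame(exposure = exposure, outcome = outcome,
             diagnostic = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}
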