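# Causal-effect estimators for two-sample MR on a harmonized set.
#
# All multi-SNP estimators treat the per-SNP exposure effects beta_exp as
# fixed regressors and model beta_out; SEs use the multiplicative
# random-effects convention (residual scale never shrunk below the
# fixed-effect model).

new_mr_result <- function(method, estimate, se, pval, k, aux = list(),
                          ci_level = 0.95, binary = FALSE) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- estimate - zq * se
  ci_high <- estimate + zq * se
  res <- list(method = method, estimate = estimate, se = se,
              ci_low = ci_low, ci_high = ci_high, pval = pval, k = k,
              aux = aux)
  if (binary) {
    res$or <- exp(estimate)
    res$or_ci_low <- exp(ci_low)
    res$or_ci_high <- exp(ci_high)
  }
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$k))
  if (!is.null(x$or)) {
    cat(sprintf("  OR %.3g (95%% CI %.3g-%.3g)\n", x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, k = x$k, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = if (is.null(x$or)) NA_real_ else x$or,
             or_ci_low = if (is.null(x$or_ci_low)) NA_real_ else x$or_ci_low,
             or_ci_high = if (is.null(x$or_ci_high)) NA_real_ else x$or_ci_high,
             egger_intercept = if (is.null(x$aux$intercept)) NA_real_ else x$aux$intercept,
             egger_intercept_se = if (is.null(x$aux$intercept_se)) NA_real_ else x$aux$intercept_se,
             egger_intercept_pval = if (is.null(x$aux$intercept_pval)) NA_real_ else x$aux$intercept_pval,
             raps_tau2 = if (is.null(x$aux$tau2)) NA_real_ else x$aux$tau2,
             stringsAsFactors = FALSE)
}

check_hs <- function(data, k_min, method) {
  stopifnot(inherits(data, "harmonized_set"))
  if (nrow(data) < k_min) {
    bimr_stop("insufficient_instruments", "%s requires k >= %d (got %d)",
              method, k_min, nrow(data))
  }
  invisible(nrow(data))
}

is_binary_outcome <- function(data) isTRUE(attr(data, "outcome_binary"))

# Fast closed-form weighted regression through the origin with multiplicative
# random effects; shared by mr_ivw, leave-one-out and MR-PRESSO internals.
ivw_fit <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  k <- length(bx)
  if (k > 1) {
    sigma2 <- sum(w * (by - est * bx)^2) / (k - 1)
    sigma2 <- max(sigma2, 1)  # multiplicative RE floor at the fixed-effect model
  } else {
    sigma2 <- 1
  }
  se <- sqrt(sigma2 / sxx)
  list(estimate = est, se = se, sigma2 = sigma2)
}

# Weighted regression with intercept, instruments oriented to bx >= 0.
egger_fit <- function(bx, by, se_out) {
  flip <- bx < 0
  bx <- abs(bx); by <- ifelse(flip, -by, by)
  if (max(bx) - min(bx) < 1e-12 * max(abs(bx), 1)) {
    bimr_stop("numerical_error", "Egger slope unidentified: all beta_exp equal")
  }
  w <- 1 / se_out^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  k <- length(bx)
  resid <- by - intercept - slope * bx
  sigma2 <- max(sum(w * resid^2) / (k - 2), 1)
  se_slope <- sqrt(sigma2 * sw / det)
  se_intercept <- sqrt(sigma2 * swxx / det)
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept, sigma2 = sigma2,
       df = k - 2)
}

#' Wald ratio estimator (single instrument)
#'
#' Causal estimate `beta_out / beta_exp` with first-order delta-method
#' standard error `se_out / |beta_exp|`.
#'
#' @param data a `harmonized_set` with exactly one SNP.
#' @return an `mr_result`.
#' @export
mr_wald_ratio <- function(data) {
  stopifnot(inherits(data, "harmonized_set"))
  if (nrow(data) != 1L) {
    bimr_stop("insufficient_instruments", "wald_ratio requires exactly one SNP")
  }
  if (data$beta_exp == 0) {
    bimr_stop("numerical_error", "wald_ratio undefined: beta_exp = 0")
  }
  est <- data$beta_out / data$beta_exp
  se <- data$se_out / abs(data$beta_exp)
  p <- 2 * stats::pnorm(-abs(est / se))
  new_mr_result("wald_ratio", est, se, p, 1L, binary = is_binary_outcome(data))
}

#' Inverse-variance weighted estimator with multiplicative random effects
#'
#' Weighted least-squares regression of `beta_out` on `beta_exp` through the
#' origin with weights `1/se_out^2` — equivalently the
#' `(beta_exp/se_out)^2`-weighted mean of per-SNP Wald ratios. The standard
#' error is scaled by the residual standard deviation (multiplicative random
#' effects) but never below the fixed-effect value.
#'
#' @param data a `harmonized_set` with k >= 2.
#' @return an `mr_result`.
#' @export
mr_ivw <- function(data) {
  check_hs(data, 2L, "ivw")
  fit <- ivw_fit(data$beta_exp, data$beta_out, data$se_out)
  p <- 2 * stats::pnorm(-abs(fit$estimate / fit$se))
  new_mr_result("ivw", fit$estimate, fit$se, p, nrow(data),
                aux = list(sigma2 = fit$sigma2),
                binary = is_binary_outcome(data))
}

#' MR-Egger regression
#'
#' Weighted least-squares of `beta_out` on `beta_exp` with an intercept
#' (weights `1/se_out^2`, multiplicative random-effects scaling as in
#' [mr_ivw()]). Instruments are oriented so every `beta_exp` is
#' non-negative before fitting, which gives the intercept its directional-
#' pleiotropy interpretation. The intercept, its SE and p-value are carried
#' in `aux`.
#'
#' @param data a `harmonized_set` with k >= 3.
#' @param use_t use t-distribution (df k-2) rather than normal p-values.
#' @return an `mr_result`.
#' @export
mr_egger <- function(data, use_t = FALSE) {
  check_hs(data, 3L, "egger")
  fit <- egger_fit(data$beta_exp, data$beta_out, data$se_out)
  pfun <- if (use_t) {
    function(z) 2 * stats::pt(-abs(z), df = fit$df)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  new_mr_result("egger", fit$slope, fit$se_slope, pfun(fit$slope / fit$se_slope),
                nrow(data),
                aux = list(intercept = fit$intercept,
                           intercept_se = fit$se_intercept,
                           intercept_pval = pfun(fit$intercept / fit$se_intercept),
                           sigma2 = fit$sigma2),
                binary = is_binary_outcome(data))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(r[1])
  n <- length(r)
  if (0.5 >= cw[n]) return(r[n])
  j <- max(which(cw <= 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

#' Weighted median estimator
#'
#' Per-SNP Wald ratios are ordered and the estimate is the linear
#' interpolation of the ordered ratios at normalized cumulative weight 1/2
#' (cumulative weight of the j-th ratio taken as the sum of the first j
#' weights minus half the j-th), with inverse-variance weights
#' `(beta_exp/se_out)^2`. The estimate is consistent when instruments
#' carrying at least half the weight are valid. The SE comes from a
#' parametric bootstrap resampling `beta_exp` and `beta_out` from their
#' sampling distributions.
#'
#' @param data a `harmonized_set` with k >= 3.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (recorded in `aux`).
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1) {
  check_hs(data, 3L, "weighted_median")
  bx <- data$beta_exp; by <- data$beta_out
  sx <- data$se_exp; sy <- data$se_out
  w <- (bx / sy)^2
  est <- weighted_median_point(by / bx, w)
  k <- length(bx)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- stats::rnorm(k, bx, sx)
      byb <- stats::rnorm(k, by, sy)
      weighted_median_point(byb / bxb, (bxb / sy)^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(est / se))
  new_mr_result("weighted_median", est, se, p, k,
                aux = list(n_boot = n_boot, seed = seed),
                binary = is_binary_outcome(data))
}

#' Maximum-likelihood estimator
#'
#' Maximizes the joint normal likelihood with per-SNP nuisance means
#' \eqn{\xi_j}: `beta_exp_j ~ N(xi_j, se_exp_j^2)`,
#' `beta_out_j ~ N(theta * xi_j, se_out_j^2)`. The nuisance effects are
#' profiled out in closed form, leaving the one-dimensional profile
#' objective \eqn{\sum_j (beta_{out,j} - \theta beta_{exp,j})^2 /
#' (se_{out,j}^2 + \theta^2 se_{exp,j}^2)} which is minimized numerically
#' from the IVW starting value; the SE comes from the observed information
#' of the profile likelihood.
#'
#' @param data a `harmonized_set` with k >= 2.
#' @return an `mr_result` with the profiled \eqn{\hat\xi_j} in `aux$xi`.
#' @export
mr_max_likelihood <- function(data) {
  check_hs(data, 2L, "max_likelihood")
  bx <- data$beta_exp; by <- data$beta_out
  vx <- data$se_exp^2; vy <- data$se_out^2
  nll <- function(theta) 0.5 * sum((by - theta * bx)^2 / (vy + theta^2 * vx))
  start <- ivw_fit(bx, by, data$se_out)$estimate
  width <- max(1, 10 * abs(start))
  opt <- stats::optim(start, nll, method = "Brent",
                      lower = start - width, upper = start + width)
  if (opt$convergence != 0) {
    bimr_stop("numerical_error", "max_likelihood optimizer failed (code %d)",
              opt$convergence)
  }
  theta <- opt$par
  h <- max(1e-6, 1e-6 * abs(theta))
  info <- (nll(theta + h) - 2 * nll(theta) + nll(theta - h)) / h^2
  if (!is.finite(info) || info <= 0) {
    bimr_stop("numerical_error", "max_likelihood information not positive at optimum")
  }
  se <- 1 / sqrt(info)
  xi <- (bx / vx + theta * by / vy) / (1 / vx + theta^2 / vy)
  p <- 2 * stats::pnorm(-abs(theta / se))
  new_mr_result("max_likelihood", theta, se, p, nrow(data),
                aux = list(xi = xi), binary = is_binary_outcome(data))
}

huber_psi <- function(t, c) pmax(pmin(t, c), -c)
huber_rho <- function(t, c) ifelse(abs(t) <= c, t^2 / 2, c * abs(t) - c^2 / 2)

#' Robust adjusted profile score estimator (RAPS)
#'
#' Profile-score estimation of the causal effect with per-SNP standardized
#' residuals
#' \deqn{t_j(\theta, \tau^2) = (beta_{out,j} - \theta beta_{exp,j}) /
#'   \sqrt{se_{out,j}^2 + \theta^2 se_{exp,j}^2 + \tau^2}.}
#' The effect solves the M-estimating equation from the (optionally
#' Huber-robustified) loss in the residuals; with `overdispersion = TRUE`
#' the systematic-pleiotropy variance \eqn{\tau^2 \ge 0} is estimated
#' jointly from its moment estimating equation
#' \eqn{\sum_j \psi(t_j) t_j = k\,\delta} (\eqn{\delta = E[\psi(Z)Z]} under
#' a standard normal). A \eqn{\hat\tau^2} pinned at 0 is legal and reported.
#' The SE is the M-estimation sandwich.
#'
#' @param data a `harmonized_set` with k >= 3.
#' @param overdispersion estimate tau^2 (default TRUE).
#' @param loss `"huber"` (default, tuning constant `huber_c`) or
#'   `"quadratic"`.
#' @param huber_c Huber tuning constant (default 1.345).
#' @param max_iter,tol iteration controls for the alternating solver.
#' @return an `mr_result` with `aux$tau2`.
#' @export
mr_raps <- function(data, overdispersion = TRUE, loss = c("huber", "quadratic"),
                    huber_c = 1.345, max_iter = 200, tol = 1e-7) {
  check_hs(data, 3L, "raps")
  loss <- match.arg(loss)
  bx <- data$beta_exp; by <- data$beta_out
  vx <- data$se_exp^2; vy <- data$se_out^2
  k <- length(bx)
  psi <- if (loss == "huber") function(t) huber_psi(t, huber_c) else function(t) t
  dpsi <- if (loss == "huber") function(t) as.numeric(abs(t) <= huber_c) else function(t) rep(1, length(t))
  rho <- if (loss == "huber") function(t) huber_rho(t, huber_c) else function(t) t^2 / 2
  delta <- if (loss == "huber") 2 * stats::pnorm(huber_c) - 1 else 1

  tfun <- function(theta, tau2) (by - theta * bx) / sqrt(vy + theta^2 * vx + tau2)
  obj <- function(theta, tau2) sum(rho(tfun(theta, tau2)))
  disp_eq <- function(tau2, theta) {
    t <- tfun(theta, tau2)
    sum(psi(t) * t) - k * delta
  }

  theta <- ivw_fit(bx, by, data$se_out)$estimate
  tau2 <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    theta_old <- theta; tau2_old <- tau2
    width <- max(1, 10 * abs(theta))
    theta <- stats::optimize(obj, c(theta - width, theta + width),
                             tau2 = tau2, tol = 1e-12)$minimum
    if (overdispersion) {
      if (disp_eq(0, theta) <= 0) {
        tau2 <- 0  # residuals already under-dispersed: pin at boundary
      } else {
        upper <- max(vy) + stats::var(by - theta * bx)
        while (disp_eq(upper, theta) > 0) upper <- upper * 4
        tau2 <- stats::uniroot(disp_eq, c(0, upper), theta = theta,
                               tol = 1e-14)$root
      }
    }
    # optimize() cannot localize a minimum much below sqrt(machine eps), so
    # the convergence floors are absolute + relative
    if (abs(theta - theta_old) < tol * max(1, abs(theta)) &&
        abs(tau2 - tau2_old) < 1e-10 + 1e-4 * tau2) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    bimr_stop("numerical_error",
              "raps did not converge in %d iterations (theta=%g, tau2=%g)",
              max_iter, theta, tau2)
  }

  # sandwich SE for theta (tau2 treated as plugged-in)
  v <- vy + theta^2 * vx + tau2
  t <- tfun(theta, tau2)
  dt <- -bx / sqrt(v) - t * theta * vx / v
  A <- sum(dpsi(t) * dt^2)
  B <- sum(psi(t)^2 * dt^2)
  if (!is.finite(A) || A <= 0) {
    bimr_stop("numerical_error", "raps sandwich bread not positive")
  }
  se <- sqrt(B) / A
  p <- 2 * stats::pnorm(-abs(theta / se))
  new_mr_result("raps", theta, se, p, k,
                aux = list(tau2 = tau2, loss = loss, iterations = it),
                binary = is_binary_outcome(data))
}

#' Run the full estimator battery appropriate to the instrument count
#'
#' With one SNP only the Wald ratio is computed; with two SNPs IVW and the
#' maximum-likelihood estimator; with three or more all five multi-SNP
#' methods (IVW, MR-Egger, weighted median, maximum likelihood, RAPS). For
#' binary outcomes every result also carries the odds ratio
#' `exp(estimate)` with exponentiated CI bounds. A method failure is
#' recorded and does not abort the others.
#'
#' @param data a `harmonized_set` with k >= 1.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param raps_overdispersion,raps_loss RAPS settings.
#' @return list with `results` (named list of `mr_result`) and `failures`
#'   (named character vector of error messages).
#' @export
mr_run_all <- function(data, n_boot = 1000, seed = 1,
                       raps_overdispersion = TRUE, raps_loss = "huber") {
  check_hs(data, 1L, "run_all")
  k <- nrow(data)
  runners <- if (k == 1L) {
    list(wald_ratio = function() mr_wald_ratio(data))
  } else if (k == 2L) {
    list(ivw = function() mr_ivw(data),
         max_likelihood = function() mr_max_likelihood(data))
  } else {
    list(ivw = function() mr_ivw(data),
         egger = function() mr_egger(data),
         weighted_median = function() mr_weighted_median(data, n_boot, seed),
         max_likelihood = function() mr_max_likelihood(data),
         raps = function() mr_raps(data, overdispersion = raps_overdispersion,
                                   loss = raps_loss))
  }
  results <- list(); failures <- character(0)
  for (m in names(runners)) {
    r <- tryCatch(runners[[m]](), error = function(e) e)
    if (inherits(r, "error")) failures[m] <- conditionMessage(r)
    else results[[m]] <- r
  }
  list(results = results, failures = failures)
}
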