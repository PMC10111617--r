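# Causal-effect estimators for harmonized per-SNP effect pairs: Wald ratio,
# inverse-variance weighted (IVW), MR-Egger and the weighted median.
#
# All estimators return an `mr_estimate`: the causal effect on the log-OR
# scale with its standard error, two-sided p-value, odds ratio and 95% CI.

new_mr_estimate <- function(method, beta, se, pval, n_snp,
                            egger_intercept = NULL,
                            egger_intercept_se = NULL,
                            egger_intercept_p = NULL) {
  est <- list(method = method, beta = beta, se = se, pval = pval,
              or = exp(beta),
              ci_low = exp(beta - Z95 * se),
              ci_high = exp(beta + Z95 * se),
              n_snp = as.integer(n_snp))
  if (!is.null(egger_intercept)) {
    est$egger_intercept <- egger_intercept
    est$egger_intercept_se <- egger_intercept_se
    est$egger_intercept_p <- egger_intercept_p
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  intercept = %.3g (se %.3g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

check_harmonized <- function(h) {
  if (!all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(h)))
    stop_mr("expected a harmonized_set (or data.frame with beta_exp/se_exp/beta_out/se_out)")
  h
}

#' Wald ratio estimator
#'
#' Single-instrument causal estimate: the outcome effect divided by the
#' exposure effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|`.
#'
#' @param h a `harmonized_set` restricted to exactly one SNP.
#' @return an `mr_estimate` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(h) {
  check_harmonized(h)
  if (nrow(h) != 1L) stop_mr("wald ratio requires exactly one SNP")
  if (h$beta_exp == 0) stop_mr("undefined ratio: exposure effect is zero")
  beta <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp)
  new_mr_estimate("wald_ratio", beta, se, two_sided_p(beta, se), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Pools per-SNP Wald ratios with weights `beta_exp^2 / se_out^2` —
#' equivalently the slope of the zero-intercept regression of `beta_out` on
#' `beta_exp` weighted by `1 / se_out^2`. The fixed-effect standard error is
#' `1 / sqrt(sum(w))`; the default multiplicative random-effects model
#' inflates it by `sqrt(max(1, Q / (n - 1)))` where Q is Cochran's
#' heterogeneity statistic. With one SNP the estimator reduces to the Wald
#' ratio; SNPs with a zero exposure effect are excluded with a warning.
#'
#' @param h a `harmonized_set`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with method `"ivw"` (or `"wald_ratio"` after
#'   reduction to one SNP).
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(h)
  zero <- h$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("excluded %d SNP(s) with zero exposure effect", sum(zero)),
            call. = FALSE)
    h <- subset_harmonized(h, !zero)
  }
  n <- nrow(h)
  if (n == 0L) stop_mr("no usable SNPs for IVW")
  if (n == 1L) return(mr_wald_ratio(h))

  ratios <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  beta <- sum(w * ratios) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratios - beta)^2)
  se <- if (model == "multiplicative_random") {
    se_fixed * sqrt(max(1, q / (n - 1)))
  } else {
    se_fixed
  }
  new_mr_estimate("ivw", beta, se, two_sided_p(beta, se), n)
}

# Weighted regression of beta_out on beta_exp with intercept, exposure
# effects oriented non-negative, weights 1/se_out^2. Returns the pieces all
# Egger-based reporting needs. `phi_raw` is the unconstrained residual
# scale Q'/(n-2); coefficient SEs use the truncated multiplicative
# random-effects scale max(1, phi_raw).
egger_fit <- function(h) {
  check_harmonized(h)
  n <- nrow(h)
  if (n < 2L) stop_mr("Egger regression requires at least 2 SNPs")
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- s * h$beta_exp
  y <- s * h$beta_out
  w <- 1 / h$se_out^2

  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  if (d <= 0) stop_mr("degenerate design: exposure effects are collinear")
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swy - slope * swx) / sw

  resid <- y - intercept - slope * x
  qprime <- sum(w * resid^2)
  df <- n - 2L
  phi_raw <- if (df > 0) qprime / df else NA_real_
  phi <- if (df > 0) max(1, phi_raw) else 1
  slope_se <- sqrt(phi * sw / d)
  intercept_se <- sqrt(phi * swxx / d)
  list(slope = slope, slope_se = slope_se,
       intercept = intercept, intercept_se = intercept_se,
       qprime = qprime, df = df, phi_raw = phi_raw, phi = phi)
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with
#' a free intercept (weights `1 / se_out^2`, exposure effects oriented
#' non-negative). The slope is a pleiotropy-adjusted causal estimate; the
#' intercept estimates average directional pleiotropy and feeds the
#' pleiotropy test ([egger_intercept_test()]). Standard errors use the
#' multiplicative random-effects scale `sqrt(max(1, Q' / (n - 2)))`;
#' p-values come from the t distribution with `n - 2` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return an `mr_estimate` with method `"egger"` and intercept fields.
#' @export
mr_egger <- function(h) {
  check_harmonized(h)
  if (nrow(h) < 3L) stop_mr("MR-Egger requires at least 3 SNPs")
  fit <- egger_fit(h)
  pval <- 2 * pt(-abs(fit$slope / fit$slope_se), df = fit$df)
  ip <- 2 * pt(-abs(fit$intercept / fit$intercept_se), df = fit$df)
  new_mr_estimate("egger", fit$slope, fit$slope_se, pval, nrow(h),
                  egger_intercept = fit$intercept,
                  egger_intercept_se = fit$intercept_se,
                  egger_intercept_p = ip)
}

# Weighted median of `values` with weights `w`, using the cumulative-weight
# midpoint convention (cumulative weight minus half the SNP's own weight)
# and linear interpolation between the bracketing SNPs.
weighted_median_point <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  ww <- w[ord] / sum(w)
  cw <- cumsum(ww) - ww / 2
  n <- length(v)
  if (0.5 <= cw[1L]) return(v[1L])
  if (0.5 >= cw[n]) return(v[n])
  approx(cw, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The per-SNP Wald ratio at which the cumulative normalized weight
#' (`beta_exp^2 / se_out^2`) crosses one half — consistent when instruments
#' carrying at least half the weight are valid. The standard error comes
#' from a parametric bootstrap: per-SNP effects are redrawn from their
#' Gaussians and the weighted median recomputed.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the bootstrap (mandatory, so results are
#'   reproducible); the RNG state of the session is left untouched.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  check_harmonized(h)
  n <- nrow(h)
  if (n < 3L) stop_mr("weighted median requires at least 3 SNPs")
  if (missing(seed)) stop_mr("weighted median bootstrap requires a seed")
  ratios <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  beta <- weighted_median_point(ratios, w)

  boots <- withr::with_seed(as.integer(seed), {
    bx <- matrix(rnorm(n_boot * n, mean = rep(h$beta_exp, each = n_boot),
                       sd = rep(h$se_exp, each = n_boot)), nrow = n_boot)
    by <- matrix(rnorm(n_boot * n, mean = rep(h$beta_out, each = n_boot),
                       sd = rep(h$se_out, each = n_boot)), nrow = n_boot)
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(by[i, ] / bx[i, ], bx[i, ]^2 / h$se_out^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_estimate("weighted_median", beta, se, two_sided_p(beta, se), n)
}

#' Run all applicable estimators
#'
#' Dispatches on the number of instruments: one SNP gives the Wald ratio;
#' two give IVW; three or more add MR-Egger and the weighted median.
#'
#' @param h a `harmonized_set`.
#' @param ivw_model IVW error model, see [mr_ivw()].
#' @param n_boot,seed weighted-median bootstrap controls, see
#'   [mr_weighted_median()].
#' @return a named list of `mr_estimate` objects.
#' @export
mr_all <- function(h, ivw_model = "multiplicative_random",
                   n_boot = 1000, seed = 1L) {
  check_harmonized(h)
  n <- nrow(h)
  if (n == 1L) return(list(wald_ratio = mr_wald_ratio(h)))
  out <- list(ivw = mr_ivw(h, model = ivw_model))
  if (n >= 3L) {
    out$egger <- mr_egger(h)
    out$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  }
  out
}
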