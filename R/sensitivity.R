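# Heterogeneity and pleiotropy diagnostics: Cochran's Q for the IVW and
# Egger fits, the Egger intercept test, and MR-PRESSO (global, outlier and
# distortion tests) by parametric simulation.

#' Cochran's Q heterogeneity test
#'
#' For the IVW fit, Q sums the inverse-variance-weighted squared deviations
#' of the per-SNP Wald ratios from the pooled fixed-effect estimate
#' (weights `beta_exp^2 / se_out^2`, df `n - 1`). For the Egger fit, Q is
#' Ruecker's Q': the regression-scale weighted residual sum of squares of
#' the intercept model (weights `1 / se_out^2`, df `n - 2`). The p-value is
#' the upper chi-square tail at the stated degrees of freedom.
#'
#' @param h a `harmonized_set`.
#' @param fit which fitted model the residuals refer to.
#' @return a list with elements `statistic`, `df`, `pval` and `fit`.
#' @export
cochran_q <- function(h, fit = c("ivw", "egger")) {
  fit <- match.arg(fit)
  check_harmonized(h)
  n <- nrow(h)
  if (fit == "ivw") {
    if (n < 2L) stop_mr("Q for IVW requires at least 2 SNPs")
    ratios <- h$beta_out / h$beta_exp
    w <- h$beta_exp^2 / h$se_out^2
    b <- sum(w * ratios) / sum(w)
    statistic <- sum(w * (ratios - b)^2)
    df <- n - 1L
  } else {
    if (n < 3L) stop_mr("Q for Egger requires at least 3 SNPs")
    f <- egger_fit(h)
    statistic <- f$qprime
    df <- f$df
  }
  list(statistic = statistic, df = df,
       pval = pchisq(statistic, df, lower.tail = FALSE), fit = fit)
}

#' Egger intercept pleiotropy test
#'
#' Reports the intercept of the Egger regression with its standard error
#' and a two-sided t-test at `n - 2` degrees of freedom. A non-zero
#' intercept indicates average directional pleiotropy across instruments.
#' A two-SNP input is an exact fit: the algebraic line intercept is
#' returned with zero residual degrees of freedom and an `NA` p-value,
#' with a warning.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @return a list with elements `estimate`, `se`, `pval` and `df`.
#' @export
egger_intercept_test <- function(h) {
  check_harmonized(h)
  n <- nrow(h)
  fit <- egger_fit(h)
  if (fit$df == 0L) {
    warning("two-point exact fit: intercept reported with df = 0, no test possible",
            call. = FALSE)
    return(list(estimate = fit$intercept, se = NA_real_, pval = NA_real_,
                df = 0L))
  }
  list(estimate = fit$intercept, se = fit$intercept_se,
       pval = 2 * pt(-abs(fit$intercept / fit$intercept_se), df = fit$df),
       df = fit$df)
}

# Leave-one-out fixed-effect IVW slopes on the regression scale
# (beta_out ~ 0 + beta_exp, weights 1/se_out^2), one per left-out SNP.
loo_ivw_slopes <- function(bx, by, sy) {
  wxy <- bx * by / sy^2
  wxx <- bx^2 / sy^2
  (sum(wxy) - wxy) / (sum(wxx) - wxx)
}

ivw_slope <- function(bx, by, sy) sum(bx * by / sy^2) / sum(bx^2 / sy^2)

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection of horizontally pleiotropic outlier
#' instruments. The observed global statistic is the weighted residual sum
#' of squares `RSS = sum(w_j * (beta_out_j - beta_exp_j * b_(-j))^2)` with
#' leave-one-out IVW slopes `b_(-j)` and weights `1 / se_out^2`. `n_sim`
#' datasets are simulated by redrawing both effect vectors from Gaussians
#' centered on the observed exposure effects and the leave-one-out fitted
#' outcome values; the global p-value is the fraction of simulated RSS at
#' or above the observed one. Per-SNP outlier p-values compare each SNP's
#' observed residual contribution with its simulated contributions and are
#' Bonferroni-adjusted over SNPs; when outliers are flagged, the distortion
#' test compares the all-SNP and outlier-free IVW slopes against the
#' distortions obtained by removing equally many randomly chosen SNPs.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param n_sim number of simulated datasets (at least 100).
#' @param outlier_alpha per-test significance level applied to the
#'   Bonferroni-adjusted outlier p-values.
#' @param seed integer seed; results are reproducible bit-for-bit for a
#'   given `(seed, n_sim)`.
#' @return an object of class `mr_presso`: a list with `global_rss`,
#'   `global_p`, `outliers` (per-SNP data.frame), `outlier_snps`,
#'   `distortion_p` (`NA` when no outlier is flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed) {
  check_harmonized(h)
  n <- nrow(h)
  if (n < 4L) stop_mr("MR-PRESSO requires at least 4 SNPs")
  if (n_sim < 100) stop_mr("n_sim must be at least 100")
  if (missing(seed)) stop_mr("mr_presso requires a seed")

  bx <- h$beta_exp; by <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  w <- 1 / sy^2

  b_loo <- loo_ivw_slopes(bx, by, sy)
  fitted <- bx * b_loo
  contrib_obs <- w * (by - fitted)^2
  rss_obs <- sum(contrib_obs)

  res <- withr::with_seed(as.integer(seed), {
    bxs <- matrix(rnorm(n_sim * n, mean = rep(bx, each = n_sim),
                        sd = rep(sx, each = n_sim)), nrow = n_sim)
    bys <- matrix(rnorm(n_sim * n, mean = rep(fitted, each = n_sim),
                        sd = rep(sy, each = n_sim)), nrow = n_sim)

    wxy <- sweep(bxs * bys, 2L, sy^2, "/")
    wxx <- sweep(bxs^2, 2L, sy^2, "/")
    b_loo_sim <- (rowSums(wxy) - wxy) / (rowSums(wxx) - wxx)
    resid <- bys - bxs * b_loo_sim
    contrib <- sweep(resid^2, 2L, sy^2, "/")
    rss_sim <- rowSums(contrib)

    p_raw <- colMeans(sweep(contrib, 2L, contrib_obs, ">="))
    p_adj <- pmin(1, p_raw * n)
    flagged <- p_adj < outlier_alpha

    distortion_p <- NA_real_
    k <- sum(flagged)
    if (k > 0L && n - k >= 2L) {
      b_all <- ivw_slope(bx, by, sy)
      b_free <- ivw_slope(bx[!flagged], by[!flagged], sy[!flagged])
      d_obs <- (b_all - b_free) / abs(b_free)
      d_perm <- vapply(seq_len(n_sim), function(i) {
        drop_i <- sample.int(n, k)
        b_sub <- ivw_slope(bx[-drop_i], by[-drop_i], sy[-drop_i])
        (b_all - b_sub) / abs(b_sub)
      }, numeric(1))
      distortion_p <- mean(abs(d_perm) >= abs(d_obs))
    }
    list(global_p = mean(rss_sim >= rss_obs), p_raw = p_raw, p_adj = p_adj,
         flagged = flagged, distortion_p = distortion_p)
  })

  flagged <- res$flagged
  outliers <- data.frame(snp_id = h$snp_id, p_raw = res$p_raw,
                         p_adj = res$p_adj, flagged = flagged,
                         stringsAsFactors = FALSE)
  global_p <- res$global_p
  distortion_p <- res$distortion_p

  structure(list(global_rss = rss_obs, global_p = global_p,
                 outliers = outliers,
                 outlier_snps = h$snp_id[flagged],
                 distortion_p = distortion_p,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.3g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outlier_snps)) {
    cat(sprintf("  outliers: %s; distortion p = %.3g\n",
                paste(x$outlier_snps, collapse = ", "), x$distortion_p))
  } else {
    cat("  no outliers flagged; distortion test not applicable\n")
  }
  invisible(x)
}

#' Full sensitivity report
#'
#' Bundles the heterogeneity and pleiotropy diagnostics for one harmonized
#' instrument set: Cochran's Q under the IVW and Egger fits, the Egger
#' intercept test, and MR-PRESSO (when at least 4 SNPs are available).
#'
#' @param h a `harmonized_set`.
#' @param n_sim,outlier_alpha,seed MR-PRESSO controls, see [mr_presso()].
#' @return an object of class `sensitivity_report`.
#' @export
sensitivity_report <- function(h, n_sim = 1000, outlier_alpha = 0.05,
                               seed = 1L) {
  check_harmonized(h)
  n <- nrow(h)
  rep <- list(
    q_ivw = if (n >= 2L) cochran_q(h, "ivw") else NULL,
    q_egger = if (n >= 3L) cochran_q(h, "egger") else NULL,
    egger_intercept = if (n >= 3L) egger_intercept_test(h) else NULL,
    presso = if (n >= 4L) mr_presso(h, n_sim = n_sim,
                                    outlier_alpha = outlier_alpha,
                                    seed = seed) else NULL,
    n_simulations = as.integer(n_sim),
    seed = as.integer(seed)
  )
  structure(rep, class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  fmt_q <- function(q, label) {
    if (is.null(q)) return(invisible(NULL))
    cat(sprintf("  %s, Q = %.2f (df %d), p = %.2g\n",
                label, q$statistic, q$df, q$pval))
  }
  cat("Sensitivity analysis\n")
  fmt_q(x$q_ivw, "IVW")
  fmt_q(x$q_egger, "MR Egger")
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.3g, p = %.2g\n",
                x$egger_intercept$estimate, x$egger_intercept$pval))
  if (!is.null(x$presso))
    cat(sprintf("  MR-PRESSO global p = %.3g (%d outlier(s))\n",
                x$presso$global_p, length(x$presso$outlier_snps)))
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precisions, the data behind the usual
#' MR funnel plot used to eyeball directional pleiotropy.
#'
#' @param h a `harmonized_set`.
#' @return a data.frame with columns `snp_id`, `ratio` and `precision`
#'   (`|beta_exp| / se_out`, the reciprocal of the ratio's standard error).
#' @export
funnel_data <- function(h) {
  check_harmonized(h)
  data.frame(snp_id = h$snp_id,
             ratio = h$beta_out / h$beta_exp,
             precision = abs(h$beta_exp) / h$se_out,
             stringsAsFactors = FALSE)
}
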