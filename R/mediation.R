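# Two-step MR mediation: combine the exposure->outcome (total, c),
# exposure->mediator (a) and mediator->outcome (b) estimates into the
# product-of-coefficients decomposition. All arithmetic is on the log-OR
# scale, where mediated + direct = total holds exactly.

# Accept either an mr_estimate or a bare log-scale effect.
effect_of <- function(x, what = "estimate") {
  if (inherits(x, "mr_estimate")) return(x$beta)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(as.numeric(x))
  stop_mr("%s must be an mr_estimate or a single log-scale effect", what)
}

se_of <- function(x, what = "estimate") {
  if (inherits(x, "mr_estimate")) return(x$se)
  stop_mr("%s must be an mr_estimate carrying a standard error", what)
}

#' Mediation decomposition (product of coefficients)
#'
#' Combines the total effect of the exposure on the outcome (c), the
#' exposure-to-mediator effect (a) and the mediator-to-outcome effect (b)
#' into: mediated effect `a * b`, direct effect `c - a * b`, and proportion
#' mediated `(a * b) / c`. All inputs are taken on the log scale (log odds
#' ratios for binary-outcome steps); values are carried at full precision
#' and rounded only when printed.
#'
#' @param total,step1,step2 `mr_estimate` objects (or bare log-scale
#'   effects) for c, a and b respectively.
#' @return an object of class `mediation_result` with fields
#'   `total_effect`, `step1_effect`, `step2_effect`, `mediated_effect`,
#'   `direct_effect`, `proportion_mediated`, and placeholders `se_mediated`,
#'   `ci_mediated`, `method_se` (filled by [mediated_se()]).
#' @examples
#' # worked example with printed two-decimal odds ratios
#' mediate_decompose(log(1.27), log(1.06), log(1.25))
#' @export
mediate_decompose <- function(total, step1, step2) {
  c_ <- effect_of(total, "total")
  a <- effect_of(step1, "step1")
  b <- effect_of(step2, "step2")
  mediated <- a * b
  direct <- c_ - mediated
  proportion <- if (c_ == 0) {
    warning("total effect is zero: proportion mediated undefined",
            call. = FALSE)
    NA_real_
  } else {
    mediated / c_
  }
  stopifnot(isTRUE(all.equal(mediated + direct, c_, tolerance = 1e-12)))
  structure(list(total_effect = c_, step1_effect = a, step2_effect = b,
                 mediated_effect = mediated, direct_effect = direct,
                 proportion_mediated = proportion,
                 se_mediated = NA_real_, ci_mediated = NULL,
                 method_se = "none"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation decomposition (log-OR scale)\n")
  cat(sprintf("  total effect (c):        %.4f\n", x$total_effect))
  cat(sprintf("  exposure->mediator (a):  %.4f\n", x$step1_effect))
  cat(sprintf("  mediator->outcome (b):   %.4f\n", x$step2_effect))
  cat(sprintf("  mediated effect (a*b):   %.4f\n", x$mediated_effect))
  cat(sprintf("  direct effect (c - a*b): %.4f\n", x$direct_effect))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated:     undefined (total effect is zero)\n")
  } else {
    cat(sprintf("  proportion mediated:     %.2f%%\n",
                100 * x$proportion_mediated))
  }
  if (!is.na(x$se_mediated))
    cat(sprintf("  se(mediated) [%s]:    %.4f (95%% CI %.4f, %.4f)\n",
                x$method_se, x$se_mediated,
                x$ci_mediated[1L], x$ci_mediated[2L]))
  invisible(x)
}

#' Uncertainty for the mediated effect
#'
#' Standard error and 95% CI for the product `a * b`. The delta method
#' gives `se = sqrt(b^2 * se_a^2 + a^2 * se_b^2)` with a normal CI; the
#' parametric bootstrap resamples (a, b) from independent Gaussians and
#' takes the sd and 2.5/97.5% quantiles of the products.
#'
#' @param step1,step2 `mr_estimate` objects for a and b (or lists with
#'   `beta` and `se`).
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (bootstrap method only).
#' @param seed integer seed (bootstrap method only).
#' @return a list with `se`, `ci_low`, `ci_high` and `method`.
#' @export
mediated_se <- function(step1, step2, method = c("delta", "bootstrap"),
                        n_boot = 1000, seed = 1L) {
  method <- match.arg(method)
  a <- effect_of(step1, "step1"); b <- effect_of(step2, "step2")
  get_se <- function(x) if (inherits(x, "mr_estimate")) x$se else x$se %||%
    stop_mr("step estimates must carry standard errors")
  se_a <- get_se(step1); se_b <- get_se(step2)
  if (any(!is.finite(c(se_a, se_b))) || se_a < 0 || se_b < 0)
    stop_mr("standard errors must be non-negative")

  if (method == "delta") {
    se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
    return(list(se = se, ci_low = a * b - Z95 * se, ci_high = a * b + Z95 * se,
                method = "delta"))
  }
  prods <- withr::with_seed(as.integer(seed), {
    rnorm(n_boot, a, se_a) * rnorm(n_boot, b, se_b)
  })
  ci <- unname(quantile(prods, c(0.025, 0.975)))
  list(se = sd(prods), ci_low = ci[1L], ci_high = ci[2L],
       method = "bootstrap")
}

#' Screen candidate mediators
#'
#' Retains the candidates whose mediator-to-outcome causal test is
#' significant at `alpha` with a strict inequality (`p < alpha`): a
#' candidate with no detectable effect on the outcome cannot carry a
#' mediated path and is not taken forward to the decomposition.
#'
#' @param candidates a named numeric vector of mediator-to-outcome
#'   p-values, or a named list of `mr_estimate` objects.
#' @param alpha screening level in (0, 1).
#' @return character vector of retained mediator names (possibly empty),
#'   in input order.
#' @export
screen_mediators <- function(candidates, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop_mr("alpha must lie in (0, 1]")
  if (length(candidates) == 0L) return(character(0))
  p <- if (is.list(candidates)) {
    vapply(candidates, function(x) {
      if (inherits(x, "mr_estimate")) x$pval else as.numeric(x)
    }, numeric(1))
  } else {
    candidates
  }
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop_mr("candidates must be named")
  names(p)[p < alpha]
}
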