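# Two-sided 95% normal multiplier, fixed so that serialized CIs are stable
# across platforms.
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a base seed
#'
#' All stochastic components of the package (weighted-median bootstrap,
#' MR-PRESSO simulations, the synthetic-data generator) take explicit seeds.
#' The pipeline derives one child seed per component from its single run
#' seed with this function, so that a run is reproducible from one integer.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed integer base seed.
#' @param offset non-negative integer component offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(((abs(as.numeric(seed)) %% 1000003) * 2011 + abs(offset)) %%
               2147483647)
}

# Gaussian two-sided p from an effect and its standard error.
two_sided_p <- function(beta, se) 2 * pnorm(-abs(beta / se))

# Clamp p-values into (0, 1]; Gaussian tails can underflow to 0.
clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)
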