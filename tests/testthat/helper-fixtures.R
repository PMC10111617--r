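# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# Minimal canonical summary-statistics table.
make_records <- function(n = 3, beta = NULL, se = NULL, pval = NULL,
                         ea = NULL, oa = NULL, chrom = NULL, pos = NULL,
                         eaf = NULL, nn = NULL, ids = NULL) {
  beta <- beta %||% seq(0.1, by = 0.05, length.out = n)
  se <- se %||% rep(0.01, n)
  data.frame(
    snp_id = ids %||% sprintf("rs%04d", seq_len(n)),
    chrom = chrom %||% rep("1", n),
    pos = pos %||% (1e6 * seq_len(n)),
    effect_allele = ea %||% rep("A", n),
    other_allele = oa %||% rep("G", n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta,
    se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = nn %||% rep(1e5, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonized set straight from effect vectors.
make_harmonized <- function(beta_exp, beta_out, se_exp = NULL, se_out = NULL,
                            n_exp = NULL, n_out = NULL) {
  k <- length(beta_exp)
  df <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(k)),
    beta_exp = beta_exp,
    se_exp = se_exp %||% rep(0.01, k),
    beta_out = beta_out,
    se_out = se_out %||% rep(0.05, k),
    stringsAsFactors = FALSE
  )
  if (!is.null(n_exp)) df$n_exp <- n_exp
  if (!is.null(n_out)) df$n_out <- n_out
  as_harmonized_set(df)
}

# A reproducible 20-SNP fixture with genuine heterogeneity, used by the
# weighted-least-squares oracle and bootstrap-convergence tests.
fixture_20snp <- function(seed = 7101, slope = 0.25) {
  withr::with_seed(seed, {
    bx <- abs(rnorm(20, 0.05, 0.02)) + 0.01
    sx <- rep(0.002, 20)
    sy <- runif(20, 0.01, 0.05)
    by <- slope * bx + rnorm(20, 0, sy)
    make_harmonized(bx, by, sx, sy)
  })
}

# Null-scenario configuration: real instruments, zero causal effects.
null_config <- function(seed, n_snp = 50) {
  simulation_config(seed = seed, n_snp_causal = n_snp, n_snp_mediator = 0,
                    n_snp_null = 0, beta_xm = 0, beta_my = 0,
                    beta_xy_direct = 0)
}

# Harmonized exposure/outcome set from a simulated study, optionally after
# p-value selection and clumping (the common test path).
harmonized_from_study <- function(study, threshold = 5e-8, clumped = TRUE) {
  sel <- select_by_pvalue(study$exposure, threshold)
  if (clumped) sel <- clump(sel, study$ld)
  harmonize(sel, study$outcome)
}
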