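# Instrument selection: significance thresholding, greedy LD clumping,
# instrument-strength F statistics and Steiger directionality filtering.

#' Select instruments by association p-value
#'
#' Keeps exactly the records with `pval < threshold` (strict inequality),
#' preserving the input order. Genome-wide significance (5e-8) is the usual
#' threshold; instrument-poor traits conventionally relax to 1e-5.
#'
#' @param records canonical summary-statistics data.frame.
#' @param threshold selection p-value threshold in (0, 1].
#' @return the subset of `records` passing the threshold.
#' @export
select_by_pvalue <- function(records, threshold = 5e-8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_mr("threshold must be a single probability in (0, 1]")
  keep <- records$pval < threshold
  if (!any(keep))
    stop_mr("no SNPs pass p < %g; consider a relaxed threshold (e.g. 1e-5) for instrument-poor traits",
            threshold)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld))
    stop_mr("LD matrix must be square")
  if (is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld)))
    stop_mr("LD matrix must carry identical SNP ids as row and column names")
  if (any(abs(ld - t(ld)) > 1e-8)) stop_mr("LD matrix must be symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop_mr("LD matrix must have unit diagonal")
  if (any(ld < -1 - 1e-8 | ld > 1 + 1e-8))
    stop_mr("LD correlations must lie in [-1, 1]")
  invisible(ld)
}

#' Greedy LD clumping
#'
#' Prunes correlated instruments: records are visited in order of ascending
#' p-value (ties broken by `snp_id`); each visited SNP is accepted unless it
#' lies within `window_kb` of an already-accepted SNP on the same chromosome
#' with squared LD correlation at or above `r2_threshold`. Records absent
#' from the LD matrix (or the whole matrix, when `ld` is `NULL`) are treated
#' as independent. When chromosome/position are unavailable the window
#' restriction is waived and the r-squared criterion alone decides.
#'
#' @param records canonical summary-statistics data.frame.
#' @param ld square correlation matrix (cells are r, not r-squared) with SNP
#'   ids as dimnames, or `NULL`.
#' @param r2_threshold squared-correlation threshold above which two SNPs
#'   are considered dependent.
#' @param window_kb clumping window in kilobases.
#' @return the accepted records, in acceptance (ascending p-value) order.
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  if (nrow(records) == 0L) return(records)
  if (!is.null(ld)) {
    validate_ld_matrix(ld)
    absent <- setdiff(records$snp_id, rownames(ld))
    if (length(absent))
      message(sprintf("clump: %d SNP(s) absent from the LD matrix treated as independent",
                      length(absent)))
  }
  ord <- order(records$pval, records$snp_id)
  ids <- records$snp_id
  chrom <- if ("chrom" %in% names(records)) as.character(records$chrom)
           else rep(NA_character_, nrow(records))
  pos <- if ("pos" %in% names(records)) records$pos
         else rep(NA_real_, nrow(records))

  in_ld <- if (is.null(ld)) rep(FALSE, nrow(records))
           else ids %in% rownames(ld)
  window_bp <- window_kb * 1000

  accepted <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (a in accepted) {
      if (!(in_ld[i] && in_ld[a])) next
      r2 <- ld[ids[i], ids[a]]^2
      if (r2 < r2_threshold) next
      same_window <- TRUE
      if (!is.na(chrom[i]) && !is.na(chrom[a]) &&
          !is.na(pos[i]) && !is.na(pos[a])) {
        same_window <- chrom[i] == chrom[a] &&
          abs(pos[i] - pos[a]) <= window_bp
      }
      if (same_window) { conflict <- TRUE; break }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  out <- records[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-instrument F statistic
#'
#' The per-SNP approximation of the first-stage F statistic,
#' `F = (beta/se)^2`. Values above 10 are conventionally taken to indicate
#' a non-weak instrument.
#'
#' @param beta,se per-SNP effect and standard error (vectorized).
#' @return numeric vector of F statistics.
#' @seealso [f_from_r2()] for the variance-explained form.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop_mr("se must be positive")
  (beta / se)^2
}

#' F statistic from variance explained
#'
#' The exact single-regressor form `F = (n - 2) * r2 / (1 - r2)`. With
#' `r2 = t^2 / (t^2 + n - 2)` this reproduces [f_statistic()] identically;
#' with an allele-frequency-based `r2 = 2 * eaf * (1 - eaf) * beta^2` (for a
#' standardized trait) it gives the variance-explained alternative.
#'
#' @param r2 per-SNP variance explained, in [0, 1).
#' @param n sample size.
#' @return numeric vector of F statistics.
#' @export
f_from_r2 <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop_mr("r2 must lie in [0, 1)")
  (n - 2) * r2 / (1 - r2)
}

# Variance explained by one SNP from its t statistic.
r2_from_t <- function(t, n) t^2 / (t^2 + n - 2)

#' Steiger directionality filter
#'
#' Removes SNPs more strongly associated with the outcome than with the
#' exposure — the signature of reverse causation. For each SNP the variance
#' explained on either side is `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta/se`; a SNP is retained when `r2_exposure > r2_outcome` and the
#' one-sided test on the Fisher-transformed correlations is significant at
#' `alpha`.
#'
#' @param h a `harmonized_set`.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes; default to
#'   the per-SNP `n_exp`/`n_out` columns of `h`.
#' @param alpha significance level of the direction test.
#' @return the filtered `harmonized_set`, with a `"steiger"` attribute
#'   holding the per-SNP r-squared values, test p-values and decisions.
#' @export
steiger_filter <- function(h, n_exp = NULL, n_out = NULL, alpha = 0.05) {
  n_exp <- n_exp %||% h$n_exp
  n_out <- n_out %||% h$n_out
  if (is.null(n_exp) || is.null(n_out) ||
      any(!is.finite(n_exp)) || any(!is.finite(n_out)))
    stop_mr("steiger_filter requires exposure and outcome sample sizes")
  if (any(n_exp <= 3) || any(n_out <= 3)) stop_mr("sample sizes must exceed 3")

  t_exp <- h$beta_exp / h$se_exp
  t_out <- h$beta_out / h$se_out
  r2_exp <- r2_from_t(t_exp, n_exp)
  r2_out <- r2_from_t(t_out, n_out)
  r_exp <- pmin(sqrt(r2_exp), 1 - 1e-12)
  r_out <- pmin(sqrt(r2_out), 1 - 1e-12)

  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p_dir <- pnorm(-z)  # one-sided: H1 is rho_exposure > rho_outcome
  retained <- r2_exp > r2_out & p_dir < alpha

  detail <- data.frame(snp_id = h$snp_id, r2_exp = r2_exp, r2_out = r2_out,
                       steiger_z = z, steiger_p = p_dir, retained = retained,
                       stringsAsFactors = FALSE)
  if (!any(retained))
    stop_mr("Steiger filtering removed all SNPs: no instruments with a defensible exposure-to-outcome direction")
  if (any(!retained))
    message(sprintf("steiger_filter: removed %d of %d SNP(s)",
                    sum(!retained), length(retained)))
  out <- subset_harmonized(h, retained)
  out$r2_exp <- r2_exp[retained]
  out$r2_out <- r2_out[retained]
  attr(out, "steiger") <- detail
  out
}

#' Write an LD correlation matrix
#'
#' Tab-separated square matrix; the first row and first column carry the
#' SNP identifiers, cells are correlations r (not r-squared).
#'
#' @param ld square correlation matrix with SNP-id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  df <- data.frame(SNP = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD correlation matrix
#'
#' @param path path to a matrix written by [write_ld_matrix()].
#' @return a validated square correlation matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- read.delim(open_input(path), sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}
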