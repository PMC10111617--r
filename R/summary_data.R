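# GWAS summary statistics: canonical representation, I/O and harmonization.
#
# A summary-statistics table is a plain data.frame with one row per SNP and
# the canonical columns below. Coordinates are 1-based; chromosomes are
# stored as character so "X" is admissible; binary-trait betas are log odds
# ratios.

CANONICAL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

MANDATORY_COLS <- c("snp_id", "effect_allele", "other_allele",
                    "beta", "se", "pval")

# Default mapping canonical name -> file header (the package's own TSV
# dialect). UKB/FinnGen-style headers can be mapped via `column_map`.
DEFAULT_HEADERS <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
                     effect_allele = "EA", other_allele = "OA",
                     eaf = "EAF", beta = "BETA", se = "SE",
                     pval = "P", n = "N")

BASES <- c("A", "C", "G", "T")

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) ea == complement_allele(oa)

open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-separated summary-statistics file (optionally
#' gzip-compressed) into the canonical per-SNP representation. Alleles are
#' uppercased; indels and multi-allelic rows, rows with unparsable beta/se,
#' and rows with identical alleles are rejected (the rejection count is
#' reported via [message()] and stored in the `"n_rejected"` attribute).
#' Missing p-values are reconstituted as the two-sided Gaussian tail of
#' `beta/se`; p-values grossly inconsistent with `beta/se` trigger a warning
#' but are kept as read.
#'
#' @param path path to the file. `.gz` suffixes are decompressed
#'   transparently.
#' @param column_map optional named character vector mapping canonical
#'   column names (`snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the headers used
#'   in the file; unspecified entries fall back to the package defaults
#'   (`SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`).
#' @return a data.frame with the canonical columns, one row per retained
#'   SNP, with attribute `n_rejected`.
#' @seealso [write_summary_stats()], [harmonize()]
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_mr("file not found: %s", path)
  map <- DEFAULT_HEADERS
  if (!is.null(column_map)) {
    cm <- unlist(column_map)
    unknown <- setdiff(names(cm), CANONICAL_COLS)
    if (length(unknown))
      stop_mr("unknown canonical column(s) in column_map: %s",
              paste(unknown, collapse = ", "))
    map[names(cm)] <- cm
  }

  con <- open_input(path)
  first <- readLines(con, n = 1L)
  close(con)
  if (!length(first)) stop_mr("empty file: %s", path)
  sep <- if (grepl("\t", first)) "\t" else ","

  raw <- read.delim(open_input(path), sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)

  for (col in MANDATORY_COLS) {
    if (!(map[[col]] %in% names(raw)))
      stop_mr("missing mandatory column '%s' (expected header '%s')",
              col, map[[col]])
  }

  get_col <- function(col) {
    if (map[[col]] %in% names(raw)) raw[[map[[col]]]] else rep(NA, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(as.character(x)))

  out <- data.frame(
    snp_id        = as.character(get_col("snp_id")),
    chrom         = as.character(get_col("chrom")),
    pos           = num(get_col("pos")),
    effect_allele = toupper(trimws(as.character(get_col("effect_allele")))),
    other_allele  = toupper(trimws(as.character(get_col("other_allele")))),
    eaf           = num(get_col("eaf")),
    beta          = num(get_col("beta")),
    se            = num(get_col("se")),
    pval          = num(get_col("pval")),
    n             = num(get_col("n")),
    stringsAsFactors = FALSE
  )

  snp_only <- out$effect_allele %in% BASES & out$other_allele %in% BASES
  valid <- is.finite(out$beta) & is.finite(out$se) & out$se > 0 &
    snp_only & out$effect_allele != out$other_allele
  n_rejected <- sum(!valid)
  if (n_rejected > 0)
    message(sprintf("read_summary_stats: rejected %d of %d rows (unparsable beta/se, non-positive se, indel/multi-allelic or degenerate alleles)",
                    n_rejected, nrow(out)))
  out <- out[valid, , drop = FALSE]

  bad_p <- !is.finite(out$pval) | out$pval <= 0 | out$pval > 1
  if (any(bad_p)) {
    out$pval[bad_p] <- clamp_p(two_sided_p(out$beta[bad_p], out$se[bad_p]))
    message(sprintf("read_summary_stats: reconstituted %d p-value(s) from beta/se",
                    sum(bad_p)))
  }

  # Consistency check (warn, never reject): GWAS p-values may come from
  # non-Wald tests, so the tolerance is a full order of magnitude.
  expected <- clamp_p(two_sided_p(out$beta, out$se))
  ok <- bad_p | expected < 1e-300 |
    abs(log10(out$pval) - log10(expected)) <= 1
  if (any(!ok))
    warning(sprintf("%d p-value(s) inconsistent with |beta/se| under the Gaussian approximation",
                    sum(!ok)), call. = FALSE)

  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write GWAS summary statistics
#'
#' Serializes records to the canonical tab-separated dialect with fixed
#' column order `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`; missing
#' values are written as `NA`. A write–read–write cycle is byte-identical.
#'
#' @param records data.frame with the canonical columns (see
#'   [read_summary_stats()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L)
    stop_mr("no records to write")
  missing_cols <- setdiff(CANONICAL_COLS, names(records))
  for (col in missing_cols) records[[col]] <- NA
  out <- records[, CANONICAL_COLS]
  names(out) <- DEFAULT_HEADERS[CANONICAL_COLS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect allele for the
#' SNPs present in both datasets. Matching alleles are kept as-is; swapped
#' alleles flip the sign of the outcome beta (and reflect the outcome
#' allele frequency); strand-complement pairs are complemented first and
#' then matched the same way. Palindromic (A/T and C/G) SNPs cannot be
#' oriented from alleles alone and are removed unconditionally; allele
#' pairs still irreconcilable after complementing are dropped with a
#' warning.
#'
#' @param exposure,outcome canonical summary-statistics data.frames (see
#'   [read_summary_stats()]).
#' @param palindrome_policy how to treat palindromic SNPs; only `"drop"`
#'   is implemented.
#' @return a `harmonized_set`: a data.frame with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `pval_exp`,
#'   `eaf_exp`, `n_exp`, `beta_out`, `se_out`, `pval_out`, `eaf_out`,
#'   `n_out`, and attributes `n_dropped_palindromic`, `n_flipped` and
#'   `n_dropped_incompatible`.
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = "drop") {
  palindrome_policy <- match.arg(palindrome_policy, "drop")
  for (d in list(exposure, outcome)) {
    miss <- setdiff(MANDATORY_COLS, names(d))
    if (length(miss))
      stop_mr("input lacks column(s): %s", paste(miss, collapse = ", "))
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop_mr("no shared SNPs between exposure and outcome")

  e <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  pal <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  n_pal <- sum(pal)
  e <- e[!pal, , drop = FALSE]
  o <- o[!pal, , drop = FALSE]
  if (nrow(e) == 0L)
    stop_mr("no SNPs remain after removing %d palindromic SNP(s)", n_pal)

  direct    <- o$effect_allele == e$effect_allele &
               o$other_allele  == e$other_allele
  swapped   <- o$effect_allele == e$other_allele &
               o$other_allele  == e$effect_allele
  comp_dir  <- complement_allele(o$effect_allele) == e$effect_allele &
               complement_allele(o$other_allele)  == e$other_allele
  comp_swap <- complement_allele(o$effect_allele) == e$other_allele &
               complement_allele(o$other_allele)  == e$effect_allele

  keep <- direct | comp_dir
  flip <- !keep & (swapped | comp_swap)
  incompatible <- !(keep | flip)
  if (any(incompatible))
    warning(sprintf("dropped %d SNP(s) with irreconcilable alleles",
                    sum(incompatible)), call. = FALSE)

  sel <- keep | flip
  e <- e[sel, , drop = FALSE]
  o <- o[sel, , drop = FALSE]
  flip <- flip[sel]
  if (nrow(e) == 0L) stop_mr("no SNPs remain after harmonization")

  eaf_out <- o$eaf %||% rep(NA_real_, nrow(o))
  h <- data.frame(
    snp_id        = e$snp_id,
    chrom         = if ("chrom" %in% names(e)) as.character(e$chrom) else NA_character_,
    pos           = if ("pos" %in% names(e)) e$pos else NA_real_,
    effect_allele = e$effect_allele,
    other_allele  = e$other_allele,
    beta_exp      = e$beta,
    se_exp        = e$se,
    pval_exp      = e$pval,
    eaf_exp       = if ("eaf" %in% names(e)) e$eaf else NA_real_,
    n_exp         = if ("n" %in% names(e)) e$n else NA_real_,
    beta_out      = ifelse(flip, -o$beta, o$beta),
    se_out        = o$se,
    pval_out      = o$pval,
    eaf_out       = ifelse(flip, 1 - eaf_out, eaf_out),
    n_out         = if ("n" %in% names(o)) o$n else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  as_harmonized_set(h,
                    n_dropped_palindromic = n_pal,
                    n_flipped = sum(flip),
                    n_dropped_incompatible = sum(incompatible))
}

#' Construct a harmonized set from a data.frame
#'
#' Low-level constructor used by [harmonize()] and by the simulator/tests
#' when per-SNP effect pairs are already aligned to a common effect allele.
#'
#' @param h data.frame with at least `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @param n_dropped_palindromic,n_flipped,n_dropped_incompatible
#'   harmonization provenance counts.
#' @return `h` with class `harmonized_set` and provenance attributes.
#' @export
as_harmonized_set <- function(h, n_dropped_palindromic = 0L, n_flipped = 0L,
                              n_dropped_incompatible = 0L) {
  required <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(required, names(h))
  if (length(miss))
    stop_mr("harmonized set lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(h) < 1L) stop_mr("harmonized set must contain at least one SNP")
  if (any(!is.finite(h$se_exp)) || any(h$se_exp <= 0) ||
      any(!is.finite(h$se_out)) || any(h$se_out <= 0))
    stop_mr("standard errors must be strictly positive")
  if (!("pval_exp" %in% names(h)))
    h$pval_exp <- clamp_p(two_sided_p(h$beta_exp, h$se_exp))
  if (!("pval_out" %in% names(h)))
    h$pval_out <- clamp_p(two_sided_p(h$beta_out, h$se_out))
  structure(h,
            class = c("harmonized_set", "data.frame"),
            n_dropped_palindromic = n_dropped_palindromic,
            n_flipped = n_flipped,
            n_dropped_incompatible = n_dropped_incompatible)
}

# Subset a harmonized set while preserving class and provenance attributes.
subset_harmonized <- function(h, idx) {
  out <- as.data.frame(h)[idx, , drop = FALSE]
  rownames(out) <- NULL
  as_harmonized_set(out,
                    n_dropped_palindromic = attr(h, "n_dropped_palindromic") %||% 0L,
                    n_flipped = attr(h, "n_flipped") %||% 0L,
                    n_dropped_incompatible = attr(h, "n_dropped_incompatible") %||% 0L)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized exposure/outcome set: %d SNPs (%d palindromic dropped, %d flipped)\n",
              nrow(x), attr(x, "n_dropped_palindromic") %||% 0L,
              attr(x, "n_flipped") %||% 0L))
  print(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
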