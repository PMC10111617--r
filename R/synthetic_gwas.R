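# Summary-level GWAS simulator with the mediation causal structure
# G -> X -> M -> Y plus a direct X -> Y path. Effects are generated directly
# on the summary-statistic scale (log-OR for the binary outcome, with a
# case/control-adjusted standard error) because that is what two-sample MR
# consumes; no individual-level genotypes are simulated.
#
# Default sizes emulate the three-cohort design the package targets: a
# ~497k quantitative exposure GWAS with 45 instruments, a ~194k mediator
# GWAS with 50 instruments of its own, and a binary-outcome cohort of
# 6,303 cases / 325,717 controls.

PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2L, byrow = TRUE)
NONPAL_PAIRS <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                         "T", "G", "G", "T", "T", "C", "C", "T"),
                       ncol = 2L, byrow = TRUE)

#' Simulation configuration
#'
#' Builds and validates the parameter set of the summary-statistics
#' simulator. The defaults are the package's reference study conditions:
#' 45 exposure-instrument loci at UK-Biobank scale, 50 mediator-instrument
#' loci, a FinnGen-scale case/control outcome, per-SNP heritability 0.1%,
#' exposure-to-mediator effect 0.06, mediator log-OR log(1.25) and direct
#' log-OR 0.22 (so the true proportion mediated is about 5.7%).
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param n_snp_causal number of exposure-instrument loci.
#' @param n_snp_mediator number of loci instrumenting the mediator
#'   directly (needed for the mediator-to-outcome step of two-step MR).
#' @param n_snp_null number of null loci (no true effect anywhere).
#' @param n_exp,n_med exposure and mediator GWAS sample sizes.
#' @param n_case,n_control outcome GWAS cases and controls; `n_out` is
#'   their sum and the outcome log-OR standard errors use the effective
#'   sample size `n_case * n_control / n_out`.
#' @param beta_xm true exposure-to-mediator effect (a), in mediator SD per
#'   exposure SD.
#' @param beta_my true mediator-to-outcome log odds ratio (b).
#' @param beta_xy_direct true direct exposure-to-outcome log odds ratio
#'   (c'); the total effect is `a * b + c'`.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param per_snp_h2 expected per-SNP variance explained in its primary
#'   trait, in (0, 1).
#' @param pleiotropy list with `mode` (`"none"`, `"balanced"` or
#'   `"directional"`), `sd` and `offset`: a per-SNP horizontal-pleiotropy
#'   term added to the outcome effects of the exposure-instrument loci
#'   (balanced: Normal(0, sd^2); directional: offset plus that noise).
#' @param n_outlier_snps,outlier_scale number of exposure-instrument loci
#'   receiving an extra outcome offset of `outlier_scale` outcome standard
#'   errors (random sign).
#' @param frac_palindromic fraction of SNPs assigned A/T or C/G allele
#'   pairs.
#' @param ld_blocks optional list of `list(size =, r2 =)` entries; each
#'   block adds `size - 1` proxy SNPs tagging one exposure-instrument
#'   locus with correlation `sqrt(r2)`.
#' @param reverse_causal_snps number of loci whose primary effect is on
#'   the outcome (reverse causation).
#' @param reverse_backprop fraction of a reverse-causal SNP's outcome
#'   effect that leaks back into the exposure associations.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_snp_causal = 45L,
                              n_snp_mediator = 50L,
                              n_snp_null = 50L,
                              n_exp = 496946L,
                              n_med = 194453L,
                              n_case = 6303L,
                              n_control = 325717L,
                              beta_xm = 0.06,
                              beta_my = log(1.25),
                              beta_xy_direct = 0.22,
                              maf_range = c(0.05, 0.5),
                              per_snp_h2 = 0.001,
                              pleiotropy = list(mode = "none", sd = 0,
                                                offset = 0),
                              n_outlier_snps = 0L,
                              outlier_scale = 0,
                              frac_palindromic = 0,
                              ld_blocks = NULL,
                              reverse_causal_snps = 0L,
                              reverse_backprop = 0.3) {
  if (missing(seed)) stop_mr("simulation_config requires a seed")
  cfg <- list(seed = as.integer(seed),
              n_snp_causal = as.integer(n_snp_causal),
              n_snp_mediator = as.integer(n_snp_mediator),
              n_snp_null = as.integer(n_snp_null),
              n_exp = as.numeric(n_exp), n_med = as.numeric(n_med),
              n_case = as.numeric(n_case), n_control = as.numeric(n_control),
              n_out = as.numeric(n_case) + as.numeric(n_control),
              beta_xm = beta_xm, beta_my = beta_my,
              beta_xy_direct = beta_xy_direct,
              maf_range = as.numeric(maf_range),
              per_snp_h2 = per_snp_h2,
              pleiotropy = modifyList(list(mode = "none", sd = 0, offset = 0),
                                      pleiotropy),
              n_outlier_snps = as.integer(n_outlier_snps),
              outlier_scale = outlier_scale,
              frac_palindromic = frac_palindromic,
              ld_blocks = ld_blocks,
              reverse_causal_snps = as.integer(reverse_causal_snps),
              reverse_backprop = reverse_backprop)

  with(cfg, {
    if (n_snp_causal < 0 || n_snp_mediator < 0 || n_snp_null < 0 ||
        reverse_causal_snps < 0)
      stop_mr("SNP counts must be non-negative")
    if (n_snp_causal + n_snp_mediator + n_snp_null + reverse_causal_snps < 1)
      stop_mr("at least one SNP must be simulated")
    if (n_exp < 2 || n_med < 2 || n_case < 1 || n_control < 1)
      stop_mr("sample sizes too small")
    if (per_snp_h2 <= 0 || per_snp_h2 >= 1)
      stop_mr("per_snp_h2 must lie in (0, 1)")
    if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
        maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L])
      stop_mr("maf_range must be an increasing interval within (0, 0.5]")
    if (frac_palindromic < 0 || frac_palindromic > 1)
      stop_mr("frac_palindromic must lie in [0, 1]")
    if (!pleiotropy$mode %in% c("none", "balanced", "directional"))
      stop_mr("pleiotropy mode must be none, balanced or directional")
    if (n_outlier_snps > n_snp_causal)
      stop_mr("n_outlier_snps cannot exceed n_snp_causal")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a three-cohort summary-statistics study
#'
#' Generates exposure, mediator and outcome GWAS summary statistics under
#' the causal structure G -> X -> M -> Y with a direct X -> Y path. Per
#' locus, a true effect on its primary trait is drawn as
#' Normal(0, h2 / (2 maf (1 - maf))) — so the expected variance explained
#' equals `per_snp_h2` — and propagated along the causal paths; observed
#' betas add Gaussian noise with the analytic standard errors
#' `1 / sqrt(2 maf (1 - maf) n)` (outcome: effective case/control n).
#' Effect alleles are labelled so the primary-trait effect is
#' non-negative. Optional features inject horizontal pleiotropy, outcome
#' outliers, palindromic allele pairs, LD proxy blocks and reverse-causal
#' loci.
#'
#' @param config a `simulation_config`.
#' @return an object of class `synthetic_study`: a list with canonical
#'   summary-statistics data.frames `exposure`, `mediator`, `outcome`, an
#'   LD correlation matrix `ld`, the generating `truth` (effects,
#'   per-locus roles, special-SNP ids) and the echoed `config`.
#' @export
simulate_gwas <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_mr("config must be built by simulation_config()")
  cfg <- config
  withr::with_seed(cfg$seed, simulate_gwas_impl(cfg))
}

simulate_gwas_impl <- function(cfg) {
  nc <- cfg$n_snp_causal; nm <- cfg$n_snp_mediator
  nr <- cfg$reverse_causal_snps; nn <- cfg$n_snp_null
  n_base <- nc + nm + nr + nn
  role <- rep(c("causal", "mediator_instrument", "reverse", "null"),
              times = c(nc, nm, nr, nn))

  maf <- runif(n_base, cfg$maf_range[1L], cfg$maf_range[2L])
  het <- 2 * maf * (1 - maf)
  # primary-trait true effect, oriented to the trait-increasing allele
  gamma <- abs(rnorm(n_base, 0, sqrt(cfg$per_snp_h2 / het)))
  gamma[role == "null"] <- 0

  a <- cfg$beta_xm; b <- cfg$beta_my; c_dir <- cfg$beta_xy_direct
  total <- a * b + c_dir
  n_eff_out <- cfg$n_case * cfg$n_control / cfg$n_out

  se_x <- 1 / sqrt(het * cfg$n_exp)
  se_m <- 1 / sqrt(het * cfg$n_med)
  se_y <- 1 / sqrt(het * n_eff_out)

  pleio_y <- numeric(n_base)
  causal_idx <- which(role == "causal")
  if (cfg$pleiotropy$mode == "balanced") {
    pleio_y[causal_idx] <- rnorm(nc, 0, cfg$pleiotropy$sd)
  } else if (cfg$pleiotropy$mode == "directional") {
    pleio_y[causal_idx] <- cfg$pleiotropy$offset +
      rnorm(nc, 0, cfg$pleiotropy$sd)
  }

  outlier_idx <- integer(0)
  outlier_off <- numeric(n_base)
  if (cfg$n_outlier_snps > 0L) {
    outlier_idx <- sample(causal_idx, cfg$n_outlier_snps)
    outlier_off[outlier_idx] <- cfg$outlier_scale * se_y[outlier_idx] *
      sample(c(-1, 1), cfg$n_outlier_snps, replace = TRUE)
  }

  mean_x <- mean_m <- mean_y <- numeric(n_base)
  is_c <- role == "causal"; is_m <- role == "mediator_instrument"
  is_r <- role == "reverse"
  mean_x[is_c] <- gamma[is_c]
  mean_m[is_c] <- a * gamma[is_c]
  mean_y[is_c] <- total * gamma[is_c] + pleio_y[is_c] + outlier_off[is_c]
  mean_m[is_m] <- gamma[is_m]
  mean_y[is_m] <- b * gamma[is_m]
  mean_y[is_r] <- gamma[is_r]
  mean_x[is_r] <- cfg$reverse_backprop * gamma[is_r]

  # LD proxy blocks: each block tags one exposure-instrument locus; proxies
  # carry the tag's true effects scaled by r and share its allele frequency.
  proxy <- list(tag = integer(0), r = numeric(0))
  if (!is.null(cfg$ld_blocks)) {
    if (nc == 0L) stop_mr("ld_blocks require exposure-instrument loci to tag")
    tag_pool <- rep(causal_idx, length.out = length(cfg$ld_blocks))
    for (i in seq_along(cfg$ld_blocks)) {
      blk <- cfg$ld_blocks[[i]]
      size <- as.integer(blk$size %||% blk[[1L]])
      r2 <- as.numeric(blk$r2 %||% blk[[2L]])
      if (size < 2L) next
      if (r2 < 0 || r2 > 1) stop_mr("ld block r2 must lie in [0, 1]")
      proxy$tag <- c(proxy$tag, rep(tag_pool[i], size - 1L))
      proxy$r <- c(proxy$r, rep(sqrt(r2), size - 1L))
    }
  }
  n_proxy <- length(proxy$tag)
  n_all <- n_base + n_proxy
  if (n_proxy > 0L) {
    maf <- c(maf, maf[proxy$tag])
    het <- c(het, het[proxy$tag])
    se_x <- c(se_x, se_x[proxy$tag])
    se_m <- c(se_m, se_m[proxy$tag])
    se_y <- c(se_y, se_y[proxy$tag])
    mean_x <- c(mean_x, proxy$r * mean_x[proxy$tag])
    mean_m <- c(mean_m, proxy$r * mean_m[proxy$tag])
    mean_y <- c(mean_y, proxy$r * mean_y[proxy$tag])
    role <- c(role, rep("ld_proxy", n_proxy))
  }

  beta_x <- rnorm(n_all, mean_x, se_x)
  beta_m <- rnorm(n_all, mean_m, se_m)
  beta_y <- rnorm(n_all, mean_y, se_y)

  snp_id <- sprintf("rs%05d", seq_len(n_all))
  chrom <- as.character(rep_len(1:22, n_all))
  pos <- 1e6 * seq_len(n_all)
  if (n_proxy > 0L) {
    # proxies sit next to their tag, inside any sensible clumping window
    chrom[(n_base + 1L):n_all] <- chrom[proxy$tag]
    pos[(n_base + 1L):n_all] <- pos[proxy$tag] + 1000 * seq_len(n_proxy)
  }

  n_pal <- round(cfg$frac_palindromic * n_all)
  pal_idx <- if (n_pal > 0L) sample.int(n_all, n_pal) else integer(0)
  pair_idx <- sample.int(nrow(NONPAL_PAIRS), n_all, replace = TRUE)
  ea <- NONPAL_PAIRS[pair_idx, 1L]
  oa <- NONPAL_PAIRS[pair_idx, 2L]
  if (n_pal > 0L) {
    ppair <- sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE)
    ea[pal_idx] <- PALINDROMIC_PAIRS[ppair, 1L]
    oa[pal_idx] <- PALINDROMIC_PAIRS[ppair, 2L]
  }

  ld <- diag(n_all)
  dimnames(ld) <- list(snp_id, snp_id)
  if (n_proxy > 0L) {
    for (j in seq_len(n_proxy)) {
      pj <- n_base + j
      tj <- proxy$tag[j]
      ld[pj, tj] <- ld[tj, pj] <- proxy$r[j]
      same_tag <- which(proxy$tag == proxy$tag[j])
      for (k in same_tag) {
        pk <- n_base + k
        if (pk != pj) ld[pj, pk] <- ld[pk, pj] <- proxy$r[j] * proxy$r[k]
      }
    }
  }

  make_stats <- function(beta, se, n) {
    data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = maf,
               beta = beta, se = se,
               pval = clamp_p(two_sided_p(beta, se)),
               n = rep(n, n_all), stringsAsFactors = FALSE)
  }

  truth <- list(
    a = a, b = b, c_direct = c_dir, total = total,
    proportion_mediated = if (total != 0) a * b / total else NA_real_,
    causal_ids = snp_id[role == "causal"],
    mediator_instrument_ids = snp_id[role == "mediator_instrument"],
    reverse_ids = snp_id[role == "reverse"],
    null_ids = snp_id[role == "null"],
    ld_proxy_ids = snp_id[role == "ld_proxy"],
    outlier_ids = snp_id[outlier_idx],
    palindromic_ids = snp_id[pal_idx],
    effects = data.frame(snp_id = snp_id, role = role, maf = maf,
                         mean_exp = mean_x, mean_med = mean_m,
                         mean_out = mean_y, se_exp = se_x, se_med = se_m,
                         se_out = se_y, stringsAsFactors = FALSE)
  )
  stopifnot(isTRUE(all.equal(truth$total, truth$a * truth$b + truth$c_direct)))

  structure(list(exposure = make_stats(beta_x, se_x, cfg$n_exp),
                 mediator = make_stats(beta_m, se_m, cfg$n_med),
                 outcome = make_stats(beta_y, se_y, cfg$n_out),
                 ld = ld, truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  t <- x$truth
  cat(sprintf("Synthetic summary-statistics study: %d SNPs (seed %d)\n",
              nrow(x$exposure), x$config$seed))
  cat(sprintf("  truth: a = %.4f, b = %.4f, c' = %.4f, total = %.4f, proportion mediated = %.2f%%\n",
              t$a, t$b, t$c_direct, t$total, 100 * t$proportion_mediated))
  cat(sprintf("  roles: %d causal, %d mediator-instrument, %d reverse, %d null, %d LD proxies\n",
              length(t$causal_ids), length(t$mediator_instrument_ids),
              length(t$reverse_ids), length(t$null_ids),
              length(t$ld_proxy_ids)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Serializes the three summary-statistics tables (`exposure.tsv`,
#' `mediator.tsv`, `outcome.tsv`), the LD matrix (`ld.tsv`) and the
#' generating truth plus configuration (`truth.json`) into a directory.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study")) stop_mr("not a synthetic_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(study$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(study$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(study$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(study$ld, file.path(dir, "ld.tsv"))
  truth <- study$truth
  truth$effects <- NULL  # per-SNP means are re-derivable; keep file small
  meta <- list(truth = truth,
               config = unclass(study$config))
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(dir)
}

#' Read a synthetic study from disk
#'
#' @param dir a directory written by [write_study()].
#' @return a list with `exposure`, `mediator`, `outcome`, `ld`, `truth`
#'   and `config` (the per-SNP truth table is not round-tripped).
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  structure(list(exposure = read_summary_stats(file.path(dir, "exposure.tsv")),
                 mediator = read_summary_stats(file.path(dir, "mediator.tsv")),
                 outcome = read_summary_stats(file.path(dir, "outcome.tsv")),
                 ld = read_ld_matrix(file.path(dir, "ld.tsv")),
                 truth = meta$truth, config = meta$config),
            class = "synthetic_study")
}
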