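# End-to-end orchestration of the three-step design: (1) MR of the exposure
# and of every candidate mediator against the outcome, (2) screening of the
# candidates on their outcome association, (3) two-step mediation MR for
# the retained mediators, with a machine-readable report.

#' Pipeline configuration
#'
#' Assembles and validates the tuning parameters of [run_pipeline()].
#'
#' @param p_threshold default instrument-selection p-value threshold.
#' @param p_threshold_overrides optional named numeric vector of per-trait
#'   thresholds (e.g. `c(A4 = 1e-5)` for instrument-poor traits).
#' @param clump_r2,clump_window_kb LD-clumping controls, see [clump()].
#' @param f_min minimum per-instrument F statistic (strict inequality).
#' @param steiger_alpha Steiger direction-test level, see [steiger_filter()].
#' @param ivw_model IVW error model, see [mr_ivw()].
#' @param wm_n_boot weighted-median bootstrap resamples.
#' @param presso_n_sim,presso_outlier_alpha MR-PRESSO controls.
#' @param screen_alpha mediator-screening level (strict inequality).
#' @param require_significant_total perform the mediation decomposition
#'   only when the total exposure-to-outcome effect is itself significant
#'   at `screen_alpha`. The proportion mediated is a ratio with the total
#'   effect in the denominator and is numerically meaningless when that
#'   denominator is indistinguishable from zero.
#' @param mediation_se `"delta"` or `"bootstrap"`, see [mediated_se()].
#' @param mediation_n_boot bootstrap resamples for the mediated-effect se.
#' @param step2_exclude_exposure_instruments drop, from the
#'   mediator-to-outcome instrument set, SNPs that are also genome-wide
#'   significant for the exposure. Their mediator-to-outcome ratios are
#'   inflated by the direct exposure path, which would bias the
#'   decomposition.
#' @param column_map optional column mapping passed to
#'   [read_summary_stats()] when inputs are file paths.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(p_threshold = 5e-8,
                            p_threshold_overrides = NULL,
                            clump_r2 = 0.001,
                            clump_window_kb = 10000,
                            f_min = 10,
                            steiger_alpha = 0.05,
                            ivw_model = "multiplicative_random",
                            wm_n_boot = 1000,
                            presso_n_sim = 1000,
                            presso_outlier_alpha = 0.05,
                            screen_alpha = 0.05,
                            require_significant_total = TRUE,
                            mediation_se = "delta",
                            mediation_n_boot = 1000,
                            step2_exclude_exposure_instruments = TRUE,
                            column_map = NULL) {
  cfg <- list(p_threshold = p_threshold,
              p_threshold_overrides = p_threshold_overrides,
              clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
              f_min = f_min, steiger_alpha = steiger_alpha,
              ivw_model = match.arg(ivw_model,
                                    c("multiplicative_random", "fixed")),
              wm_n_boot = wm_n_boot,
              presso_n_sim = presso_n_sim,
              presso_outlier_alpha = presso_outlier_alpha,
              screen_alpha = screen_alpha,
              require_significant_total = isTRUE(require_significant_total),
              mediation_se = match.arg(mediation_se,
                                       c("delta", "bootstrap")),
              mediation_n_boot = mediation_n_boot,
              step2_exclude_exposure_instruments =
                isTRUE(step2_exclude_exposure_instruments),
              column_map = column_map)
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1)
    stop_mr("p_threshold must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of
#' [pipeline_config()]; unspecified keys keep their defaults.
#'
#' @param path path to the YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_mr("unknown pipeline config key(s): %s",
            paste(unknown, collapse = ", "))
  if (!is.null(raw$p_threshold_overrides))
    raw$p_threshold_overrides <- unlist(raw$p_threshold_overrides)
  if (!is.null(raw$column_map)) raw$column_map <- unlist(raw$column_map)
  do.call(pipeline_config, raw)
}

trait_threshold <- function(config, trait) {
  ov <- config$p_threshold_overrides
  if (!is.null(ov) && trait %in% names(ov)) return(as.numeric(ov[[trait]]))
  config$p_threshold
}

run_stage <- function(stage, log, expr) {
  tryCatch(expr, error = function(e) {
    stop_mr("[stage %s] %s", stage, conditionMessage(e))
  })
}

# One exposure-or-mediator -> outcome MR analysis, through the full
# instrument-QC and estimation chain. `log` is an environment collecting
# per-stage messages.
analyse_pair <- function(iv_stats, out_stats, pair_name, threshold, ld,
                         config, seed, log) {
  note <- function(fmt, ...) {
    log$lines <- c(log$lines, sprintf("[%s] %s", pair_name, sprintf(fmt, ...)))
  }
  note("input: %d IV-side SNPs, %d outcome-side SNPs",
       nrow(iv_stats), nrow(out_stats))

  sel <- run_stage("select_by_pvalue", log,
                   select_by_pvalue(iv_stats, threshold))
  note("select_by_pvalue (p < %g): %d SNPs", threshold, nrow(sel))

  cl <- run_stage("clump", log,
                  clump(sel, ld = ld, r2_threshold = config$clump_r2,
                        window_kb = config$clump_window_kb))
  note("clump (r2 < %g, %d kb): %d SNPs", config$clump_r2,
       config$clump_window_kb, nrow(cl))

  h <- run_stage("harmonize", log, harmonize(cl, out_stats))
  note("harmonize: %d SNPs (%d palindromic dropped, %d flipped)",
       nrow(h), attr(h, "n_dropped_palindromic"), attr(h, "n_flipped"))

  f <- f_statistic(h$beta_exp, h$se_exp)
  strong <- f > config$f_min
  if (!any(strong))
    stop_mr("[stage f_filter] all instruments weak (F <= %g) for %s",
            config$f_min, pair_name)
  h <- subset_harmonized(h, strong)
  f <- f[strong]
  note("F filter (F > %g): %d SNPs, F range %.2f-%.2f", config$f_min,
       nrow(h), min(f), max(f))

  have_n <- all(is.finite(h$n_exp)) && all(is.finite(h$n_out))
  if (have_n) {
    h <- run_stage("steiger_filter", log,
                   suppressMessages(steiger_filter(h,
                                                   alpha = config$steiger_alpha)))
    f <- f_statistic(h$beta_exp, h$se_exp)
    note("steiger_filter (alpha %g): %d SNPs", config$steiger_alpha, nrow(h))
  } else {
    note("steiger_filter skipped: per-SNP sample sizes unavailable")
  }

  estimates <- run_stage("estimators", log,
                         mr_all(h, ivw_model = config$ivw_model,
                                n_boot = config$wm_n_boot,
                                seed = derive_seed(seed, 11L)))
  sens <- run_stage("sensitivity", log,
                    sensitivity_report(h, n_sim = config$presso_n_sim,
                                       outlier_alpha = config$presso_outlier_alpha,
                                       seed = derive_seed(seed, 23L)))
  note("estimates: %s", paste(names(estimates), collapse = ", "))

  list(pair = pair_name,
       instruments = list(n_significant = nrow(sel),
                          n_clumped = nrow(cl),
                          n_final = nrow(h),
                          f_range = c(min(f), max(f)),
                          p_threshold = threshold,
                          snp_ids = h$snp_id),
       estimates = estimates,
       sensitivity = sens,
       harmonized = h)
}

primary_estimate <- function(analysis) {
  analysis$estimates$ivw %||% analysis$estimates$wald_ratio
}

resolve_stats <- function(x, config) {
  if (is.character(x)) read_summary_stats(x, config$column_map) else x
}

#' Run the two-step MR mediation pipeline
#'
#' Executes the full design: instrument QC and MR of the exposure against
#' the outcome (total effect) and of every candidate mediator against the
#' outcome; screening of the candidates on their outcome association;
#' and, for each retained mediator, the exposure-to-mediator MR (step 1)
#' and the mediation decomposition with its uncertainty. Every stage logs
#' input/output counts; a stage failure aborts with the stage name.
#'
#' @param exposure exposure summary statistics (canonical data.frame or
#'   file path).
#' @param outcome outcome summary statistics (data.frame or path).
#' @param mediators named list of candidate-mediator summary statistics
#'   (data.frames or paths); may be empty.
#' @param ld optional LD correlation matrix (matrix or path); absent SNPs
#'   are treated as independent.
#' @param config a `pipeline_config`.
#' @param seed integer seed driving every stochastic component
#'   (weighted-median bootstrap, MR-PRESSO, mediation bootstrap).
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `estimates.tsv`, `instruments.tsv`, `sensitivity.json`,
#'   `funnel.tsv` and `logs.txt`. Reruns with the same inputs, config and
#'   seed produce byte-identical files.
#' @param exposure_name,outcome_name labels used in the report.
#' @return the pipeline report (a list; see [validate_report()]),
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(exposure, outcome, mediators = list(), ld = NULL,
                         config = pipeline_config(), seed = 1L,
                         out_dir = NULL,
                         exposure_name = "exposure",
                         outcome_name = "outcome") {
  if (!inherits(config, "pipeline_config"))
    stop_mr("config must be built by pipeline_config() or load_pipeline_config()")
  if (length(mediators) && (is.null(names(mediators)) ||
                            any(!nzchar(names(mediators)))))
    stop_mr("mediators must be a named list")
  exposure <- resolve_stats(exposure, config)
  outcome <- resolve_stats(outcome, config)
  mediators <- lapply(mediators, resolve_stats, config = config)
  if (is.character(ld)) ld <- read_ld_matrix(ld)

  log <- new.env(parent = emptyenv())
  log$lines <- character(0)

  exp_threshold <- trait_threshold(config, exposure_name)
  total_analysis <- analyse_pair(exposure, outcome,
                                 paste0(exposure_name, "->", outcome_name),
                                 exp_threshold, ld, config,
                                 derive_seed(seed, 1L), log)

  exposure_sig_ids <- exposure$snp_id[exposure$pval < exp_threshold]

  mediator_analyses <- list()
  for (m in names(mediators)) {
    med_stats <- mediators[[m]]
    if (config$step2_exclude_exposure_instruments) {
      overlap <- med_stats$snp_id %in% exposure_sig_ids
      if (any(overlap)) {
        log$lines <- c(log$lines,
                       sprintf("[%s->%s] excluded %d exposure-significant SNP(s) from the mediator instrument pool",
                               m, outcome_name, sum(overlap)))
        med_stats <- med_stats[!overlap, , drop = FALSE]
      }
    }
    mediator_analyses[[m]] <- analyse_pair(
      med_stats, outcome, paste0(m, "->", outcome_name),
      trait_threshold(config, m), ld, config,
      derive_seed(seed, 100L + match(m, names(mediators))), log)
  }

  screen_p <- vapply(mediator_analyses,
                     function(a) primary_estimate(a)$pval, numeric(1))
  retained <- if (length(screen_p)) {
    screen_mediators(screen_p, alpha = config$screen_alpha)
  } else {
    character(0)
  }
  log$lines <- c(log$lines,
                 sprintf("[screening] retained %d of %d candidate mediator(s) at p < %g: %s",
                         length(retained), length(mediator_analyses),
                         config$screen_alpha,
                         if (length(retained)) paste(retained, collapse = ", ")
                         else "none"))

  total_est <- primary_estimate(total_analysis)
  total_significant <- total_est$pval < config$screen_alpha
  do_mediation <- total_significant || !config$require_significant_total
  if (!do_mediation && length(retained))
    log$lines <- c(log$lines,
                   sprintf("[mediation] skipped: total effect not significant (p = %.3g >= %g), proportion mediated would be unstable",
                           total_est$pval, config$screen_alpha))

  mediation <- list()
  for (m in if (do_mediation) retained else character(0)) {
    step1 <- analyse_pair(exposure, mediators[[m]],
                          paste0(exposure_name, "->", m),
                          exp_threshold, ld, config,
                          derive_seed(seed, 200L + match(m, retained)), log)
    step1_est <- primary_estimate(step1)
    step2_est <- primary_estimate(mediator_analyses[[m]])
    dec <- mediate_decompose(total_est, step1_est, step2_est)
    unc <- mediated_se(step1_est, step2_est,
                       method = config$mediation_se,
                       n_boot = config$mediation_n_boot,
                       seed = derive_seed(seed, 300L + match(m, retained)))
    dec$se_mediated <- unc$se
    dec$ci_mediated <- c(unc$ci_low, unc$ci_high)
    dec$method_se <- unc$method
    mediation[[m]] <- list(step1 = serialize_analysis(step1),
                           result = unclass(dec))
    log$lines <- c(log$lines,
                   sprintf("[mediation %s] mediated = %.4f, direct = %.4f, proportion = %.2f%%",
                           m, dec$mediated_effect, dec$direct_effect,
                           100 * dec$proportion_mediated))
  }

  report <- list(
    software = "mrmediate",
    version = as.character(packageVersion("mrmediate")),
    seed = as.integer(seed),
    config = unclass(config),
    exposure = serialize_analysis(total_analysis),
    mediators = lapply(mediator_analyses, serialize_analysis),
    screening = list(alpha = config$screen_alpha,
                     p_values = as.list(screen_p),
                     retained = as.list(retained),
                     total_effect_p = total_est$pval,
                     mediation_performed = do_mediation),
    mediation = mediation
  )
  validate_report(report)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(report, total_analysis, mediator_analyses,
                           log, out_dir)
    return(invisible(report))
  }
  report
}

serialize_estimate <- function(est) unclass(est)

serialize_sensitivity <- function(sens) {
  out <- list(q_ivw = sens$q_ivw, q_egger = sens$q_egger,
              egger_intercept = sens$egger_intercept,
              n_simulations = sens$n_simulations, seed = sens$seed)
  if (!is.null(sens$presso)) {
    p <- sens$presso
    out$presso <- list(global_rss = p$global_rss, global_p = p$global_p,
                       outlier_snps = as.list(p$outlier_snps),
                       distortion_p = p$distortion_p,
                       n_sim = p$n_sim, seed = p$seed)
  }
  out
}

serialize_analysis <- function(analysis) {
  list(pair = analysis$pair,
       instruments = list(
         n_significant = analysis$instruments$n_significant,
         n_clumped = analysis$instruments$n_clumped,
         n_final = analysis$instruments$n_final,
         f_min = analysis$instruments$f_range[1L],
         f_max = analysis$instruments$f_range[2L],
         p_threshold = analysis$instruments$p_threshold,
         snp_ids = as.list(analysis$instruments$snp_ids)),
       estimates = lapply(analysis$estimates, serialize_estimate),
       sensitivity = serialize_sensitivity(analysis$sensitivity))
}

estimates_table <- function(analyses) {
  rows <- lapply(analyses, function(a) {
    do.call(rbind, lapply(a$estimates, function(e) {
      data.frame(pair = a$pair, method = e$method, nsnp = e$n_snp,
                 beta = e$beta, se = e$se, pval = e$pval, or = e$or,
                 ci_low = e$ci_low, ci_high = e$ci_high,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(report, total_analysis, mediator_analyses,
                                   log, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, file.path(out_dir, "report.json"))

  analyses <- c(list(total_analysis), mediator_analyses)
  write.table(estimates_table(analyses), file.path(out_dir, "estimates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  iv_rows <- do.call(rbind, lapply(analyses, function(a) {
    h <- a$harmonized
    data.frame(pair = a$pair, snp_id = h$snp_id, beta_exp = h$beta_exp,
               se_exp = h$se_exp, pval_exp = h$pval_exp,
               f_stat = f_statistic(h$beta_exp, h$se_exp),
               stringsAsFactors = FALSE)
  }))
  write.table(iv_rows, file.path(out_dir, "instruments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sens <- lapply(analyses, function(a) serialize_sensitivity(a$sensitivity))
  names(sens) <- vapply(analyses, `[[`, character(1), "pair")
  writeLines(jsonlite::toJSON(sens, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             file.path(out_dir, "sensitivity.json"))

  write.table(funnel_data(total_analysis$harmonized),
              file.path(out_dir, "funnel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(log$lines, file.path(out_dir, "logs.txt"))
  invisible(out_dir)
}

#' Validate a pipeline report
#'
#' Structural validation of a pipeline report (in memory or a
#' `report.json` path) against the schema shipped at
#' `inst/extdata/report_schema.json`: required top-level fields, required
#' per-analysis fields, and the guarantee that every retained mediator has
#' a mediation result.
#'
#' @param report a report list returned by [run_pipeline()], or a path to
#'   a `report.json`.
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "mrmediate"),
                                simplifyVector = TRUE)
  miss <- setdiff(schema$required, names(report))
  if (length(miss))
    stop_mr("report lacks required field(s): %s", paste(miss, collapse = ", "))
  check_analysis <- function(a, label) {
    miss <- setdiff(schema$analysis_required, names(a))
    if (length(miss))
      stop_mr("analysis '%s' lacks field(s): %s", label,
              paste(miss, collapse = ", "))
    miss_est <- setdiff(schema$estimate_required, names(a$estimates[[1L]]))
    if (length(miss_est))
      stop_mr("analysis '%s' estimate lacks field(s): %s", label,
              paste(miss_est, collapse = ", "))
  }
  check_analysis(report$exposure, "exposure")
  for (m in names(report$mediators)) check_analysis(report$mediators[[m]], m)
  if (isTRUE(report$screening$mediation_performed)) {
    retained <- unlist(report$screening$retained)
    missing_med <- setdiff(retained, names(report$mediation))
    if (length(missing_med))
      stop_mr("retained mediator(s) without a mediation result: %s",
              paste(missing_med, collapse = ", "))
  }
  invisible(TRUE)
}
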