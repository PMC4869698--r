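# End-to-end orchestration: simulate -> QC -> phenotype prep -> scan ->
# known-SNP subset tests -> grouped report, with per-stage logging.

#' Run configuration
#'
#' Built from a YAML file or an R list. Recognised fields:
#' `seed`, `out_dir`; either `simulate:` (a [sim_config()] field list,
#' plus optional `effects:` rows of `variant_index`/`beta_add`/
#' `beta_domdev`/`trait`) or `vcf:`/`phenotypes:` input paths;
#' optional `known_snps:` (TSV with `vid` and `trait` columns),
#' `qc:` threshold overrides, `genotype_mode:` and `report:` options
#' (`ci_digits`).
#'
#' @param x Path to a YAML config file, or a named list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$genotype_mode <- cfg$genotype_mode %||% "dosage"
  qc <- cfg$qc %||% list()
  cfg$qc <- qc_thresholds(min_info = qc$min_info %||% 0.9,
                          hwe_alpha = qc$hwe_alpha %||% 1e-6,
                          min_maf = qc$min_maf %||% 0.005)
  cfg$report <- cfg$report %||% list()
  cfg$report$ci_digits <- cfg$report$ci_digits %||% 2L
  if (is.null(cfg$simulate) && is.null(cfg$vcf))
    stop("config needs either a 'simulate' block or a 'vcf' path")
  for (p in c(cfg$vcf, cfg$phenotypes, cfg$known_snps))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_config_from_block <- function(block, seed) {
  effects <- lapply(block$effects %||% list(), function(e)
    planted_effect(e$variant_index, e$beta_add %||% 0,
                   e$beta_domdev %||% 0, e$trait %||% "bmi"))
  args <- block[setdiff(names(block), "effects")]
  args$effect_spec <- effects
  if (is.null(args$seed)) args$seed <- seed
  do.call(sim_config, args)
}

log_line <- function(log_path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Stages: (optional) simulation, variant QC, phenotype preparation,
#' dominance-deviation scan of inverse-normalised BMI (and of type 2
#' diabetes when enough cases are present), known-SNP subset tests with
#' Bonferroni thresholds, and a grouped-statistics report for the top
#' dominance-deviation hit. Each stage logs records in/out; outputs are
#' written under `config$out_dir` and the same config + seed always
#' reproduces byte-identical files.
#'
#' @param config A [run_config()], a path to a YAML config, or a list.
#' @return Invisible list with `results` (BMI scan data.frame), `lambda`,
#'   `qc`, `phenotypes`, `thresholds` and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(log = file.path(config$out_dir, "pipeline.log"),
                vcf = file.path(config$out_dir, "genotypes.vcf"),
                cohort = file.path(config$out_dir, "cohort.tsv"),
                qc = file.path(config$out_dir, "qc_reasons.tsv"),
                results = file.path(config$out_dir, "assoc_bmi.tsv"),
                report = file.path(config$out_dir, "report.md"))
  if (file.exists(paths$log)) file.remove(paths$log)
  log_line(paths$log, "run_pipeline seed=%d out_dir=%s", config$seed,
           config$out_dir)

  # -- stage: inputs (simulate or load) ------------------------------------
  if (!is.null(config$simulate)) {
    sc <- sim_config_from_block(config$simulate, config$seed)
    variants <- simulate_genotypes(sc)
    cohort <- simulate_phenotypes(sc, variants)
    write_vcf(variants, paths$vcf, sample_ids = cohort$sample_id)
    write_cohort_table(cohort, paths$cohort)
    log_line(paths$log, "simulate: %d variants x %d samples",
             length(variants), nrow(cohort))
  } else {
    vc <- read_vcf(config$vcf)
    variants <- vc$variants
    cohort <- read_cohort_table(config$phenotypes)
    log_line(paths$log, "load: %d variants, %d samples", length(variants),
             nrow(cohort))
  }

  # -- stage: variant QC ---------------------------------------------------
  qc <- apply_filters(variants, config$qc)
  data.table::fwrite(qc$reasons, paths$qc, sep = "\t", quote = FALSE)
  log_line(paths$log, "qc: %d in, %d pass, %d excluded", length(variants),
           length(qc$passing), length(variants) - length(qc$passing))
  if (!length(qc$passing))
    warning("no variants pass QC; scan output will be empty")

  # -- stage: phenotype prep ----------------------------------------------
  phen <- prepare_phenotypes(cohort)
  n_bmi <- sum(!is.na(phen$bmi_invnorm))
  log_line(paths$log, "prep: %d samples in, %d with analysable BMI, %d excluded",
           nrow(phen), n_bmi, sum(phen$exclusion_reason != ""))

  # -- stage: scan ---------------------------------------------------------
  covs <- cohort[intersect("chip", names(cohort))]
  if (ncol(covs) == 0 || length(unique(covs[[1]])) < 2) covs <- NULL
  scan <- scan_assoc(qc$passing, phen$bmi_invnorm, covariates = covs,
                     trait_kind = "quantitative",
                     mode = config$genotype_mode)
  write_results(scan$results, paths$results)
  log_line(paths$log, "scan[bmi]: %d variants tested, lambda=%.3f",
           nrow(scan$results), scan$lambda)

  # -- stage: known-SNP subset thresholds ---------------------------------
  thresholds <- list(gwa = bonferroni_threshold(0.05,
                                                max(1, nrow(scan$results))))
  known_hits <- NULL
  if (!is.null(config$known_snps)) {
    known <- as.data.frame(data.table::fread(config$known_snps, sep = "\t"))
    sub <- scan$results[scan$results$vid %in% known$vid, ]
    thr <- bonferroni_threshold(0.05, max(1, nrow(sub)))
    thresholds$known <- thr
    known_hits <- sub[!is.na(sub$p_domdev) &
                        sub$p_domdev < thr$threshold, ]
    log_line(paths$log, "known-SNP subset: %d tested, %d below %s",
             nrow(sub), nrow(known_hits), thr$rendered)
  }

  # -- stage: grouped report for the top domdev hit ------------------------
  top <- NULL
  if (nrow(scan$results) && any(!is.na(scan$results$p_domdev))) {
    i <- which.min(scan$results$p_domdev)
    top_vid <- scan$results$vid[i]
    v <- qc$passing[[which(vapply(qc$passing, `[[`, "", "vid") == top_vid)]]
    top <- list(vid = top_vid,
                class_summary = genotype_class_summary(v, phen$bmi_raw))
    log_line(paths$log, "top domdev hit: %s p=%.3g", top_vid,
             scan$results$p_domdev[i])
  }
  report <- make_report(scan$results, grouped = top,
                        thresholds = thresholds, qq = scan$qq,
                        lambda = scan$lambda,
                        ci_digits = config$report$ci_digits)
  writeLines(report, paths$report)
  log_line(paths$log, "report written to %s", paths$report)
  invisible(list(results = scan$results, lambda = scan$lambda, qc = qc,
                 phenotypes = phen, thresholds = thresholds, top = top,
                 paths = paths))
}

# Truncate toward zero at `digits` decimal places (the convention used for
# printed genotype-class CIs; see the methods vignette).
trunc_dp <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

fmt_dp <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Render a mean (95% CI) cell
#'
#' Means are rounded; CI bounds are truncated toward zero at `digits`
#' decimal places, reproducing the printing convention of genotype-class
#' tables (e.g. mean 27.27, CI (27.2257, 27.3143) renders as
#' `"27.27 (27.22, 27.31)"`).
#'
#' @param mean,ci_low,ci_high Numeric scalars.
#' @param digits Decimal places (default 2).
#' @return Character scalar.
#' @export
format_mean_ci <- function(mean, ci_low, ci_high, digits = 2) {
  sprintf("%s (%s, %s)", fmt_dp(round(mean, digits), digits),
          fmt_dp(trunc_dp(ci_low, digits), digits),
          fmt_dp(trunc_dp(ci_high, digits), digits))
}

#' Build a markdown report
#'
#' Emits the scan summary, a genotype-class mean/CI table for the top hit
#' (when given), an OR table block, QQ data and the significance
#' thresholds. With empty results a header-only report is produced.
#'
#' @param results Scan results data.frame.
#' @param grouped Optional list with `vid` and a `genotype_class_summary`.
#' @param or_tables Optional named list of [odds_ratio()] results.
#' @param thresholds Named list of [bonferroni_threshold()] results.
#' @param qq Optional QQ data.frame (`expected`, `observed`).
#' @param lambda Optional genomic-inflation factor.
#' @param ci_digits Decimal places for CI rendering.
#' @return Character vector of report lines.
#' @export
make_report <- function(results, grouped = NULL, or_tables = NULL,
                        thresholds = NULL, qq = NULL, lambda = NA,
                        ci_digits = 2) {
  out <- c("# Dominance-deviation analysis report", "")
  out <- c(out, sprintf("Variants tested: %d", nrow(results)))
  if (is.finite(lambda))
    out <- c(out, sprintf("Genomic inflation (domdev): %.3f", lambda))
  if (!is.null(thresholds)) {
    out <- c(out, "", "## Significance thresholds", "")
    for (nm in names(thresholds))
      out <- c(out, sprintf("- %s: %s (%.3g)", nm,
                            thresholds[[nm]]$rendered,
                            thresholds[[nm]]$threshold))
  }
  if (!is.null(grouped)) {
    cs <- grouped$class_summary
    out <- c(out, "", sprintf("## Genotype-class means: %s", grouped$vid),
             "", "| class | n | mean (95% CI) | SD |",
             "|---|---|---|---|")
    for (k in seq_len(nrow(cs))) {
      if (cs$n[k] == 0) next
      out <- c(out, sprintf("| %s | %d | %s | %s |", rownames(cs)[k],
                            cs$n[k],
                            format_mean_ci(cs$mean[k], cs$ci_low[k],
                                           cs$ci_high[k], ci_digits),
                            fmt_dp(cs$sd[k], ci_digits)))
    }
  }
  if (!is.null(or_tables)) {
    out <- c(out, "", "## Odds ratios", "",
             "| contrast | OR (95% CI) |", "|---|---|")
    for (nm in names(or_tables)) {
      o <- or_tables[[nm]]
      out <- c(out, sprintf("| %s | %s (%s, %s)%s |", nm,
                            fmt_dp(o$or), fmt_dp(o$ci_low),
                            fmt_dp(o$ci_high),
                            if (isTRUE(o$corrected)) " [0.5-corrected]"
                            else ""))
    }
  }
  if (!is.null(qq) && nrow(qq)) {
    out <- c(out, "", "## QQ data (top 10)", "",
             "| expected -log10 p | observed -log10 p |", "|---|---|")
    top <- utils::head(qq[order(-qq$observed), ], 10)
    for (k in seq_len(nrow(top)))
      out <- c(out, sprintf("| %.3f | %.3f |", top$expected[k],
                            top$observed[k]))
  }
  out
}
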