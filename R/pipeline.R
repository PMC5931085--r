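#' Configuration of a full pipeline run
#'
#' A run either simulates its inputs (`sim` = a [sim_config()]) or loads
#' them from files (`weights_path`, `dosages_path`, `phenotypes_path`,
#' `grouping_path`). Primary outcomes are pooled by DerSimonian-Laird over
#' per-study second-stage fits; secondary (subtype) outcomes use the single
#' study-stratified model.
#'
#' @param sim optional [sim_config()]; when given, inputs are simulated.
#' @param weights_path,dosages_path,phenotypes_path,grouping_path input
#'   files, used when `sim` is `NULL`.
#' @param primary_outcomes,secondary_outcomes case-definition labels (see
#'   [available_case_definitions()]).
#' @param subsets named list of score subsets; each element is `NULL` (the
#'   full QC-passing panel) or a list with `rule` and optionally
#'   `threshold`/`tags` for [grs_subset()].
#' @param min_imputation_r2 QC threshold for [qc_filter()].
#' @param egger,screen,conventional,bootstrap analysis toggles.
#' @param power_or odds ratio at which the design's power is reported.
#' @param seed integer seed (overrides `sim$seed` when simulating).
#' @param out_dir optional output directory; when given, all tables are
#'   written there with stable filenames.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       weights_path = NULL, dosages_path = NULL,
                       phenotypes_path = NULL, grouping_path = NULL,
                       primary_outcomes = c("all", "invasive", "borderline"),
                       secondary_outcomes = c("high_grade_serous",
                                              "lowgrade_borderline_serous",
                                              "mucinous", "endometrioid",
                                              "clear_cell"),
                       subsets = list(main = NULL),
                       min_imputation_r2 = 0.6,
                       egger = TRUE, screen = TRUE, conventional = TRUE,
                       bootstrap = FALSE,
                       power_or = 1.10,
                       seed = 1L, out_dir = NULL) {
  known <- available_case_definitions()
  bad <- setdiff(c(primary_outcomes, secondary_outcomes), known)
  if (length(bad)) {
    stop_bad_arg("outcomes", paste("unknown case definitions:",
                                   paste(bad, collapse = ", ")))
  }
  if (is.null(sim)) {
    paths <- c(weights_path, dosages_path, phenotypes_path)
    if (length(paths) < 3) {
      stop_bad_arg("sim", "either `sim` or all three input paths are required")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_bad_arg("paths", paste("not found:", paste(missing, collapse = ", ")))
    }
  }
  cfg <- list(sim = sim, weights_path = weights_path,
              dosages_path = dosages_path, phenotypes_path = phenotypes_path,
              grouping_path = grouping_path,
              primary_outcomes = primary_outcomes,
              secondary_outcomes = secondary_outcomes,
              subsets = subsets, min_imputation_r2 = min_imputation_r2,
              egger = egger, screen = screen, conventional = conventional,
              bootstrap = bootstrap, power_or = power_or,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# Stable hash of the numeric/structural content of a run configuration.
config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x, control = c("exact")), tmp)
  unname(tools::md5sum(tmp))
}

#' Execute the full MR pipeline
#'
#' Runs, in order: input simulation or loading; weight-table QC; score
#' construction (per requested subset); first stage with diagnostics;
#' per-study second stages pooled by DerSimonian-Laird for primary
#' outcomes; the single stratified model for secondary outcomes; optional
#' MR-Egger, confounder screen, conventional comparator and bootstrap; and
#' a power row. Any failing stage is recorded with the stage name in
#' `$errors` and the remaining stages still run; when `out_dir` is set the
#' (partial) report tables are written with stable filenames, each carrying
#' the configuration hash.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  report <- list(config_hash = hash, seed = config$seed,
                 outcomes = list(), errors = list(),
                 versions = list(
                   package = as.character(utils::packageVersion("heightmr")),
                   r = R.version.string))
  note_error <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    hm_log("stage %s failed: %s", stage, conditionMessage(e))
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    synth <- simulate_cohort(sim)
    weights <- synth$weight_table
    dosages <- synth$dosages
    cohort <- synth$cohort
    report$truth <- synth$truth
  } else {
    weights <- read_weight_table(config$weights_path)
    dosages <- read_dosages(config$dosages_path)
    cohort <- read_phenotypes(config$phenotypes_path)
    if (!is.null(config$grouping_path)) {
      cohort <- apply_grouping(cohort, read_grouping(config$grouping_path))
    } else if (!"group" %in% names(cohort)) {
      cohort$group <- cohort$study
    }
  }
  hm_log("inputs: %d SNPs, %d participants (%d cases / %d controls), %d studies in %d groups",
         nrow(weights), nrow(cohort), sum(cohort$status == 1),
         sum(cohort$status == 0), length(unique(cohort$study)),
         length(unique(cohort$group)))

  weights_qc <- qc_filter(weights, config$min_imputation_r2)

  for (subset_name in names(config$subsets)) {
    spec <- config$subsets[[subset_name]]
    w_sub <- if (is.null(spec)) weights_qc else {
      grs_subset(weights_qc, spec$rule, threshold = spec$threshold,
                 tags = spec$tags)
    }
    label <- sprintf("GRS-%d", nrow(w_sub))
    grs <- compute_grs(w_sub, dosages, subset_label = label)

    fit1 <- tryCatch(first_stage(grs, cohort), error = function(e) {
      note_error(paste0("first_stage/", subset_name), e); NULL
    })
    if (is.null(fit1)) next
    pred <- predict_height(fit1, grs)
    sub_report <- list(subset = subset_name, grs_label = label,
                       first_stage = fit1,
                       descriptives = tryCatch(grs_descriptives(grs, cohort),
                                               error = function(e) NULL))

    for (oc in config$primary_outcomes) {
      cd <- case_definition(oc)
      res <- tryCatch({
        est <- mr_study_estimates(pred, cohort, cd)
        meta <- dersimonian_laird(est)
        list(kind = "pooled", estimates = est, meta = meta,
             forest = forest_table(est, meta),
             or = or_per_5cm(meta$pooled_beta, meta$pooled_se))
      }, error = function(e) {
        note_error(paste("second_stage", subset_name, oc, sep = "/"), e)
        list(kind = "excluded", reason = conditionMessage(e))
      })
      sub_report$outcomes[[oc]] <- res
    }
    for (oc in config$secondary_outcomes) {
      cd <- case_definition(oc)
      res <- tryCatch({
        strat <- stratified_pooled_model(pred, cohort, cd)
        list(kind = "stratified", stratified = strat)
      }, error = function(e) {
        note_error(paste("stratified", subset_name, oc, sep = "/"), e)
        list(kind = "excluded", reason = conditionMessage(e))
      })
      sub_report$outcomes[[oc]] <- res
    }

    if (isTRUE(config$bootstrap)) {
      sub_report$bootstrap <- tryCatch(
        mr_bootstrap(grs, cohort, case_definition("all"),
                     seed = derive_seed(config$seed, 77L)),
        error = function(e) { note_error("bootstrap", e); NULL })
    }
    report$outcomes[[subset_name]] <- sub_report
  }

  main <- report$outcomes[[1]]
  if (isTRUE(config$egger) && !is.null(main)) {
    report$egger <- tryCatch({
      grs_main <- compute_grs(weights_qc, dosages)
      summaries <- per_snp_outcome_betas(
        weights_qc, dosages, cohort, case_definition("all"),
        cm_per_unit = main$first_stage$grs_coefficient)
      list(summaries = summaries,
           egger = egger_regression(summaries),
           ivw = mr_ivw(summaries))
    }, error = function(e) { note_error("egger", e); NULL })
  }
  if (isTRUE(config$screen) && !is.null(main)) {
    report$screen <- tryCatch({
      grs_main <- compute_grs(weights_qc, dosages)
      confounder_screen(grs_main, cohort)
    }, error = function(e) { note_error("screen", e); NULL })
  }
  if (isTRUE(config$conventional)) {
    report$conventional <- tryCatch(
      conventional_analysis(cohort, case_definition("all")),
      error = function(e) { note_error("conventional", e); NULL })
  }
  if (!is.null(main)) {
    n_total <- nrow(cohort)
    report$power <- tryCatch(data.frame(
      n_total = n_total,
      case_fraction = mean(cohort$status == 1),
      r2_xz = main$first_stage$full_r2,
      or = config$power_or, alpha = 0.05,
      power = mr_power_binary(n_total, mean(cohort$status == 1),
                              main$first_stage$full_r2, config$power_or)),
      error = function(e) { note_error("power", e); NULL })
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir)
  }
  report
}

# Write every report table with stable filenames; each carries the config hash.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = report$config_hash, seed = report$seed)
  for (subset_name in names(report$outcomes)) {
    sr <- report$outcomes[[subset_name]]
    for (oc in names(sr$outcomes)) {
      res <- sr$outcomes[[oc]]
      stem <- file.path(out_dir, paste(subset_name, oc, sep = "_"))
      if (res$kind == "pooled") {
        est <- res$estimates
        ci <- or_per_5cm(est$beta, est$se)
        est$or_5cm <- ci$or; est$ci_low <- ci$ci_low; est$ci_high <- ci$ci_high
        write_table_tsv(est, paste0(stem, "_estimates.tsv"), prov)
        m <- res$meta
        meta_row <- data.frame(outcome = oc, k = m$k,
                               pooled_or_5cm = res$or$or,
                               ci_low = res$or$ci_low,
                               ci_high = res$or$ci_high,
                               tau2 = m$tau2, q = m$q, df = m$df,
                               i2_pct = m$i2, p_het = m$p_heterogeneity)
        write_table_tsv(meta_row, paste0(stem, "_meta.tsv"), prov)
        write_table_tsv(res$forest, paste0(stem, "_forest.tsv"), prov)
      } else if (res$kind == "stratified") {
        write_table_tsv(res$stratified, paste0(stem, "_stratified.tsv"), prov)
      } else {
        write_table_tsv(data.frame(outcome = oc, excluded = TRUE,
                                   reason = res$reason),
                        paste0(stem, "_excluded.tsv"), prov)
      }
    }
  }
  if (!is.null(report$egger)) {
    e <- report$egger$egger
    write_table_tsv(report$egger$summaries,
                    file.path(out_dir, "snp_summaries.tsv"), prov)
    write_table_tsv(data.frame(slope = e$slope, slope_se = e$slope_se,
                               p_slope = e$p_slope, intercept = e$intercept,
                               intercept_se = e$intercept_se,
                               p_intercept = e$p_intercept,
                               or_5cm = e$or_5cm, ci_low = e$ci_low,
                               ci_high = e$ci_high, n_snps = e$n_snps),
                    file.path(out_dir, "egger.tsv"), prov)
  }
  if (!is.null(report$screen)) {
    write_table_tsv(report$screen,
                    file.path(out_dir, "confounder_screen.tsv"), prov)
  }
  if (!is.null(report$conventional)) {
    write_table_tsv(report$conventional,
                    file.path(out_dir, "conventional.tsv"), prov)
  }
  if (!is.null(report$power)) {
    write_table_tsv(report$power, file.path(out_dir, "power.tsv"), prov)
  }
  info <- list(config_hash = report$config_hash, seed = report$seed,
               versions = report$versions,
               timestamp = format(Sys.time(), tz = "UTC"),
               errors = report$errors)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (config %s, seed %d)\n", substr(x$config_hash, 1, 8),
              x$seed))
  for (subset_name in names(x$outcomes)) {
    sr <- x$outcomes[[subset_name]]
    cat(sprintf("subset %s [%s]: first-stage %.2f cm/unit, partial F %.1f\n",
                subset_name, sr$grs_label, sr$first_stage$grs_coefficient,
                sr$first_stage$partial_f))
    for (oc in names(sr$outcomes)) {
      res <- sr$outcomes[[oc]]
      if (res$kind == "pooled") {
        cat(sprintf("  %-28s pooled OR/5cm %.3f (%.3f-%.3f), k=%d, I2=%.0f%%\n",
                    oc, res$or$or, res$or$ci_low, res$or$ci_high,
                    res$meta$k, res$meta$i2))
      } else if (res$kind == "stratified") {
        s <- res$stratified
        cat(sprintf("  %-28s stratified OR/5cm %.3f (%.3f-%.3f), k=%d\n",
                    oc, s$or_5cm, s$ci_low, s$ci_high, s$k))
      } else {
        cat(sprintf("  %-28s excluded: %s\n", oc, res$reason))
      }
    }
  }
  if (!is.null(x$egger)) {
    cat(sprintf("MR-Egger: OR/5cm %.3f (%.3f-%.3f), intercept p = %.3f\n",
                x$egger$egger$or_5cm, x$egger$egger$ci_low,
                x$egger$egger$ci_high, x$egger$egger$p_intercept))
  }
  if (!is.null(x$conventional)) {
    cat(sprintf("conventional OR/5cm %.3f (%.3f-%.3f) over %d studies\n",
                x$conventional$or_5cm, x$conventional$ci_low,
                x$conventional$ci_high, x$conventional$n_studies))
  }
  if (!is.null(x$power)) {
    cat(sprintf("power to detect OR %.2f: %.1f%%\n", x$power$or,
                100 * x$power$power))
  }
  if (length(x$errors)) {
    cat(sprintf("stages with errors: %s\n",
                paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
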