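#' First-stage regression of height on the genetic risk score
#'
#' Fits, in controls with observed height, a linear regression of height on
#' the score (plus age and five principal components when `adjusted = TRUE`,
#' the default) and returns the instrument-strength diagnostics: the
#' cm-per-score-unit coefficient, the increment in R-squared attributable to
#' the score given the covariates (semi-partial R-squared, from the nested
#' residual-sum-of-squares comparison), the corresponding partial-F
#' statistic with 1 numerator degree of freedom, and the unadjusted
#' R-squared of height on the score alone.
#'
#' @param grs a `grs_vector` from [compute_grs()].
#' @param cohort phenotype data.frame with `participant_id`, `status`,
#'   `height`, `age`, `PC1`..`PC5`.
#' @param adjusted logical; include age and principal components.
#' @return an object of class `first_stage_fit`.
#' @export
first_stage <- function(grs, cohort, adjusted = TRUE) {
  covars <- if (adjusted) c("age", paste0("PC", 1:5)) else character()
  m <- merge(grs, cohort[, c("participant_id", "status", "height", covars),
                         drop = FALSE],
             by = "participant_id")
  fit_data <- m[m$status == 0 & !is.na(m$height), , drop = FALSE]
  if (nrow(fit_data) < 30) {
    stop(sprintf(
      "first stage needs at least 30 controls with height; got %d",
      nrow(fit_data)), call. = FALSE)
  }
  full_formula <- stats::reformulate(c("score", covars), response = "height")
  fit_full <- stats::lm(full_formula, data = fit_data)
  aliased <- names(stats::coef(fit_full))[is.na(stats::coef(fit_full))]
  if (length(aliased)) {
    stop(sprintf("singular first-stage design; collinear column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  cov_formula <- if (length(covars)) {
    stats::reformulate(covars, response = "height")
  } else height ~ 1
  fit_cov <- stats::lm(cov_formula, data = fit_data)

  rss_full <- sum(stats::resid(fit_full)^2)
  rss_cov <- sum(stats::resid(fit_cov)^2)
  tss <- sum((fit_data$height - mean(fit_data$height))^2)
  df_resid <- fit_full$df.residual
  partial_r2 <- (rss_cov - rss_full) / tss
  full_r2 <- 1 - rss_full / tss
  partial_f <- if (rss_full > 0) {
    (rss_cov - rss_full) / (rss_full / df_resid)
  } else Inf
  unadj <- stats::lm(height ~ score, data = fit_data)
  unadjusted_r2 <- summary(unadj)$r.squared

  out <- list(grs_coefficient = unname(stats::coef(fit_full)["score"]),
              coefficients = stats::coef(fit_full),
              partial_r2 = partial_r2,
              full_r2 = full_r2,
              unadjusted_r2 = unadjusted_r2,
              partial_f = partial_f,
              partial_f_df = c(1, df_resid),
              residual_sd = sqrt(rss_full / df_resid),
              n_fit = nrow(fit_data),
              adjusted = adjusted)
  class(out) <- "first_stage_fit"
  out
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("first stage (n = %d controls with height%s)\n", x$n_fit,
              if (x$adjusted) ", adjusted for age + 5 PCs" else ""))
  cat(sprintf("  %.3f cm per score unit; R2 = %.4f (unadjusted), %.4f (full)\n",
              x$grs_coefficient, x$unadjusted_r2, x$full_r2))
  cat(sprintf("  partial R2 = %.4f, partial F = %.1f on (%d, %d) df\n",
              x$partial_r2, x$partial_f, x$partial_f_df[1], x$partial_f_df[2]))
  invisible(x)
}

#' Predicted height from the first-stage fit
#'
#' `predicted_i = gamma * score_i`, using only the score term of the first
#' stage. The intercept and covariate terms are deliberately omitted:
#' covariates re-enter the second stage directly, so carrying their
#' first-stage contributions into the prediction would double-count the
#' adjustment. Predictions are defined for every scored participant,
#' including those without measured height.
#'
#' @param fit a `first_stage_fit`.
#' @param grs a `grs_vector`.
#' @return data.frame with `participant_id` and `predicted_height` (cm).
#' @export
predict_height <- function(fit, grs) {
  stopifnot(inherits(fit, "first_stage_fit"))
  data.frame(participant_id = grs$participant_id,
             predicted_height = fit$grs_coefficient * grs$score,
             stringsAsFactors = FALSE)
}

#' Second-stage logistic model for one study (group)
#'
#' Maximum-likelihood logistic regression of case status on genetically
#' predicted height, adjusted for age and five principal components, within
#' one analysis group (a study, or a case-control study merged with its
#' regional case-only studies). Cases are restricted to the outcome's case
#' definition; the group must contribute strictly more than
#' `min_cases_per_study` qualifying cases, otherwise it is excluded with a
#' log notice and `NULL` is returned.
#'
#' @param predicted data.frame from [predict_height()].
#' @param cohort phenotype data.frame (must carry a `group` column; see
#'   [apply_grouping()]).
#' @param case_def a [case_definition()].
#' @param group the analysis group ID to fit.
#' @param covariates covariate column names entering the model (default age
#'   and five principal components).
#' @return a one-row data.frame (study estimate): `study_id`, `outcome`,
#'   `n_cases`, `n_controls`, `beta` (log-odds per cm), `se`, or `NULL` if
#'   the group is excluded (too few qualifying cases, or a degenerate
#'   separated fit that carries no odds-ratio information).
#' @export
second_stage <- function(predicted, cohort, case_def, group,
                         covariates = c("age", paste0("PC", 1:5))) {
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no participants in group %s", group), call. = FALSE)
  }
  sub <- apply_case_definition(sub, case_def)
  n_cases <- sum(sub$status == 1)
  n_controls <- sum(sub$status == 0)
  if (n_controls == 0) {
    stop(sprintf(
      "group %s has no controls; apply the case-only grouping map (apply_grouping) before per-study fits",
      group), call. = FALSE)
  }
  if (n_cases <= case_def$min_cases_per_study) {
    hm_log("second_stage[%s]: group %s excluded (%d cases, need > %d)",
           case_def$label, group, n_cases, case_def$min_cases_per_study)
    return(NULL)
  }
  d <- merge(sub, predicted, by = "participant_id")
  f <- stats::reformulate(c("predicted_height", covariates),
                          response = "status")
  fit <- stats::glm(f, data = d, family = stats::binomial(),
                    control = stats::glm.control(maxit = 100))
  if (!fit$converged) {
    stop(sprintf("second stage did not converge for group %s after %d IRLS iterations",
                 group, fit$iter), call. = FALSE)
  }
  co <- summary(fit)$coefficients
  # Quasi-complete separation in very small groups can yield a formally
  # converged fit whose predicted-height coefficient is astronomically
  # large; such fits carry no information about the odds ratio and would
  # corrupt the heterogeneity statistics, so they are excluded like the
  # rare-outcome path.
  degenerate <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
    abs(co["predicted_height", "Estimate"]) > 10 ||
    co["predicted_height", "Std. Error"] > 10
  if (degenerate) {
    hm_log("second_stage[%s]: group %s excluded (degenerate fit, likely separation)",
           case_def$label, group)
    return(NULL)
  }
  data.frame(study_id = group, outcome = case_def$label,
             n_cases = n_cases, n_controls = n_controls,
             beta = unname(co["predicted_height", "Estimate"]),
             se = unname(co["predicted_height", "Std. Error"]),
             stringsAsFactors = FALSE)
}

#' Per-group study estimates for an outcome
#'
#' Runs [second_stage()] over every analysis group in the cohort and binds
#' the surviving estimates.
#'
#' @inheritParams second_stage
#' @return data.frame of study estimates (possibly with fewer rows than
#'   groups, when groups fail the case-count threshold).
#' @export
mr_study_estimates <- function(predicted, cohort, case_def,
                               covariates = c("age", paste0("PC", 1:5))) {
  groups <- sort(unique(cohort$group))
  res <- lapply(groups, function(g) {
    second_stage(predicted, cohort, case_def, g, covariates = covariates)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    stop(sprintf("no group passed the > %d case threshold for outcome %s",
                 case_def$min_cases_per_study, case_def$label), call. = FALSE)
  }
  out
}

#' Merge case-only studies with their regional analysis group
#'
#' Attaches/overwrites the `group` column of a cohort from a grouping map,
#' so that case-only studies are analysed with the controls of a
#' case-control study from the same region.
#'
#' @param cohort phenotype data.frame with a `study` column.
#' @param grouping data.frame with columns `study`, `group` (default
#'   [ocac_grouping()]).
#' @return the cohort with its `group` column set.
#' @export
apply_grouping <- function(cohort, grouping = ocac_grouping()) {
  g <- grouping$group[match(cohort$study, grouping$study)]
  unknown <- unique(cohort$study[is.na(g)])
  if (length(unknown)) {
    stop(sprintf("studies missing from grouping map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cohort$group <- g
  cohort
}

#' Odds ratio per 5 cm with 95% confidence interval
#'
#' `OR = exp(5 beta)`, `CI = exp(5 beta +/- 1.959964 * 5 se)`.
#'
#' @param beta log-odds per cm.
#' @param se standard error of `beta` (per cm); must be positive.
#' @return data.frame with `or`, `ci_low`, `ci_high` (vectorised over
#'   `beta`/`se`).
#' @export
or_per_5cm <- function(beta, se) {
  if (any(se <= 0)) stop_bad_arg("se", "must be positive")
  data.frame(or = exp(5 * beta),
             ci_low = exp(5 * beta - Z95 * 5 * se),
             ci_high = exp(5 * beta + Z95 * 5 * se))
}

#' Conventional (measured-height) analysis
#'
#' The observational comparator to MR: a logistic model of case status on
#' measured height (per 5 cm), adjusted for parity, oral-contraceptive use,
#' education and age at menarche, with stratum indicator terms for study x
#' 5-year-age-group cells. Restricted to studies where more than half of
#' participants have height and all adjustment confounders observed.
#' Strata containing only cases or only controls are dropped (with a logged
#' count) since they carry no information about the odds ratio.
#'
#' @param cohort phenotype data.frame.
#' @param case_def a [case_definition()].
#' @param min_coverage minimum per-study fraction of participants with
#'   complete height and confounder data (default 0.5).
#' @return a one-row data.frame with `outcome`, `n_cases`, `n_controls`,
#'   `n_studies`, `beta` (log-odds per cm), `se`, `or_5cm`, `ci_low`,
#'   `ci_high`.
#' @export
conventional_analysis <- function(cohort, case_def = case_definition("all"),
                                  min_coverage = 0.5) {
  vars <- c("height", "parous", "oc_use", "education_years", "menarche_age")
  complete <- stats::complete.cases(cohort[, vars])
  cov_by_study <- tapply(complete, cohort$study, mean)
  eligible <- names(cov_by_study)[cov_by_study > min_coverage]
  if (length(eligible) == 0) {
    stop("no study has sufficient height/confounder coverage", call. = FALSE)
  }
  d <- cohort[cohort$study %in% eligible & complete, , drop = FALSE]
  d <- apply_case_definition(d, case_def)
  d$age_band <- 5 * floor(d$age / 5)
  d$stratum <- interaction(d$study, d$age_band, drop = TRUE)
  mixed <- tapply(d$status, d$stratum, function(s) any(s == 1) && any(s == 0))
  n_pure <- sum(!mixed)
  if (n_pure > 0) {
    hm_log("conventional_analysis: dropping %d stratum/strata with cases only or controls only",
           n_pure)
    d <- d[d$stratum %in% names(mixed)[mixed], , drop = FALSE]
    d$stratum <- droplevels(d$stratum)
  }
  rhs <- c("height", "parous", "oc_use", "education_years", "menarche_age",
           if (nlevels(d$stratum) > 1) "stratum")
  fit <- stats::glm(stats::reformulate(rhs, response = "status"),
                    data = d, family = stats::binomial(),
                    control = stats::glm.control(maxit = 100))
  co <- summary(fit)$coefficients
  beta <- unname(co["height", "Estimate"])
  se <- unname(co["height", "Std. Error"])
  ci <- or_per_5cm(beta, se)
  data.frame(outcome = case_def$label,
             n_cases = sum(d$status == 1), n_controls = sum(d$status == 0),
             n_studies = length(eligible),
             beta = beta, se = se,
             or_5cm = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' Within-study bootstrap of the two-stage standard error
#'
#' The second-stage standard errors are the naive logistic-model SEs and do
#' not propagate first-stage estimation error (the generated-regressor
#' problem). This nonparametric bootstrap resamples participants within
#' each study and refits both stages, quantifying how much the naive SE
#' understates the sampling variability of the pooled estimate.
#'
#' @param grs a `grs_vector`.
#' @param cohort phenotype data.frame with `group` set.
#' @param case_def a [case_definition()].
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param adjusted passed to [first_stage()].
#' @return a list with `pooled_beta_se_boot` (bootstrap SE of the pooled
#'   log-odds per cm), `pooled_betas` (the replicate estimates), `n_boot`.
#' @export
mr_bootstrap <- function(grs, cohort, case_def, n_boot = 200, seed = 1,
                         adjusted = TRUE) {
  betas <- with_stream(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$group),
                           function(i) sample(i, replace = TRUE)))
      co_b <- cohort[idx, , drop = FALSE]
      co_b$participant_id <- sprintf("b%07d", seq_len(nrow(co_b)))
      grs_b <- grs[match(cohort$participant_id[idx], grs$participant_id), ,
                   drop = FALSE]
      grs_b$participant_id <- co_b$participant_id
      fit1 <- first_stage(grs_b, co_b, adjusted = adjusted)
      pred <- predict_height(fit1, grs_b)
      est <- mr_study_estimates(pred, co_b, case_def)
      dersimonian_laird(est)$pooled_beta
    }, numeric(1))
  })
  list(pooled_beta_se_boot = stats::sd(betas), pooled_betas = betas,
       n_boot = n_boot)
}
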