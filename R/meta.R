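#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools study-specific log-odds estimates with the moment-based
#' DerSimonian-Laird estimator of between-study variance. With fixed
#' weights `u_i = 1/se_i^2`: `beta_FE = sum(u beta)/sum(u)`,
#' `Q = sum(u (beta - beta_FE)^2)`,
#' `tau2 = max(0, (Q - (k-1)) / (sum(u) - sum(u^2)/sum(u)))`; random-effects
#' weights are `w_i = 1/(se_i^2 + tau2)`, the pooled estimate
#' `sum(w beta)/sum(w)` with standard error `sum(w)^(-1/2)`. Heterogeneity
#' is summarised by Cochran's Q (chi-square with k-1 df) and
#' `I2 = max(0, (Q - (k-1))/Q) * 100` (0 when Q = 0).
#'
#' @param estimates data.frame with columns `beta` and `se` (one row per
#'   study), e.g. from [mr_study_estimates()]; all `se` must be positive.
#' @return an object of class `meta_result`: `pooled_beta`, `pooled_se`,
#'   `tau2`, `q`, `df`, `i2` (percent), `p_heterogeneity`, `k`,
#'   `per_study_weights` (normalised to sum 1), plus the input estimates.
#' @examples
#' est <- data.frame(beta = c(0.05, 0.10, 0.15), se = rep(0.05, 3))
#' dersimonian_laird(est)
#' @export
dersimonian_laird <- function(estimates) {
  beta <- estimates$beta
  se <- estimates$se
  k <- length(beta)
  if (k == 0) stop("no study estimates to pool", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_bad_arg("estimates", "all standard errors must be positive and finite")
  }
  u <- 1 / se^2
  beta_fe <- sum(u * beta) / sum(u)
  q <- sum(u * (beta - beta_fe)^2)
  df <- k - 1
  tau2 <- if (k > 1) {
    max(0, (q - df) / (sum(u) - sum(u^2) / sum(u)))
  } else 0
  w <- 1 / (se^2 + tau2)
  pooled_beta <- sum(w * beta) / sum(w)
  pooled_se <- sum(w)^(-0.5)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  p_het <- if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else 1
  out <- list(pooled_beta = pooled_beta, pooled_se = pooled_se,
              tau2 = tau2, q = q, df = df, i2 = i2,
              p_heterogeneity = p_het, k = k,
              per_study_weights = w / sum(w),
              estimates = estimates)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  ci <- or_per_5cm(x$pooled_beta, x$pooled_se)
  cat(sprintf("random-effects meta-analysis of %d studies\n", x$k))
  cat(sprintf("  pooled OR per 5 cm = %.3f (95%% CI %.3f-%.3f)\n",
              ci$or, ci$ci_low, ci$ci_high))
  cat(sprintf("  tau2 = %.5f, Q = %.3f on %d df (p = %.3f), I2 = %.1f%%\n",
              x$tau2, x$q, x$df, x$p_heterogeneity, x$i2))
  invisible(x)
}

#' Single stratified logistic model across studies
#'
#' The alternative to per-study fits plus pooling, used for secondary
#' (subtype) outcomes where per-study case counts are small: one logistic
#' model of case status on predicted height with age, five principal
#' components and study-group indicator terms.
#'
#' @inheritParams second_stage
#' @return a one-row data.frame: `outcome`, `k` (groups), `n_cases`,
#'   `n_controls`, `beta`, `se`, `or_5cm`, `ci_low`, `ci_high`.
#' @export
stratified_pooled_model <- function(predicted, cohort, case_def,
                                    covariates = c("age", paste0("PC", 1:5))) {
  sub <- apply_case_definition(cohort, case_def)
  cases_by_group <- tapply(sub$status == 1, sub$group, sum)
  keep_groups <- names(cases_by_group)[
    !is.na(cases_by_group) & cases_by_group > case_def$min_cases_per_study]
  dropped <- setdiff(unique(sub$group), keep_groups)
  if (length(dropped)) {
    hm_log("stratified_pooled_model[%s]: excluding %d group(s) with <= %d cases",
           case_def$label, length(dropped), case_def$min_cases_per_study)
  }
  d <- sub[sub$group %in% keep_groups, , drop = FALSE]
  if (nrow(d) == 0 || sum(d$status == 1) == 0) {
    stop(sprintf("no qualifying cases for outcome %s", case_def$label),
         call. = FALSE)
  }
  if (sum(d$status == 0) == 0) {
    stop("no controls after grouping; apply the case-only grouping map first",
         call. = FALSE)
  }
  d <- merge(d, predicted, by = "participant_id")
  terms <- c("predicted_height", covariates,
             if (length(keep_groups) > 1) "factor(group)")
  fit <- stats::glm(stats::reformulate(terms, response = "status"),
                    data = d, family = stats::binomial(),
                    control = stats::glm.control(maxit = 100))
  if (!fit$converged) {
    stop(sprintf("stratified model for %s did not converge after %d iterations",
                 case_def$label, fit$iter), call. = FALSE)
  }
  co <- summary(fit)$coefficients
  beta <- unname(co["predicted_height", "Estimate"])
  se <- unname(co["predicted_height", "Std. Error"])
  ci <- or_per_5cm(beta, se)
  data.frame(outcome = case_def$label, k = length(keep_groups),
             n_cases = sum(d$status == 1), n_controls = sum(d$status == 0),
             beta = beta, se = se, or_5cm = ci$or,
             ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' Forest-plot data table
#'
#' Per-study odds ratios with confidence intervals plus a pooled row,
#' sorted by study label, in a form ready for plotting or serialisation.
#'
#' @param estimates data.frame of study estimates (columns `study_id`,
#'   `beta`, `se`, optionally `n_cases`, `n_controls`).
#' @param meta the corresponding [dersimonian_laird()] result.
#' @return data.frame with `label`, `n_cases`, `n_controls`, `or`,
#'   `ci_low`, `ci_high`, `weight_pct`, `pooled` (logical); `k + 1` rows.
#' @export
forest_table <- function(estimates, meta) {
  est <- estimates[order(estimates$study_id), , drop = FALSE]
  w <- meta$per_study_weights[order(estimates$study_id)]
  ci <- or_per_5cm(est$beta, est$se)
  rows <- data.frame(label = est$study_id,
                     n_cases = est$n_cases %||% NA_integer_,
                     n_controls = est$n_controls %||% NA_integer_,
                     or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                     weight_pct = 100 * w, pooled = FALSE,
                     stringsAsFactors = FALSE)
  pci <- or_per_5cm(meta$pooled_beta, meta$pooled_se)
  pooled <- data.frame(label = "Pooled (random effects)",
                       n_cases = sum(est$n_cases %||% NA_integer_),
                       n_controls = sum(est$n_controls %||% NA_integer_),
                       or = pci$or, ci_low = pci$ci_low,
                       ci_high = pci$ci_high,
                       weight_pct = 100, pooled = TRUE,
                       stringsAsFactors = FALSE)
  rbind(rows, pooled)
}
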