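#' Per-SNP disease association summary statistics
#'
#' Estimates, for each instrument SNP separately, the per-allele log-odds
#' of disease from a pooled logistic model of case status on dosage with
#' age, five principal components and study-group indicator terms. The
#' exposure effects (`beta_exposure`, cm per effect allele) are copied from
#' the weight table. This is the summary-statistic input MR-Egger needs.
#'
#' A pooled, study-indicator-adjusted fit is used rather than per-study
#' fits meta-analysed per SNP: with hundreds of SNPs and many small
#' studies, per-study per-SNP fits are unstable for rare outcomes.
#'
#' The SNP-wise iteratively-reweighted-least-squares sweep runs in compiled
#' code (the design differs between SNPs only in the dosage column) and
#' agrees with `stats::glm` to near machine precision.
#'
#' SNPs whose fit fails (non-convergence or a degenerate dosage column) are
#' dropped and reported; if they exceed 1% of the panel the function fails
#' hard.
#'
#' @param weights a weight table; `beta_exposure` is taken as
#'   `weight * cm_per_unit`.
#' @param dosages dosage matrix (participants x SNPs).
#' @param cohort phenotype data.frame with `group` set.
#' @param case_def a [case_definition()].
#' @param cm_per_unit cm of height per weight unit (the first-stage slope;
#'   use 1 if weights are already in cm per allele).
#' @return data.frame with `rsid`, `beta_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @export
per_snp_outcome_betas <- function(weights, dosages, cohort, case_def,
                                  cm_per_unit = 1) {
  weights <- validate_weight_table(weights)
  d <- apply_case_definition(cohort, case_def)
  d <- d[order(d$participant_id), , drop = FALSE]
  dos <- dosages[d$participant_id, weights$rsid, drop = FALSE]
  y <- as.numeric(d$status)
  groups <- unique(d$group)
  base_X <- cbind(`(Intercept)` = 1,
                  age = d$age, PC1 = d$PC1, PC2 = d$PC2, PC3 = d$PC3,
                  PC4 = d$PC4, PC5 = d$PC5)
  if (length(groups) > 1) {
    gm <- stats::model.matrix(~ factor(d$group))[, -1, drop = FALSE]
    base_X <- cbind(base_X, gm)
  }
  J <- nrow(weights)
  sweep <- .logistic_sweep(base_X, dos, y)
  beta_out <- sweep$beta
  se_out <- sweep$se
  dropped <- weights$rsid[sweep$converged == 0]
  if (length(dropped)) {
    if (length(dropped) / J >= 0.01) {
      stop(sprintf(
        "per-SNP outcome models failed for %d of %d SNPs (>= 1%%): %s",
        length(dropped), J,
        paste(utils::head(dropped, 10), collapse = ", ")), call. = FALSE)
    }
    hm_log("per_snp_outcome_betas: dropped %d SNP(s): %s", length(dropped),
           paste(dropped, collapse = ", "))
  }
  ok <- !is.na(beta_out)
  data.frame(rsid = weights$rsid[ok],
             beta_exposure = weights$weight[ok] * cm_per_unit,
             beta_outcome = beta_out[ok],
             se_outcome = se_out[ok],
             stringsAsFactors = FALSE)
}

#' MR-Egger regression
#'
#' Weighted least squares of per-SNP outcome effects on exposure effects
#' with an unconstrained intercept, weights `1/se_outcome^2`. The slope is
#' the pleiotropy-adjusted causal effect (log-odds per cm when exposure
#' effects are in cm per allele); a non-zero intercept indicates directional
#' pleiotropy. SNPs are first oriented so every exposure effect is positive
#' (negating both effects of a SNP leaves the fit unchanged). By default the
#' residual dispersion is fixed at 1 (covariance `(X'WX)^-1`); setting
#' `dispersion = "multiplicative"` inflates it by the residual-based
#' multiplicative overdispersion factor. Two-sided p-values use the t
#' distribution with `n_snps - 2` df.
#'
#' @param summaries data.frame with `beta_exposure`, `beta_outcome`,
#'   `se_outcome` (see [per_snp_outcome_betas()]); at least 3 SNPs.
#' @param dispersion `"fixed"` or `"multiplicative"`.
#' @return an object of class `egger_result`: `slope`, `slope_se`,
#'   `p_slope`, `intercept`, `intercept_se`, `p_intercept`, `or_5cm`,
#'   `ci_low`, `ci_high`, `n_snps`, `dispersion`.
#' @export
egger_regression <- function(summaries, dispersion = c("fixed",
                                                       "multiplicative")) {
  dispersion <- match.arg(dispersion)
  bx <- summaries$beta_exposure
  by <- summaries$beta_outcome
  se <- summaries$se_outcome
  n <- length(bx)
  if (n < 3) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  if (any(se <= 0)) stop_bad_arg("summaries", "se_outcome must be positive")
  flip <- bx < 0
  by[flip] <- -by[flip]
  bx[flip] <- -bx[flip]
  if (stats::var(bx) < 1e-16) {
    stop("degenerate instrument: no variance in exposure effects",
         call. = FALSE)
  }
  w <- 1 / se^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * by))
  cov <- solve(xtwx)
  resid <- by - X %*% coef
  if (dispersion == "multiplicative") {
    phi <- sum(w * resid^2) / (n - 2)
    cov <- cov * phi
  }
  intercept <- coef[1]; slope <- coef[2]
  intercept_se <- sqrt(cov[1, 1]); slope_se <- sqrt(cov[2, 2])
  p_int <- 2 * stats::pt(abs(intercept / intercept_se), df = n - 2,
                         lower.tail = FALSE)
  p_slope <- 2 * stats::pt(abs(slope / slope_se), df = n - 2,
                           lower.tail = FALSE)
  ci <- or_per_5cm(slope, slope_se)
  out <- list(slope = slope, slope_se = slope_se, p_slope = p_slope,
              intercept = intercept, intercept_se = intercept_se,
              p_intercept = p_int,
              or_5cm = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
              n_snps = n, dispersion = dispersion)
  class(out) <- "egger_result"
  out
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger over %d SNPs (%s dispersion)\n", x$n_snps,
              x$dispersion))
  cat(sprintf("  slope = %.4f per cm (SE %.4f, p = %.3g); OR per 5 cm %.3f (%.3f-%.3f)\n",
              x$slope, x$slope_se, x$p_slope, x$or_5cm, x$ci_low, x$ci_high))
  cat(sprintf("  intercept = %.5f per allele (SE %.5f, p = %.3f)\n",
              x$intercept, x$intercept_se, x$p_intercept))
  invisible(x)
}

#' Inverse-variance-weighted (intercept-constrained) estimate
#'
#' The fixed-effect IVW slope `sum(w bx by) / sum(w bx^2)` with
#' `w = 1/se_outcome^2`; algebraically the MR-Egger fit with its intercept
#' constrained to zero. Used as the internal cross-check and as the
#' comparator whose bias MR-Egger corrects under directional pleiotropy.
#'
#' @inheritParams egger_regression
#' @return list with `slope`, `slope_se`.
#' @export
mr_ivw <- function(summaries) {
  bx <- summaries$beta_exposure
  by <- summaries$beta_outcome
  w <- 1 / summaries$se_outcome^2
  flip <- bx < 0
  by[flip] <- -by[flip]
  bx[flip] <- -bx[flip]
  list(slope = sum(w * bx * by) / sum(w * bx^2),
       slope_se = 1 / sqrt(sum(w * bx^2)))
}

#' Screen the score against potential confounders
#'
#' One model per confounder, with the score as the predictor: linear
#' regression for continuous confounders (age, education years, age at
#' menarche), logistic for binary ones (parity, oral-contraceptive
#' ever-use). A valid instrument should be unrelated to confounders of the
#' observational height-disease association.
#'
#' @param grs a `grs_vector`.
#' @param cohort phenotype data.frame.
#' @param confounders named character vector mapping confounder column to
#'   `"linear"` or `"logistic"`.
#' @param controls_only restrict to controls (default) or use everyone.
#' @return data.frame with one row per confounder: `confounder`, `type`,
#'   `estimate` (per score unit), `se`, `p`, `n`, `flagged` (p < 0.05),
#'   `assessable`.
#' @export
confounder_screen <- function(grs, cohort,
                              confounders = c(age = "linear",
                                              parous = "logistic",
                                              oc_use = "logistic",
                                              education_years = "linear",
                                              menarche_age = "linear"),
                              controls_only = TRUE) {
  m <- merge(grs, cohort, by = "participant_id")
  if (controls_only) m <- m[m$status == 0, , drop = FALSE]
  rows <- lapply(names(confounders), function(v) {
    type <- confounders[[v]]
    base <- data.frame(confounder = v, type = type, estimate = NA_real_,
                       se = NA_real_, p = NA_real_, n = 0L, flagged = FALSE,
                       assessable = FALSE, stringsAsFactors = FALSE)
    if (!v %in% names(m)) return(base)
    d <- m[!is.na(m[[v]]), c(v, "score")]
    if (nrow(d) < 10 || stats::var(d[[v]]) == 0) return(base)
    f <- stats::reformulate("score", response = v)
    fit <- if (type == "logistic") {
      stats::glm(f, data = d, family = stats::binomial())
    } else {
      stats::lm(f, data = d)
    }
    co <- summary(fit)$coefficients
    base$estimate <- unname(co["score", 1])
    base$se <- unname(co["score", 2])
    base$p <- unname(co["score", 4])
    base$n <- nrow(d)
    base$flagged <- base$p < 0.05
    base$assessable <- TRUE
    base
  })
  do.call(rbind, rows)
}
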