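#' Configuration of the synthetic multi-study case-control generator
#'
#' Defines the structural model under which cohorts are simulated: SNP panel
#' (allele frequencies, per-allele height effects, imputation quality),
#' height model (instrument variance explained, mean and SD), disease model
#' (causal odds ratio per 5 cm, pleiotropy, confounding), and the per-study
#' case/control composition.
#'
#' Height for participant i in study s is
#' `height = mean + shift_s + sum_j b_j g_ij + (confounder and residual terms)`
#' with the per-allele effects `b_j` rescaled so that the *observed* genetic
#' risk score (i.e., after imputation noise) explains `target_instrument_r2`
#' of within-study height variance. Disease is sampled from
#' `logit P(case) = alpha_s + log(true_or_per_5cm)/5 * (height - mean) +
#' pleiotropy + confounder + age terms`, and each study's case and control
#' counts are achieved by rejection sampling.
#'
#' @param studies data.frame with one row per study and columns `study`,
#'   `n_invasive`, `n_borderline`, `n_unknown`, `n_controls`, `case_only`,
#'   `has_height`, `has_confounders`, `group` (see [ocac_design()] and
#'   [sim_studies()]).
#' @param n_snps number of instrument SNPs.
#' @param maf_range range of effect-allele frequencies, each in (0, 1).
#' @param weight_scale raw per-allele height effect scale in cm (mean of the
#'   exponential draw; rescaled to hit `target_instrument_r2`).
#' @param target_instrument_r2 fraction of within-study height variance the
#'   observed score should explain.
#' @param height_mean_cm,height_sd_cm mean and within-study SD of height (cm).
#' @param height_study_sd SD of between-study height intercept shifts (cm).
#' @param true_or_per_5cm causal odds ratio of disease per 5 cm of height.
#' @param base_rate disease probability at the study intercept (a free
#'   parameter of the design; controls rejection-sampling efficiency, not
#'   the odds ratios).
#' @param age_effect log-odds of disease per year of age (conditional).
#' @param frac_imputed_snps fraction of SNPs that are imputed rather than
#'   genotyped.
#' @param imputation_r2_range range of imputation quality r-squared for
#'   imputed SNPs, each in (0, 1].
#' @param pleiotropy_frac fraction of SNPs with a direct (non-height) path
#'   to disease.
#' @param pleiotropy_effect per-allele log-odds of the direct path.
#' @param confounding_effect log-odds of disease per unit of a latent
#'   confounder shared with height (0 = exchangeability holds).
#' @param confounder_height_cm cm of height per unit of the latent
#'   confounder (used only when `confounding_effect != 0`).
#' @param menarche_overlap_frac,menarche_overlap_effect fraction of SNPs
#'   with a direct path to age at menarche and its per-allele effect in
#'   years (emulates genetic overlap between height and menarche timing).
#' @param cm_per_score_unit cm of height per unit of the reported score;
#'   weight-table weights are written as `b_j / cm_per_score_unit` so the
#'   first-stage slope recovers this value (default 5.2, the scale on which
#'   external GWAS weights are quoted).
#' @param histotype_mix_invasive,histotype_mix_borderline named probability
#'   vectors over histotype labels for invasive and borderline cases; each
#'   must sum to 1.
#' @param peritoneal_frac_unknown probability that an unknown-behaviour case
#'   is a primary peritoneal tumour (these are pooled with high-grade serous
#'   disease in subtype analyses).
#' @param seed integer master seed; every study derives its own stream.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()], [ocac_sim_config()]
#' @export
sim_config <- function(studies,
                       n_snps = 60,
                       maf_range = c(0.05, 0.5),
                       weight_scale = 0.03,
                       target_instrument_r2 = 0.13,
                       height_mean_cm = 163.5,
                       height_sd_cm = 6.5,
                       height_study_sd = 2,
                       true_or_per_5cm = 1.06,
                       base_rate = 0.25,
                       age_effect = 0.01,
                       frac_imputed_snps = 0.85,
                       imputation_r2_range = c(0.6, 1),
                       pleiotropy_frac = 0,
                       pleiotropy_effect = 0,
                       confounding_effect = 0,
                       confounder_height_cm = 2,
                       menarche_overlap_frac = 0,
                       menarche_overlap_effect = 0,
                       cm_per_score_unit = 5.2,
                       histotype_mix_invasive = c(serous_high = 0.408,
                                                  serous_low = 0.032,
                                                  serous_grade_unknown = 0.134,
                                                  mucinous = 0.066,
                                                  endometrioid = 0.142,
                                                  clear_cell = 0.065,
                                                  other = 0.153),
                       histotype_mix_borderline = c(serous = 0.555,
                                                    mucinous = 0.355,
                                                    other = 0.090),
                       peritoneal_frac_unknown = 0.3,
                       seed = 1L) {
  cfg <- list(studies = studies, n_snps = n_snps, maf_range = maf_range,
              weight_scale = weight_scale,
              target_instrument_r2 = target_instrument_r2,
              height_mean_cm = height_mean_cm, height_sd_cm = height_sd_cm,
              height_study_sd = height_study_sd,
              true_or_per_5cm = true_or_per_5cm, base_rate = base_rate,
              age_effect = age_effect, frac_imputed_snps = frac_imputed_snps,
              imputation_r2_range = imputation_r2_range,
              pleiotropy_frac = pleiotropy_frac,
              pleiotropy_effect = pleiotropy_effect,
              confounding_effect = confounding_effect,
              confounder_height_cm = confounder_height_cm,
              menarche_overlap_frac = menarche_overlap_frac,
              menarche_overlap_effect = menarche_overlap_effect,
              cm_per_score_unit = cm_per_score_unit,
              histotype_mix_invasive = histotype_mix_invasive,
              histotype_mix_borderline = histotype_mix_borderline,
              peritoneal_frac_unknown = peritoneal_frac_unknown,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  s <- cfg$studies
  need <- c("study", "n_invasive", "n_borderline", "n_unknown", "n_controls",
            "case_only", "has_height", "has_confounders", "group")
  if (!is.data.frame(s) || !all(need %in% names(s))) {
    stop_bad_arg("studies", paste("must be a data.frame with columns",
                                  paste(need, collapse = ", ")))
  }
  if (anyDuplicated(s$study)) stop_bad_arg("studies", "duplicated study IDs")
  counts <- s$n_invasive + s$n_borderline + s$n_unknown
  if (any(counts < 1)) {
    stop_bad_arg("studies", sprintf("studies with no cases: %s",
                                    paste(s$study[counts < 1], collapse = ", ")))
  }
  if (any(s$n_controls < 0)) stop_bad_arg("studies", "negative control counts")
  if (any(xor(s$case_only, s$n_controls == 0))) {
    stop_bad_arg("studies", "case_only flag inconsistent with n_controls")
  }
  if (cfg$n_snps < 1) stop_bad_arg("n_snps", "need at least one SNP")
  for (fr in c("target_instrument_r2", "base_rate")) {
    if (!is_fraction(cfg[[fr]], open = TRUE)) {
      stop_bad_arg(fr, "must lie strictly inside (0, 1)")
    }
  }
  for (fr in c("frac_imputed_snps", "pleiotropy_frac",
               "menarche_overlap_frac")) {
    if (!is_fraction(cfg[[fr]])) stop_bad_arg(fr, "must lie in [0, 1]")
  }
  if (!all(is_fraction(cfg$maf_range, open = TRUE)) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_bad_arg("maf_range", "must be an ordered pair inside (0, 1)")
  }
  if (any(cfg$imputation_r2_range <= 0) || any(cfg$imputation_r2_range > 1) ||
      cfg$imputation_r2_range[1] > cfg$imputation_r2_range[2]) {
    stop_bad_arg("imputation_r2_range", "must be an ordered pair in (0, 1]")
  }
  for (mx in c("histotype_mix_invasive", "histotype_mix_borderline")) {
    if (abs(sum(cfg[[mx]]) - 1) > 1e-9 || any(cfg[[mx]] < 0)) {
      stop_bad_arg(mx, "probabilities must be non-negative and sum to 1")
    }
  }
  if (cfg$true_or_per_5cm <= 0) stop_bad_arg("true_or_per_5cm", "must be > 0")
  if (cfg$height_sd_cm <= 0) stop_bad_arg("height_sd_cm", "must be > 0")
  invisible(cfg)
}

#' Build a study table from aggregate counts
#'
#' Convenience constructor for generic (non-consortium-shaped) designs:
#' splits each study's cases into invasive/borderline/unknown according to
#' `behaviour_mix` (largest-remainder rounding so counts sum exactly).
#'
#' @param n_cases,n_controls per-study counts (recycled to the same length).
#' @param case_only_studies,height_missing_studies character vectors of
#'   study IDs (case-only studies imply `n_controls = 0` and must be mapped
#'   to a host study via `grouping`).
#' @param behaviour_mix probabilities for invasive, borderline and
#'   unknown-behaviour cases; must sum to 1.
#' @param grouping optional data.frame (`study`, `group`); defaults to each
#'   study being its own group.
#' @param study optional study IDs (default S1, S2, ...).
#' @return a data.frame suitable for the `studies` field of [sim_config()].
#' @export
sim_studies <- function(n_cases, n_controls,
                        case_only_studies = character(),
                        height_missing_studies = character(),
                        behaviour_mix = c(invasive = 0.887,
                                          borderline = 0.103,
                                          unknown = 0.010),
                        grouping = NULL,
                        study = NULL) {
  k <- max(length(n_cases), length(n_controls))
  n_cases <- rep_len(n_cases, k)
  n_controls <- rep_len(n_controls, k)
  study <- study %||% sprintf("S%02d", seq_len(k))
  if (abs(sum(behaviour_mix) - 1) > 1e-9) {
    stop_bad_arg("behaviour_mix", "must sum to 1")
  }
  split_counts <- function(n) {
    raw <- n * behaviour_mix
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[idx] <- base[idx] + 1
    }
    base
  }
  parts <- t(vapply(n_cases, split_counts, numeric(3)))
  n_controls[study %in% case_only_studies] <- 0L
  d <- data.frame(study = study,
                  n_invasive = as.integer(parts[, 1]),
                  n_borderline = as.integer(parts[, 2]),
                  n_unknown = as.integer(parts[, 3]),
                  n_controls = as.integer(n_controls),
                  stringsAsFactors = FALSE)
  d$case_only <- d$n_controls == 0L
  d$has_height <- !(d$study %in% height_missing_studies)
  d$has_confounders <- d$has_height
  if (is.null(grouping)) {
    d$group <- d$study
  } else {
    d$group <- grouping$group[match(d$study, grouping$study)]
    if (anyNA(d$group)) stop_bad_arg("grouping", "missing studies in map")
  }
  d
}

#' Consortium-shaped simulation configuration
#'
#' The default study conditions: the 39-study design of [ocac_design()]
#' (optionally scaled down), a 609-SNP instrument explaining 13% of height
#' variance, height 163.5 (SD 6.5) cm, and a causal odds ratio of 1.06 per
#' 5 cm.
#'
#' @param scale divisor applied to the per-study counts.
#' @param n_snps number of instrument SNPs (default 609 at full scale; pass
#'   a smaller panel for repeated simulation).
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config` object.
#' @export
ocac_sim_config <- function(scale = 1, n_snps = 609, ...) {
  sim_config(studies = ocac_design(scale), n_snps = n_snps, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  n_cases <- sum(x$studies$n_invasive + x$studies$n_borderline +
                   x$studies$n_unknown)
  cat(sprintf(
    "sim_config: %d studies (%d case-only), %d cases / %d controls\n",
    nrow(x$studies), sum(x$studies$case_only), n_cases,
    sum(x$studies$n_controls)))
  cat(sprintf("  %d SNPs, target instrument R2 = %.3f, true OR per 5 cm = %.3f\n",
              x$n_snps, x$target_instrument_r2, x$true_or_per_5cm))
  cat(sprintf("  pleiotropy: %.0f%% of SNPs at %.3f; confounding: %.3f; seed %d\n",
              100 * x$pleiotropy_frac, x$pleiotropy_effect,
              x$confounding_effect, x$seed))
  invisible(x)
}
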