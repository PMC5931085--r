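#' Simulate a multi-study case-control cohort with genotype dosages
#'
#' Generates, under a known structural model, everything the MR pipeline
#' consumes: a per-SNP weight table, an effect-allele dosage matrix, a
#' phenotype/covariate table, and a `truth` record of the realised
#' generating parameters.
#'
#' Per SNP, true genotypes are Hardy-Weinberg draws at the SNP's effect
#' allele frequency. Imputed SNPs report a posterior-mean-style dosage
#' `obs = r2 * g + (1 - r2) * 2 * maf + jitter`, with the jitter variance
#' chosen so that the squared correlation between observed and true dosage
#' equals the SNP's assigned imputation quality r2 (then clipped to [0, 2]).
#' Height is the study intercept plus the true genetic score plus (optional)
#' confounder and Gaussian residual terms, with per-allele effects rescaled
#' so the observed score explains `target_instrument_r2` of within-study
#' height variance. Disease status follows a logistic model with log-odds
#' `log(true_or_per_5cm)/5` per cm of height plus optional direct-SNP
#' (pleiotropy) and latent-confounder terms; each study's case and control
#' counts are achieved by rejection sampling from its own random stream.
#'
#' @param config a [sim_config()] object.
#' @param keep_true_dosages retain the noise-free genotype matrix in
#'   `truth$true_dosages` (memory-costly; intended for validating the
#'   imputation-noise calibration).
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `weight_table` (see [compute_grs()]), `dosages` (participants x SNPs
#'   matrix of effect-allele dosages in \[0, 2\]), `cohort` (phenotype and
#'   covariate data.frame), `truth` (realised generating parameters:
#'   `beta_per_cm`, true per-allele cm effects, pleiotropic SNP set,
#'   realised instrument R-squared), and `config`.
#' @examples
#' cfg <- sim_config(sim_studies(n_cases = c(150, 150), n_controls = c(200, 200)),
#'                   n_snps = 20, seed = 7)
#' sc <- simulate_cohort(cfg)
#' range(sc$dosages)
#' @export
simulate_cohort <- function(config, keep_true_dosages = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  J <- cfg$n_snps
  studies <- cfg$studies

  snps <- with_stream(derive_seed(cfg$seed, 0L), draw_snp_panel(cfg))

  # Imputation-noise calibration: jitter SD per imputed SNP such that the
  # squared correlation between the clipped observed dosage and the true
  # genotype equals the assigned quality r2, plus the implied observed-
  # dosage covariance/variance used for instrument-R2 calibration.
  V <- 2 * snps$maf * (1 - snps$maf)
  snps$jitter_sd <- 0
  snps$cov_eff <- V
  snps$var_eff <- V
  for (j in which(!snps$genotyped)) {
    p <- snps$maf[j]; r2 <- snps$imputation_r2[j]
    sdj <- calibrate_jitter_sd(p, r2)
    snps$jitter_sd[j] <- sdj
    g <- 0:2
    pi_g <- stats::dbinom(g, 2, p)
    mu_g <- r2 * g + (1 - r2) * 2 * p
    mom <- censored_normal_moments(mu_g, sdj)
    e_obs <- sum(pi_g * mom$m1)
    snps$cov_eff[j] <- sum(pi_g * g * mom$m1) - e_obs * 2 * p
    snps$var_eff[j] <- sum(pi_g * mom$m2) - e_obs^2
  }

  # Rescale per-allele cm effects so the observed (imputation-noised) score
  # explains the target fraction of within-study height variance:
  # R2_obs = c^2 (sum w^2 cov)^2 / (sum w^2 var * sigma^2) with cov/var the
  # observed-dosage moments above (cov = var = 2p(1-p) when genotyped).
  w2 <- snps$raw_weight^2
  c_scale <- sqrt(cfg$target_instrument_r2 * cfg$height_sd_cm^2 *
                    sum(w2 * snps$var_eff) / sum(w2 * snps$cov_eff)^2)
  b_cm <- snps$raw_weight * c_scale
  var_g <- sum(b_cm^2 * V)
  conf_var <- if (cfg$confounding_effect != 0) cfg$confounder_height_cm^2 else 0
  resid_var <- cfg$height_sd_cm^2 - var_g - conf_var
  if (resid_var <= 0) {
    stop("height variance budget exhausted: genetic plus confounder variance ",
         "exceeds height_sd_cm^2; lower target_instrument_r2 or ",
         "confounder_height_cm", call. = FALSE)
  }

  pleio <- with_stream(derive_seed(cfg$seed, 1L), {
    idx <- sample(J, size = round(cfg$pleiotropy_frac * J))
    men <- sample(J, size = round(cfg$menarche_overlap_frac * J))
    shifts <- stats::rnorm(nrow(studies), 0, cfg$height_study_sd)
    list(idx = idx, men = men, shifts = shifts)
  })
  snps$annotations <- ""
  snps$annotations[pleio$idx] <- "ovarian-cancer"

  beta_cm <- log(cfg$true_or_per_5cm) / 5
  per_study <- vector("list", nrow(studies))
  for (s in seq_len(nrow(studies))) {
    per_study[[s]] <- with_stream(
      derive_seed(cfg$seed, 1000L + s),
      simulate_study(studies[s, ], cfg, snps, b_cm, beta_cm,
                     pleio$idx, pleio$men, pleio$shifts[s],
                     keep_true_dosages))
  }

  dosages <- do.call(rbind, lapply(per_study, `[[`, "dosages"))
  cohort <- do.call(rbind, lapply(per_study, `[[`, "cohort"))
  true_dosages <- if (keep_true_dosages) {
    td <- do.call(rbind, lapply(per_study, `[[`, "true_dosages"))
    colnames(td) <- snps$rsid
    td
  } else NULL
  rownames(cohort) <- NULL
  rownames(dosages) <- cohort$participant_id
  attr(dosages, "counted_allele") <-
    stats::setNames(snps$effect_allele, snps$rsid)

  weight_table <- data.frame(
    rsid = snps$rsid,
    effect_allele = snps$effect_allele,
    other_allele = snps$other_allele,
    weight = b_cm / cfg$cm_per_score_unit,
    genotyped = snps$genotyped,
    imputation_r2 = snps$imputation_r2,
    control_maf = NA_real_,
    locus_group = snps$locus_group,
    annotations = snps$annotations,
    stringsAsFactors = FALSE)
  ctrl <- cohort$status == 0
  if (any(ctrl)) {
    freq <- colMeans(dosages[ctrl, , drop = FALSE]) / 2
    weight_table$control_maf <- pmin(freq, 1 - freq)
  }

  score_obs <- as.numeric(dosages %*% weight_table$weight)
  fitable <- ctrl & !is.na(cohort$height)
  realised_r2 <- if (sum(fitable) > 10) {
    stats::cor(score_obs[fitable], cohort$height[fitable])^2
  } else NA_real_

  out <- list(weight_table = weight_table,
              dosages = dosages,
              cohort = cohort,
              truth = list(beta_per_cm = beta_cm,
                           or_per_5cm = cfg$true_or_per_5cm,
                           b_cm = stats::setNames(b_cm, snps$rsid),
                           cm_per_score_unit = cfg$cm_per_score_unit,
                           pleiotropic_snps = snps$rsid[pleio$idx],
                           realised_instrument_r2 = realised_r2,
                           snp_maf = stats::setNames(snps$maf, snps$rsid),
                           true_dosages = true_dosages),
              config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

# Moments of a normal distribution censored (clipped) to [0, 2].
censored_normal_moments <- function(mu, s) {
  a <- (0 - mu) / s
  b <- (2 - mu) / s
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m1 <- 2 * (1 - pb) + mu * (pb - pa) + s * (da - db)
  m2 <- 4 * (1 - pb) + mu^2 * (pb - pa) + 2 * mu * s * (da - db) +
    s^2 * ((pb - pa) + a * da - b * db)
  list(m1 = m1, m2 = m2)
}

# Post-clipping squared correlation between observed and true dosage for
# the blend obs = clip(lambda g + (1 - lambda) 2p + e), e ~ N(0, s^2),
# g ~ Binomial(2, p).
clipped_corr2 <- function(p, lambda, s) {
  g <- 0:2
  pi_g <- stats::dbinom(g, 2, p)
  mu_g <- lambda * g + (1 - lambda) * 2 * p
  mom <- censored_normal_moments(mu_g, s)
  e_obs <- sum(pi_g * mom$m1)
  e_obs2 <- sum(pi_g * mom$m2)
  e_obsg <- sum(pi_g * g * mom$m1)
  v_obs <- e_obs2 - e_obs^2
  v_g <- 2 * p * (1 - p)
  (e_obsg - e_obs * 2 * p)^2 / (v_obs * v_g)
}

# Jitter SD such that the clipped blend attains the assigned imputation r2
# (boundary censoring raises the correlation, so the naive jitter SD
# understates the noise needed; solve for it numerically).
calibrate_jitter_sd <- function(p, r2) {
  lambda <- r2
  v <- 2 * p * (1 - p)
  naive <- sqrt(r2 * (1 - r2) * v)
  if (naive == 0) return(0)
  f <- function(s) clipped_corr2(p, lambda, s) - r2
  hi <- naive
  for (i in 1:12) {
    if (f(hi) < 0) break
    hi <- hi * 1.6
  }
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(naive * 0.5, hi), tol = 1e-8)$root
}

# Draw the SNP panel: frequencies, raw weights, genotyped flags,
# imputation quality, and a locus grouping (~20% of SNPs share a locus).
draw_snp_panel <- function(cfg) {
  J <- cfg$n_snps
  maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
  raw_weight <- stats::rexp(J, rate = 1 / cfg$weight_scale)
  genotyped <- stats::runif(J) >= cfg$frac_imputed_snps
  imputation_r2 <- ifelse(
    genotyped, NA_real_,
    stats::runif(J, cfg$imputation_r2_range[1], cfg$imputation_r2_range[2]))
  n_loci <- max(1L, ceiling(0.8 * J))
  locus_group <- sprintf("L%04d", sort(sample(n_loci, J, replace = TRUE)))
  bases <- c("A", "C", "G", "T")
  effect_allele <- sample(bases, J, replace = TRUE)
  other_allele <- vapply(effect_allele,
                         function(a) sample(setdiff(bases, a), 1), "")
  data.frame(rsid = sprintf("rs%06d", seq_len(J)),
             effect_allele = effect_allele, other_allele = other_allele,
             maf = maf, raw_weight = raw_weight, genotyped = genotyped,
             imputation_r2 = imputation_r2, locus_group = locus_group,
             stringsAsFactors = FALSE)
}

# Rejection-sample one study until its case and control quotas are met.
simulate_study <- function(row, cfg, snps, b_cm, beta_cm, pleio_idx,
                           men_idx, study_shift, keep_true = FALSE) {
  n_cases <- row$n_invasive + row$n_borderline + row$n_unknown
  n_controls <- row$n_controls
  J <- nrow(snps)
  V <- 2 * snps$maf * (1 - snps$maf)
  conf_on <- cfg$confounding_effect != 0
  conf_var <- if (conf_on) cfg$confounder_height_cm^2 else 0
  resid_sd <- sqrt(cfg$height_sd_cm^2 - sum(b_cm^2 * V) - conf_var)
  alpha <- stats::qlogis(cfg$base_rate)

  # batch size targets both quotas with headroom, capped for memory; a
  # design whose realised case rate is far below base_rate exhausts the
  # batch budget and fails loudly below
  per_batch <- ceiling(1.3 * max(n_cases / cfg$base_rate,
                                 n_controls / (1 - cfg$base_rate), 50))
  per_batch <- min(per_batch, 200000L)
  acc_case <- list(); acc_ctrl <- list()
  got_cases <- 0L; got_ctrls <- 0L
  for (batch in seq_len(60L)) {
    cand <- draw_candidates(per_batch, cfg, snps, b_cm, beta_cm, pleio_idx,
                            men_idx, study_shift, resid_sd, alpha, conf_on)
    is_case <- cand$status == 1L
    if (got_cases < n_cases && any(is_case)) {
      take <- which(is_case)[seq_len(min(sum(is_case), n_cases - got_cases))]
      acc_case[[length(acc_case) + 1L]] <- lapply(cand, subset_cand, take)
      got_cases <- got_cases + length(take)
    }
    if (got_ctrls < n_controls && any(!is_case)) {
      take <- which(!is_case)[seq_len(min(sum(!is_case),
                                          n_controls - got_ctrls))]
      acc_ctrl[[length(acc_ctrl) + 1L]] <- lapply(cand, subset_cand, take)
      got_ctrls <- got_ctrls + length(take)
    }
    if (got_cases >= n_cases && got_ctrls >= n_controls) break
  }
  if (got_cases < n_cases || got_ctrls < n_controls) {
    stop(sprintf(
      "study %s: could not reach %d cases / %d controls by rejection sampling (got %d / %d); adjust base_rate or effect sizes",
      row$study, n_cases, n_controls, got_cases, got_ctrls), call. = FALSE)
  }
  parts <- c(acc_case, acc_ctrl)
  bind <- function(field) do.call(rbind, lapply(parts, `[[`, field))
  bindv <- function(field) do.call(c, lapply(parts, `[[`, field))

  dosages <- bind("dosages")
  true_dosages <- if (keep_true) bind("g_true") else NULL
  n <- nrow(dosages)
  status <- bindv("status")

  behaviour <- rep(NA_character_, n)
  case_idx <- which(status == 1L)
  lab <- sample(rep(c("invasive", "borderline", "unknown"),
                    times = c(row$n_invasive, row$n_borderline,
                              row$n_unknown)))
  behaviour[case_idx] <- lab
  histo <- assign_histotypes(behaviour, cfg)

  height <- bindv("height")
  if (!row$has_height) height[] <- NA_real_
  cohort <- data.frame(
    participant_id = sprintf("%s_%05d", row$study, seq_len(n)),
    study = row$study, group = row$group,
    status = status, behaviour = behaviour,
    histotype = histo$histotype, grade = histo$grade, site = histo$site,
    height = height, age = bindv("age"),
    PC1 = bindv("pc1"), PC2 = bindv("pc2"), PC3 = bindv("pc3"),
    PC4 = bindv("pc4"), PC5 = bindv("pc5"),
    parous = bindv("parous"), oc_use = bindv("oc_use"),
    education_years = bindv("education"),
    menarche_age = bindv("menarche"),
    stringsAsFactors = FALSE)
  if (!row$has_confounders) {
    cohort[c("parous", "oc_use", "education_years", "menarche_age")] <- NA
  }
  list(dosages = dosages, cohort = cohort, true_dosages = true_dosages)
}

subset_cand <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

draw_candidates <- function(m, cfg, snps, b_cm, beta_cm, pleio_idx, men_idx,
                            study_shift, resid_sd, alpha, conf_on) {
  J <- nrow(snps)
  g_true <- matrix(stats::rbinom(m * J, 2L, rep(snps$maf, each = m)),
                   nrow = m, ncol = J)
  # observed dosage: posterior-mean-style blend for imputed SNPs
  dos <- g_true * 1.0
  imp <- which(!snps$genotyped)
  if (length(imp)) {
    r2 <- snps$imputation_r2[imp]
    p <- snps$maf[imp]
    noise <- matrix(stats::rnorm(m * length(imp)), nrow = m) *
      rep(snps$jitter_sd[imp], each = m)
    blended <- sweep(g_true[, imp, drop = FALSE], 2, r2, `*`)
    blended <- sweep(blended, 2, (1 - r2) * 2 * p, `+`) + noise
    dos[, imp] <- pmin(pmax(blended, 0), 2)
  }
  colnames(dos) <- snps$rsid

  u <- if (conf_on) stats::rnorm(m) else numeric(m)
  G <- as.numeric(g_true %*% b_cm)
  height <- cfg$height_mean_cm + study_shift + G +
    (if (conf_on) cfg$confounder_height_cm * u else 0) +
    stats::rnorm(m, 0, resid_sd)
  age <- pmin(pmax(stats::rnorm(m, 57, 10), 18), 94)
  eta <- alpha + beta_cm * (height - cfg$height_mean_cm) +
    cfg$age_effect * (age - 57)
  if (length(pleio_idx)) {
    centred <- sweep(g_true[, pleio_idx, drop = FALSE], 2,
                     2 * snps$maf[pleio_idx], `-`)
    eta <- eta + cfg$pleiotropy_effect * rowSums(centred)
  }
  if (conf_on) eta <- eta + cfg$confounding_effect * u
  status <- stats::rbinom(m, 1L, stats::plogis(eta))

  menarche <- stats::rnorm(m, 13, 1.5)
  if (length(men_idx)) {
    centred <- sweep(g_true[, men_idx, drop = FALSE], 2,
                     2 * snps$maf[men_idx], `-`)
    menarche <- menarche + cfg$menarche_overlap_effect * rowSums(centred)
  }
  list(dosages = dos, g_true = g_true, status = status, height = height,
       age = age,
       pc1 = stats::rnorm(m), pc2 = stats::rnorm(m), pc3 = stats::rnorm(m),
       pc4 = stats::rnorm(m), pc5 = stats::rnorm(m),
       parous = stats::rbinom(m, 1L, 0.85),
       oc_use = stats::rbinom(m, 1L, 0.5),
       education = pmax(stats::rnorm(m, 12, 3), 5),
       menarche = menarche)
}

# Histotype, grade and site labels conditional on behaviour only
# (independent of genotype given case status).
assign_histotypes <- function(behaviour, cfg) {
  n <- length(behaviour)
  histotype <- rep(NA_character_, n)
  grade <- rep(NA_character_, n)
  site <- ifelse(is.na(behaviour), NA_character_, "ovary")
  inv <- which(!is.na(behaviour) & behaviour == "invasive")
  if (length(inv)) {
    mix <- cfg$histotype_mix_invasive
    lab <- sample(names(mix), length(inv), replace = TRUE, prob = mix)
    histotype[inv] <- sub("^serous_.*$", "serous", lab)
    grade[inv][lab == "serous_high"] <- "high"
    grade[inv][lab == "serous_low"] <- "low"
    grade[inv][lab == "serous_grade_unknown"] <- "unknown"
  }
  bor <- which(!is.na(behaviour) & behaviour == "borderline")
  if (length(bor)) {
    mix <- cfg$histotype_mix_borderline
    histotype[bor] <- sample(names(mix), length(bor), replace = TRUE,
                             prob = mix)
  }
  unk <- which(!is.na(behaviour) & behaviour == "unknown")
  if (length(unk)) {
    histotype[unk] <- "unknown"
    site[unk] <- ifelse(stats::runif(length(unk)) < cfg$peritoneal_frac_unknown,
                        "peritoneal", "ovary")
  }
  list(histotype = histotype, grade = grade, site = site)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  co <- x$cohort
  cat(sprintf(
    "synthetic_cohort: %d participants (%d cases / %d controls), %d studies, %d SNPs\n",
    nrow(co), sum(co$status == 1), sum(co$status == 0),
    length(unique(co$study)), nrow(x$weight_table)))
  cat(sprintf("  true OR per 5 cm = %.3f; realised instrument R2 = %s\n",
              x$truth$or_per_5cm,
              ifelse(is.na(x$truth$realised_instrument_r2), "NA",
                     sprintf("%.3f", x$truth$realised_instrument_r2))))
  invisible(x)
}
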