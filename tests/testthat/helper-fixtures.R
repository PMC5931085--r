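# Shared fixtures and independent oracles, built in code at test time.

options(heightmr.verbose = FALSE)

# Minimal weight-table constructor with sensible defaults.
make_weights <- function(n = 3,
                         weight = seq_len(n) / 100,
                         genotyped = rep(TRUE, n),
                         imputation_r2 = ifelse(genotyped, NA_real_, 0.9),
                         control_maf = rep(0.3, n),
                         locus_group = sprintf("L%03d", seq_len(n)),
                         annotations = rep("", n),
                         rsid = sprintf("rs%d", seq_len(n))) {
  data.frame(rsid = rsid,
             effect_allele = rep_len(c("A", "C", "G", "T"), n),
             other_allele = rep_len(c("G", "T", "A", "C"), n),
             weight = weight, genotyped = genotyped,
             imputation_r2 = imputation_r2, control_maf = control_maf,
             locus_group = locus_group, annotations = annotations,
             stringsAsFactors = FALSE)
}

make_dosages <- function(values, ids, rsids, counted = NULL) {
  m <- matrix(values, nrow = length(ids), ncol = length(rsids),
              dimnames = list(ids, rsids))
  if (!is.null(counted)) {
    attr(m, "counted_allele") <- stats::setNames(counted, rsids)
  }
  m
}

# Minimal cohort frame: covariates default to nuisance noise.
make_cohort <- function(ids, status, study = "S1", group = study,
                        height = NA_real_, age = NULL, seed = 99, ...) {
  n <- length(ids)
  set.seed(seed)
  age <- age %||% rnorm(n, 57, 8)
  data.frame(participant_id = ids, study = study, group = group,
             status = status,
             behaviour = ifelse(status == 1, "invasive", NA_character_),
             histotype = ifelse(status == 1, "serous", NA_character_),
             grade = ifelse(status == 1, "high", NA_character_),
             site = ifelse(status == 1, "ovary", NA_character_),
             height = height, age = age,
             PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
             PC4 = rnorm(n), PC5 = rnorm(n),
             parous = rbinom(n, 1, 0.8), oc_use = rbinom(n, 1, 0.5),
             education_years = rnorm(n, 12, 2),
             menarche_age = rnorm(n, 13, 1.5),
             stringsAsFactors = FALSE, ...)
}

# Independent DerSimonian-Laird oracle, coded as explicit loops over the
# defining formulas (kept deliberately naive).
dl_oracle <- function(beta, se) {
  k <- length(beta)
  u <- numeric(k); for (i in 1:k) u[i] <- 1 / se[i]^2
  bfe <- 0; for (i in 1:k) bfe <- bfe + u[i] * beta[i]
  bfe <- bfe / sum(u)
  q <- 0; for (i in 1:k) q <- q + u[i] * (beta[i] - bfe)^2
  tau2 <- 0
  if (k > 1) {
    denom <- sum(u) - sum(u^2) / sum(u)
    tau2 <- max(0, (q - (k - 1)) / denom)
  }
  w <- numeric(k); for (i in 1:k) w[i] <- 1 / (se[i]^2 + tau2)
  pb <- 0; for (i in 1:k) pb <- pb + w[i] * beta[i]
  pb <- pb / sum(w)
  list(pooled_beta = pb, pooled_se = 1 / sqrt(sum(w)), q = q, tau2 = tau2)
}

# Independent weighted-least-squares oracle for the Egger line, via the
# closed-form scalar normal equations.
wls_oracle <- function(bx, by, w) {
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  # dispersion-1 covariance of (intercept, slope)
  list(intercept = intercept, slope = slope,
       se_intercept = sqrt(swxx / det), se_slope = sqrt(sw / det))
}

# Closed-form 2x2 contingency log odds ratio.
table2x2_log_or <- function(cases_exposed, cases_unexposed,
                            controls_exposed, controls_unexposed) {
  log(cases_exposed * controls_unexposed /
        (cases_unexposed * controls_exposed))
}

# A small two-study synthetic cohort used across tests.
small_synth <- function(seed = 7, n_snps = 15, ...) {
  cfg <- sim_config(sim_studies(n_cases = c(250, 250),
                                n_controls = c(350, 350)),
                    n_snps = n_snps, seed = seed, ...)
  simulate_cohort(cfg)
}
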