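test_that("per-SNP outcome betas match the reference glm fit", {
  sc <- small_synth(seed = 3, n_snps = 6)
  s <- per_snp_outcome_betas(sc$weight_table, sc$dosages, sc$cohort,
                             case_definition("all"))
  expect_equal(nrow(s), 6)
  d <- sc$cohort
  dos <- sc$dosages[d$participant_id, ]
  for (j in 1:6) {
    d$g <- dos[, j]
    f <- stats::glm(
      status ~ g + age + PC1 + PC2 + PC3 + PC4 + PC5 + factor(group),
      data = d, family = stats::binomial())
    co <- summary(f)$coefficients["g", ]
    expect_equal(s$beta_outcome[j], unname(co[1]), tolerance = 1e-7)
    expect_equal(s$se_outcome[j], unname(co[2]), tolerance = 1e-5)
  }
})

test_that("a single causal SNP's per-allele log odds is recovered", {
  set.seed(61)
  n <- 50000
  g <- rbinom(n, 2, 0.3)
  status <- rbinom(n, 1, plogis(-0.6 + 0.1 * g))
  co <- make_cohort(sprintf("p%06d", 1:n), status)
  dos <- make_dosages(g, co$participant_id, "rs1", counted = "A")
  w <- make_weights(1, weight = 0.05)
  s <- per_snp_outcome_betas(w, dos, co, case_definition("all"))
  expect_lt(abs(s$beta_outcome - 0.1), 3 * s$se_outcome)
})

test_that("a constant dosage column is reported and fails the 1% rule", {
  w <- make_weights(2)
  set.seed(5)
  n <- 200
  co <- make_cohort(sprintf("p%d", 1:n), rbinom(n, 1, 0.5))
  dos <- make_dosages(c(rbinom(n, 2, 0.4), rep(1, n)), co$participant_id,
                      c("rs1", "rs2"), counted = w$effect_allele)
  expect_error(per_snp_outcome_betas(w, dos, co, case_definition("all")),
               "rs2")
})

test_that("Egger line reproduces exact proportionality", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  by <- 0.37 * bx
  s <- data.frame(rsid = sprintf("rs%d", 1:5), beta_exposure = bx,
                  beta_outcome = by, se_outcome = rep(0.05, 5))
  e <- egger_regression(s)
  expect_equal(e$slope, 0.37, tolerance = 1e-12)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$or_5cm, exp(5 * 0.37), tolerance = 1e-10)
})

test_that("Egger fit matches the closed-form weighted normal equations", {
  set.seed(77)
  bx <- runif(5, 0.05, 0.5)
  by <- 0.2 * bx + rnorm(5, 0, 0.02)
  se <- runif(5, 0.02, 0.1)
  s <- data.frame(rsid = sprintf("rs%d", 1:5), beta_exposure = bx,
                  beta_outcome = by, se_outcome = se)
  e <- egger_regression(s)
  o <- wls_oracle(bx, by, 1 / se^2)
  expect_equal(e$slope, o$slope, tolerance = 1e-12)
  expect_equal(e$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(e$slope_se, o$se_slope, tolerance = 1e-12)
  expect_equal(e$intercept_se, o$se_intercept, tolerance = 1e-12)
  # t-based p-values on n - 2 df
  expect_equal(e$p_intercept,
               2 * stats::pt(abs(o$intercept / o$se_intercept), 3,
                             lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("multiplicative dispersion only rescales the standard errors", {
  set.seed(78)
  bx <- runif(8, 0.05, 0.5)
  by <- 0.2 * bx + rnorm(8, 0, 0.05)
  se <- runif(8, 0.02, 0.1)
  s <- data.frame(rsid = sprintf("rs%d", 1:8), beta_exposure = bx,
                  beta_outcome = by, se_outcome = se)
  e1 <- egger_regression(s, dispersion = "fixed")
  e2 <- egger_regression(s, dispersion = "multiplicative")
  expect_equal(e1$slope, e2$slope, tolerance = 1e-12)
  expect_equal(e2$slope_se / e1$slope_se, e2$intercept_se / e1$intercept_se,
               tolerance = 1e-10)
})

test_that("the intercept-constrained slope is the IVW estimator", {
  set.seed(79)
  bx <- runif(10, 0.05, 0.5)
  by <- 0.15 * bx + rnorm(10, 0, 0.03)
  se <- runif(10, 0.02, 0.1)
  s <- data.frame(rsid = sprintf("rs%d", 1:10), beta_exposure = bx,
                  beta_outcome = by, se_outcome = se)
  ivw <- mr_ivw(s)
  w <- 1 / se^2
  expect_equal(ivw$slope, sum(w * bx * by) / sum(w * bx^2),
               tolerance = 1e-12)
})

test_that("allele flips and exposure rescaling behave as expected", {
  set.seed(80)
  bx <- runif(6, 0.05, 0.5)
  by <- 0.2 * bx + rnorm(6, 0, 0.03)
  se <- runif(6, 0.02, 0.1)
  s <- data.frame(rsid = sprintf("rs%d", 1:6), beta_exposure = bx,
                  beta_outcome = by, se_outcome = se)
  e0 <- egger_regression(s)
  # flip one SNP's allele: negate both effects; the fit must not change
  s2 <- s
  s2$beta_exposure[3] <- -s2$beta_exposure[3]
  s2$beta_outcome[3] <- -s2$beta_outcome[3]
  e2 <- egger_regression(s2)
  expect_equal(e2$slope, e0$slope, tolerance = 1e-12)
  expect_equal(e2$intercept, e0$intercept, tolerance = 1e-12)
  # rescaling exposures by c rescales the slope by 1/c, OR unchanged
  s3 <- s
  s3$beta_exposure <- 4 * s3$beta_exposure
  e3 <- egger_regression(s3)
  expect_equal(e3$slope, e0$slope / 4, tolerance = 1e-12)
  expect_equal(e3$intercept, e0$intercept, tolerance = 1e-12)
})

test_that("degenerate Egger inputs are rejected", {
  s <- data.frame(rsid = c("a", "b"), beta_exposure = c(0.1, 0.2),
                  beta_outcome = c(0.01, 0.02), se_outcome = c(0.1, 0.1))
  expect_error(egger_regression(s), "at least 3")
  s3 <- data.frame(rsid = c("a", "b", "c"), beta_exposure = rep(0.2, 3),
                   beta_outcome = c(0.01, 0.02, 0.03),
                   se_outcome = rep(0.1, 3))
  expect_error(egger_regression(s3), "degenerate")
})

test_that("confounder screen flags a built-in genetic overlap with menarche", {
  cfg <- sim_config(sim_studies(n_cases = 500, n_controls = 6000),
                    n_snps = 30, menarche_overlap_frac = 0.5,
                    menarche_overlap_effect = 0.4, seed = 19)
  sc <- simulate_cohort(cfg)
  grs <- compute_grs(sc$weight_table, sc$dosages)
  scr <- confounder_screen(grs, sc$cohort)
  men <- scr[scr$confounder == "menarche_age", ]
  expect_true(men$flagged)
  expect_gt(men$estimate, 0)
})

test_that("constant or missing confounders are marked not assessable", {
  sc <- small_synth(seed = 47, n_snps = 8)
  co <- sc$cohort
  co$education_years <- 12               # constant
  co$parous <- NA                        # entirely missing
  grs <- compute_grs(sc$weight_table, sc$dosages)
  scr <- confounder_screen(grs, co)
  expect_false(scr$assessable[scr$confounder == "education_years"])
  expect_false(scr$assessable[scr$confounder == "parous"])
  expect_true(scr$assessable[scr$confounder == "menarche_age"])
})
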