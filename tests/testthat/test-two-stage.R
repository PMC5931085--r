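test_that("first stage matches the closed-form least-squares solution", {
  # 6-point fixture, unadjusted: normal-equations oracle
  score6 <- c(1, 2, 3, 4, 5, 6)
  height6 <- c(158, 160, 165, 163, 170, 171)
  score <- rep(score6, 6)            # replicated to pass the n >= 30 gate;
  height <- rep(height6, 6)          # the slope is unchanged by replication
  co <- make_cohort(sprintf("p%d", 1:36), rep(0, 36), height = height)
  grs <- structure(data.frame(participant_id = co$participant_id,
                              score = score, subset_label = "x"),
                   class = c("grs_vector", "data.frame"))
  fit <- first_stage(grs, co, adjusted = FALSE)
  # independent oracle: normal equations solve(X'X, X'y) on the 6 points
  X <- cbind(1, score6)
  beta <- solve(t(X) %*% X, t(X) %*% height6)
  expect_equal(fit$grs_coefficient, beta[2], tolerance = 1e-10)
})

test_that("a perfectly linear height yields partial R2 of 1", {
  co <- make_cohort(sprintf("p%d", 1:40), rep(0, 40))
  score <- seq(15, 19, length.out = 40)
  co$height <- 100 + 3.5 * score
  grs <- structure(data.frame(participant_id = co$participant_id,
                              score = score, subset_label = "x"),
                   class = c("grs_vector", "data.frame"))
  fit <- first_stage(grs, co, adjusted = FALSE)
  expect_equal(fit$partial_r2, 1, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-6)
  expect_equal(fit$grs_coefficient, 3.5, tolerance = 1e-8)
})

test_that("first-stage diagnostics satisfy the nested-model identity", {
  sc <- small_synth(seed = 19)
  grs <- compute_grs(sc$weight_table, sc$dosages)
  fit <- first_stage(grs, sc$cohort)
  expect_equal(fit$partial_f,
               fit$partial_r2 / (1 - fit$full_r2) * fit$partial_f_df[2],
               tolerance = 1e-10)
  expect_true(fit$partial_r2 >= 0 && fit$partial_r2 <= 1)
  expect_gt(fit$n_fit, 7)
})

test_that("first stage errors on tiny or singular designs", {
  co <- make_cohort(sprintf("p%d", 1:10), rep(0, 10),
                    height = rnorm(10, 163, 5))
  grs <- structure(data.frame(participant_id = co$participant_id,
                              score = rnorm(10), subset_label = "x"),
                   class = c("grs_vector", "data.frame"))
  expect_error(first_stage(grs, co), "at least 30 controls")

  co2 <- make_cohort(sprintf("p%d", 1:60), rep(0, 60),
                     height = rnorm(60, 163, 5))
  co2$PC5 <- co2$PC4  # collinear
  grs2 <- structure(data.frame(participant_id = co2$participant_id,
                               score = rnorm(60), subset_label = "x"),
                    class = c("grs_vector", "data.frame"))
  expect_error(first_stage(grs2, co2), "collinear.*PC5")
})

test_that("predicted height is the score term only and is linear", {
  fit <- structure(list(grs_coefficient = 5.2), class = "first_stage_fit")
  grs <- structure(data.frame(participant_id = c("a", "b"),
                              score = c(17, 18), subset_label = "x"),
                   class = c("grs_vector", "data.frame"))
  p <- predict_height(fit, grs)
  expect_equal(diff(p$predicted_height), 5.2)

  fit0 <- structure(list(grs_coefficient = 0), class = "first_stage_fit")
  expect_equal(predict_height(fit0, grs)$predicted_height, c(0, 0))

  # predict(a * score) with gamma equals predict(score) with a * gamma
  grs2 <- grs; grs2$score <- 2 * grs$score
  fit2 <- structure(list(grs_coefficient = 5.2 / 2),
                    class = "first_stage_fit")
  expect_equal(predict_height(fit, grs2)$predicted_height * 0.5,
               predict_height(fit2, grs2)$predicted_height)
})

test_that("second stage equals the 2x2 contingency odds ratio when collapsed", {
  a <- 40; b <- 25; cc <- 35; d <- 50  # exposed/unexposed cases, controls
  ids <- sprintf("p%03d", 1:(a + b + cc + d))
  status <- c(rep(1, a + b), rep(0, cc + d))
  exposed <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  co <- make_cohort(ids, status)
  pred <- data.frame(participant_id = ids, predicted_height = exposed)
  est <- second_stage(pred, co, case_definition("all"), "S1",
                      covariates = character())
  expect_equal(est$beta, table2x2_log_or(a, b, cc, d), tolerance = 1e-8)
  expect_equal(est$n_cases, a + b)
  expect_equal(est$n_controls, cc + d)
})

test_that("second stage enforces grouping and the case-count threshold", {
  co <- make_cohort(sprintf("p%d", 1:30), rep(1, 30))  # cases only
  pred <- data.frame(participant_id = co$participant_id,
                     predicted_height = rnorm(30))
  expect_error(second_stage(pred, co, case_definition("all"), "S1"),
               "grouping")

  co2 <- make_cohort(sprintf("q%d", 1:50), c(rep(1, 4), rep(0, 46)))
  pred2 <- data.frame(participant_id = co2$participant_id,
                      predicted_height = rnorm(50))
  expect_null(second_stage(pred2, co2, case_definition("all"), "S1"))
})

test_that("null outcomes give estimates near zero", {
  set.seed(44)
  n <- 2000
  co <- make_cohort(sprintf("p%04d", 1:n), rbinom(n, 1, 0.4))
  pred <- data.frame(participant_id = co$participant_id,
                     predicted_height = rnorm(n, 163, 2.3))
  est <- second_stage(pred, co, case_definition("all"), "S1")
  expect_lt(abs(est$beta), 3 * est$se)
})

test_that("per-5cm transform follows the exact formulas", {
  z <- 1.959964
  r0 <- or_per_5cm(0, 0.01)
  expect_equal(r0$or, 1)
  expect_equal(r0$ci_low * r0$ci_high, 1, tolerance = 1e-12)

  expect_equal(or_per_5cm(log(1.06) / 5, 0.001)$or, 1.06, tolerance = 1e-12)

  r <- or_per_5cm(0.0117, 0.0048)
  expect_equal(r$or, exp(5 * 0.0117), tolerance = 1e-12)
  expect_equal(r$ci_low, exp(5 * 0.0117 - z * 5 * 0.0048), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(5 * 0.0117 + z * 5 * 0.0048), tolerance = 1e-12)
  expect_equal(round(r$or, 3), 1.060)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(1.01, 1.11))
  expect_true(r$ci_low < r$or && r$or < r$ci_high)
  expect_error(or_per_5cm(0.1, 0), "positive")
})

test_that("two-stage estimates are invariant to rescaling the weights", {
  sc <- small_synth(seed = 23)
  run <- function(mult) {
    w <- sc$weight_table
    w$weight <- w$weight * mult
    grs <- compute_grs(w, sc$dosages)
    fit <- first_stage(grs, sc$cohort)
    list(gamma = fit$grs_coefficient,
         est = mr_study_estimates(predict_height(fit, grs), sc$cohort,
                                  case_definition("all")))
  }
  base <- run(1)
  doubled <- run(2)  # power of two: exact in floating point
  expect_identical(doubled$gamma, base$gamma / 2)
  expect_identical(doubled$est$beta, base$est$beta)
  expect_identical(doubled$est$se, base$est$se)
  tripled <- run(3)
  expect_equal(tripled$est$beta, base$est$beta, tolerance = 1e-10)
})

test_that("large single-study simulation recovers the causal odds ratio", {
  studies <- sim_studies(n_cases = 4000, n_controls = 6000)
  sc <- simulate_cohort(sim_config(studies, n_snps = 40,
                                   true_or_per_5cm = 1.25, seed = 6))
  grs <- compute_grs(sc$weight_table, sc$dosages)
  fit <- first_stage(grs, sc$cohort)
  est <- second_stage(predict_height(fit, grs), sc$cohort,
                      case_definition("all"), "S01")
  ci <- or_per_5cm(est$beta, est$se)
  expect_true(ci$ci_low < 1.25 && 1.25 < ci$ci_high)
})

test_that("conventional analysis reduces to the 2x2 odds ratio in one stratum", {
  a <- 30; b <- 45; cc <- 55; d <- 40
  ids <- sprintf("p%03d", 1:(a + b + cc + d))
  status <- c(rep(1, a + b), rep(0, cc + d))
  tall <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  co <- make_cohort(ids, status, age = 50)
  co$height <- 160 + 10 * tall
  co$parous <- 1; co$oc_use <- 0; co$education_years <- 12
  co$menarche_age <- 13
  res <- conventional_analysis(co, case_definition("all"))
  expect_equal(res$beta * 10, table2x2_log_or(a, b, cc, d), tolerance = 1e-6)
})

test_that("confounding biases the conventional estimate but not the MR estimate", {
  d <- ocac_design(scale = 5)
  cfg <- sim_config(d, n_snps = 40, true_or_per_5cm = 1.06,
                    confounding_effect = -0.25, confounder_height_cm = 3,
                    seed = 12)
  sc <- simulate_cohort(cfg)
  grs <- compute_grs(qc_filter(sc$weight_table), sc$dosages)
  fit <- first_stage(grs, sc$cohort)
  est <- mr_study_estimates(predict_height(fit, grs), sc$cohort,
                            case_definition("all"))
  mr <- dersimonian_laird(est)
  conv <- conventional_analysis(sc$cohort, case_definition("all"))
  expect_lt(conv$beta, mr$pooled_beta)
})

test_that("bootstrap SE is at least comparable to the naive pooled SE", {
  sc <- small_synth(seed = 29)
  grs <- compute_grs(sc$weight_table, sc$dosages)
  fit <- first_stage(grs, sc$cohort)
  est <- mr_study_estimates(predict_height(fit, grs), sc$cohort,
                            case_definition("all"))
  naive <- dersimonian_laird(est)$pooled_se
  bt <- mr_bootstrap(grs, sc$cohort, case_definition("all"),
                     n_boot = 30, seed = 5)
  expect_equal(length(bt$pooled_betas), 30)
  expect_gt(bt$pooled_beta_se_boot, 0.3 * naive)
  expect_lt(bt$pooled_beta_se_boot, 3 * naive)
})
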