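test_that("qc_filter keeps genotyped SNPs and well-imputed SNPs only", {
  # 697-SNP panel: 92 genotyped, 88 imputed below the 0.6 threshold
  n <- 697
  genotyped <- c(rep(TRUE, 92), rep(FALSE, 605))
  quality <- c(rep(NA_real_, 92), rep(0.95, 517), rep(0.4, 88))
  w <- make_weights(n, weight = rep(0.02, n), genotyped = genotyped,
                    imputation_r2 = quality)
  out <- qc_filter(w, 0.6)
  expect_equal(nrow(out), 609)
  expect_equal(sum(out$genotyped), 92)
  expect_equal(sum(!out$genotyped), 517)

  # threshold 0 is a no-op
  expect_equal(nrow(qc_filter(w, 0)), n)

  w10 <- make_weights(10, genotyped = rep(FALSE, 10),
                      imputation_r2 = rep(c(0.5, 0.7), 5))
  expect_equal(nrow(qc_filter(w10, 0.6)), 5)

  expect_error(qc_filter(w10, 1), "every SNP")
  expect_error(qc_filter(w10, 2), "min_imputation_r2")
})

test_that("subset rules filter as specified", {
  w <- make_weights(20, control_maf = c(rep(0.02, 4), rep(0.2, 16)),
                    genotyped = rep(c(TRUE, FALSE), 10),
                    imputation_r2 = rep(c(NA, 0.85), 10))
  expect_equal(nrow(grs_subset(w, "maf-at-least", threshold = 0.05)), 16)
  expect_equal(sum(!grs_subset(w, "genotyped-only")$genotyped), 0)
  # imputation-quality rule keeps genotyped SNPs unconditionally
  hi <- grs_subset(w, "imputation-quality-at-least", threshold = 0.9)
  expect_equal(nrow(hi), 10)
  expect_true(all(hi$genotyped))
  expect_error(grs_subset(w, "no-such-rule"), "must be one of")
})

test_that("one-per-locus keeps the max-weight SNP per locus (brute force)", {
  set.seed(42)
  w <- make_weights(12, weight = runif(12),
                    locus_group = sample(c("A", "B", "C"), 12, replace = TRUE))
  out <- grs_subset(w, "one-per-locus")
  expect_equal(nrow(out), 3)
  for (g in c("A", "B", "C")) {
    members <- w[w$locus_group == g, ]
    expect_equal(out$rsid[out$locus_group == g],
                 members$rsid[which.max(members$weight)])
  }
})

test_that("annotation exclusion removes tagged SNPs; empty set is identity", {
  w <- make_weights(6, annotations = c("", "ovarian-cancer",
                                       "hormone-level;tumour-gene", "",
                                       "tumour-gene", ""))
  expect_equal(grs_subset(w, "exclude-annotations", tags = character()), w)
  out <- grs_subset(w, "exclude-annotations", tags = "tumour-gene")
  expect_setequal(out$rsid, w$rsid[c(1, 2, 4, 6)])
})

test_that("negative input weights are re-oriented to height-increasing", {
  withr::local_options(heightmr.verbose = TRUE)
  w <- make_weights(2, weight = c(0.05, -0.03))
  expect_message(out <- validate_weight_table(w), "re-orienting")
  expect_equal(out$weight, c(0.05, 0.03))
  expect_equal(out$effect_allele[2], w$other_allele[2])
  expect_equal(out$other_allele[2], w$effect_allele[2])
})

test_that("compute_grs equals the hand-computed weighted allele sum", {
  w <- make_weights(3, weight = c(0.02, 0.03, 0.05))
  d <- make_dosages(c(1, 2, 0), "p1", w$rsid)
  expect_equal(compute_grs(w, d)$score, 0.08)

  d0 <- make_dosages(rep(0, 6), c("p1", "p2"), w$rsid)
  expect_equal(compute_grs(w, d0)$score, c(0, 0))

  w1 <- make_weights(1, weight = 0.37)
  expect_equal(compute_grs(w1, make_dosages(2, "p1", "rs1"))$score, 2 * 0.37)
})

test_that("compute_grs validates dosages and SNP coverage", {
  w <- make_weights(2)
  d <- make_dosages(c(1, 1), "p1", c("rs1", "rsX"))
  expect_error(compute_grs(w, d), "rs2")
  d2 <- make_dosages(c(0.5, 2.4), "p1", c("rs1", "rs2"))
  expect_error(compute_grs(w, d2), "rs2.*p1|outside")
  # missing entries beyond the per-SNP bound fail loudly
  d3 <- make_dosages(rep(1, 80), sprintf("p%d", 1:40), c("rs1", "rs2"))
  d3[1:3, "rs2"] <- NA
  expect_error(compute_grs(w, d3), "missing dosages exceed")
})

test_that("column orientation is resolved against the counted allele", {
  w <- make_weights(2, weight = c(0.1, 0.2))
  d <- make_dosages(c(1, 0.5, 2, 1.5), c("p1", "p2"), c("rs1", "rs2"),
                    counted = c(w$effect_allele[1], w$other_allele[2]))
  out <- compute_grs(w, d)
  # rs2 counted on the other allele: dosage flips to 2 - d
  expect_equal(out$score, c(0.1 * 1 + 0.2 * (2 - 2),
                            0.1 * 0.5 + 0.2 * (2 - 1.5)))
  bad <- d
  attr(bad, "counted_allele")["rs2"] <- "N"
  expect_error(compute_grs(w, bad), "neither")
})

test_that("score algebra: scaling, permutation, flip, subset monotonicity", {
  set.seed(8)
  n <- 25; J <- 9
  w <- make_weights(J, weight = runif(J, 0.01, 0.2),
                    locus_group = sample(c("a", "b", "c", "d"), J, TRUE))
  d <- make_dosages(runif(n * J, 0, 2), sprintf("p%02d", 1:n), w$rsid,
                    counted = w$effect_allele)
  base <- compute_grs(w, d)$score

  w2 <- w; w2$weight <- w$weight * 3
  expect_equal(compute_grs(w2, d)$score, 3 * base)

  perm <- sample(J)
  d_perm <- d[, perm]
  attr(d_perm, "counted_allele") <- attr(d, "counted_allele")[perm]
  expect_equal(compute_grs(w, d_perm)$score, base)

  # flip one column to count the other allele
  d_flip <- d
  d_flip[, 3] <- 2 - d_flip[, 3]
  attr(d_flip, "counted_allele")[w$rsid[3]] <- w$other_allele[3]
  expect_equal(compute_grs(w, d_flip)$score, base)

  sub <- grs_subset(w, "one-per-locus")
  expect_true(all(compute_grs(sub, d)$score <= base + 1e-12))
})

test_that("descriptives recover the generating cm-per-unit slope", {
  studies <- sim_studies(n_cases = 200, n_controls = 6000)
  sc <- simulate_cohort(sim_config(studies, n_snps = 40, seed = 13))
  grs <- compute_grs(sc$weight_table, sc$dosages)
  de <- grs_descriptives(grs, sc$cohort)
  expect_lt(abs(de$cm_per_unit - 5.2), 3 * de$cm_per_unit_se)
  expect_gt(de$quartile_contrast_cm, 0)
  expect_true(de$score_iqr[1] <= de$score_median &&
                de$score_median <= de$score_iqr[2])
})

test_that("descriptives handle degenerate scores and missing heights", {
  co <- make_cohort(sprintf("p%d", 1:40), rep(0:1, 20),
                    height = rnorm(40, 163, 6))
  grs_const <- structure(
    data.frame(participant_id = co$participant_id, score = 1,
               subset_label = "x"),
    class = c("grs_vector", "data.frame"))
  de <- grs_descriptives(grs_const, co)
  expect_equal(de$quartile_contrast_cm, 0)
  expect_true(is.na(de$cm_per_unit))

  co$height <- NA_real_
  expect_error(grs_descriptives(grs_const, co), "height")
})

test_that("a score unrelated to height shows a near-zero slope", {
  set.seed(15)
  co <- make_cohort(sprintf("p%d", 1:800), rep(0:1, 400),
                    height = rnorm(800, 163, 6))
  grs <- structure(
    data.frame(participant_id = co$participant_id,
               score = runif(800, 15, 19), subset_label = "x"),
    class = c("grs_vector", "data.frame"))
  de <- grs_descriptives(grs, co)
  expect_lt(abs(de$cm_per_unit), 3 * de$cm_per_unit_se)
})
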