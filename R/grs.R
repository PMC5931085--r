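#' Compute the weighted genetic risk score
#'
#' `score_i = sum_j w_j g_ij`: the weighted sum of effect-allele dosages
#' over the SNPs of the weight table. Column orientation is resolved first:
#' if a dosage column counts the other allele, dosages are flipped to
#' `2 - d` before weighting; the score therefore always sums
#' height-increasing alleles. The score is in weighted-allele units
#' (predicted extra height relative to carrying no height-increasing
#' alleles, on the scale of the weights).
#'
#' @param weights a weight table (see [validate_weight_table()]); weights
#'   must be non-negative after orientation.
#' @param dosages numeric matrix, participants in rows (rownames =
#'   participant IDs), SNPs in columns (colnames = rsids), entries in
#'   \[0, 2\]. An optional `counted_allele` attribute (named character,
#'   rsid -> allele) declares which allele each column counts; columns
#'   without a declaration are assumed to count the effect allele.
#' @param subset_label label stored on the result (e.g., `"GRS-609"`).
#' @param max_missing maximum tolerated fraction of missing dosage entries
#'   per SNP; any SNP exceeding it fails loudly (the expectation is that
#'   sporadically missing genotyped calls have already been filled with
#'   imputed dosages upstream).
#' @return a data.frame of class `grs_vector` with columns
#'   `participant_id`, `score`, `subset_label`.
#' @examples
#' \dontrun{
#' grs <- compute_grs(qc_filter(w), dosages, subset_label = "GRS-609")
#' }
#' @export
compute_grs <- function(weights, dosages, subset_label = "GRS",
                        max_missing = 0.025) {
  weights <- validate_weight_table(weights)
  if (is.null(colnames(dosages)) || is.null(rownames(dosages))) {
    stop_bad_arg("dosages", "matrix must have participant rownames and rsid colnames")
  }
  missing_snps <- setdiff(weights$rsid, colnames(dosages))
  if (length(missing_snps)) {
    stop(sprintf("SNPs in weight table absent from dosage matrix: %s%s",
                 paste(utils::head(missing_snps, 10), collapse = ", "),
                 if (length(missing_snps) > 10) ", ..." else ""),
         call. = FALSE)
  }
  d <- dosages[, weights$rsid, drop = FALSE]

  na_frac <- colMeans(is.na(d))
  if (any(na_frac > 0)) {
    bad <- na_frac > max_missing
    if (any(bad)) {
      stop(sprintf(
        "missing dosages exceed %.1f%% for SNP(s): %s; fill missing genotyped calls with imputed dosages before scoring",
        100 * max_missing,
        paste(utils::head(colnames(d)[bad], 5), collapse = ", ")),
        call. = FALSE)
    }
    # sporadic missingness: mean-dosage fill, logged
    hm_log("compute_grs: filling %d sporadically missing entries with per-SNP means",
           sum(is.na(d)))
    means <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- means[idx[, 2]]
  }

  counted <- attr(dosages, "counted_allele")
  if (!is.null(counted)) {
    counted <- counted[weights$rsid]
    flip <- !is.na(counted) & counted == weights$other_allele
    neither <- !is.na(counted) & counted != weights$effect_allele &
      counted != weights$other_allele
    if (any(neither)) {
      stop(sprintf("counted allele matches neither table allele for: %s",
                   paste(weights$rsid[neither], collapse = ", ")),
           call. = FALSE)
    }
    if (any(flip)) {
      hm_log("compute_grs: flipping %d column(s) counted on the other allele",
             sum(flip))
      d[, flip] <- 2 - d[, flip, drop = FALSE]
    }
  }

  out_of_range <- which(d < -1e-9 | d > 2 + 1e-9, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1, ]
    stop(sprintf("dosage outside [0, 2]: SNP %s, participant %s (value %.4f)",
                 colnames(d)[i[2]], rownames(d)[i[1]], d[i[1], i[2]]),
         call. = FALSE)
  }
  score <- as.numeric(d %*% weights$weight)
  res <- data.frame(participant_id = rownames(d), score = score,
                    subset_label = subset_label, stringsAsFactors = FALSE)
  class(res) <- c("grs_vector", "data.frame")
  res
}

#' First-stage descriptive diagnostics of the score
#'
#' Summarises the score distribution in controls (median, interquartile
#' range, range), the cm-per-unit slope of height on the score, and the
#' mean-height contrast between the top and bottom score quartiles, among
#' participants with observed height.
#'
#' @param grs a `grs_vector` from [compute_grs()].
#' @param cohort phenotype data.frame with `participant_id`, `status`,
#'   `height`.
#' @return a list with `score_median`, `score_iqr`, `score_range` (controls),
#'   `cm_per_unit` with its SE, `quartile_contrast_cm`, and `n`.
#' @export
grs_descriptives <- function(grs, cohort) {
  m <- merge(grs, cohort[, c("participant_id", "status", "height")],
             by = "participant_id")
  obs <- m[!is.na(m$height), , drop = FALSE]
  if (nrow(obs) == 0) {
    stop("no participants with observed height", call. = FALSE)
  }
  ctrl <- obs[obs$status == 0, , drop = FALSE]
  if (nrow(ctrl) == 0) ctrl <- obs
  if (stats::var(obs$score) > 0) {
    fit <- stats::lm(height ~ score, data = obs)
    co <- summary(fit)$coefficients
    slope <- unname(co["score", "Estimate"])
    slope_se <- unname(co["score", "Std. Error"])
  } else {
    slope <- NA_real_
    slope_se <- NA_real_
  }
  qs <- stats::quantile(obs$score, c(0.25, 0.75))
  top <- obs$height[obs$score >= qs[2]]
  bottom <- obs$height[obs$score <= qs[1]]
  contrast <- if (qs[1] == qs[2]) 0 else mean(top) - mean(bottom)
  list(score_median = stats::median(ctrl$score),
       score_iqr = unname(stats::quantile(ctrl$score, c(0.25, 0.75))),
       score_range = range(ctrl$score),
       cm_per_unit = slope,
       cm_per_unit_se = slope_se,
       quartile_contrast_cm = contrast,
       n = nrow(obs))
}
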