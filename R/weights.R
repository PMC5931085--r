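#' Validate (and orient) a SNP weight table
#'
#' The weight table carries, per instrument SNP, the external GWAS
#' per-allele height effect (`weight`), allele labels, genotyped/imputed
#' status with imputation quality, control minor allele frequency, a locus
#' grouping, and pleiotropy annotation tags. Weights are stored oriented to
#' the height-increasing allele: any row with a negative weight is
#' re-oriented at load time (alleles swapped, weight negated), so that
#' downstream scores sum height-increasing alleles.
#'
#' @param weights data.frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `weight`, `genotyped`, `imputation_r2`, `control_maf`,
#'   `locus_group`, `annotations`.
#' @return the validated, oriented weight table.
#' @export
validate_weight_table <- function(weights) {
  need <- c("rsid", "effect_allele", "other_allele", "weight", "genotyped",
            "imputation_r2", "control_maf", "locus_group", "annotations")
  missing <- setdiff(need, names(weights))
  if (length(missing)) {
    stop_bad_arg("weights", paste("missing columns:",
                                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(weights$rsid)) {
    stop_bad_arg("weights", "duplicated rsids")
  }
  neg <- which(!is.na(weights$weight) & weights$weight < 0)
  if (length(neg)) {
    hm_log("weight table: re-orienting %d SNP(s) to the height-increasing allele",
           length(neg))
    ea <- weights$effect_allele[neg]
    weights$effect_allele[neg] <- weights$other_allele[neg]
    weights$other_allele[neg] <- ea
    weights$weight[neg] <- -weights$weight[neg]
  }
  imputed_na <- !weights$genotyped & is.na(weights$imputation_r2)
  if (any(imputed_na)) {
    stop_bad_arg("weights", sprintf(
      "imputed SNPs without imputation_r2: %s",
      paste(utils::head(weights$rsid[imputed_na], 5), collapse = ", ")))
  }
  weights
}

#' Exclude poorly-imputed SNPs
#'
#' Retains genotyped SNPs unconditionally and imputed SNPs whose imputation
#' quality r-squared is at least `min_imputation_r2`. With the conventional
#' 0.6 threshold a 697-SNP height panel with 92 genotyped SNPs reduces to
#' 609 (92 genotyped / 517 imputed).
#'
#' @param weights a weight table (see [validate_weight_table()]).
#' @param min_imputation_r2 quality threshold in \[0, 1\].
#' @return the filtered weight table.
#' @export
qc_filter <- function(weights, min_imputation_r2 = 0.6) {
  if (!is.numeric(min_imputation_r2) || min_imputation_r2 < 0 ||
      min_imputation_r2 > 1) {
    stop_bad_arg("min_imputation_r2", "must lie in [0, 1]")
  }
  weights <- validate_weight_table(weights)
  keep <- weights$genotyped | weights$imputation_r2 >= min_imputation_r2
  out <- weights[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("qc_filter removed every SNP; lower `min_imputation_r2`",
         call. = FALSE)
  }
  hm_log("qc_filter: retained %d of %d SNPs (%d genotyped / %d imputed), removed %d",
         nrow(out), nrow(weights), sum(out$genotyped), sum(!out$genotyped),
         nrow(weights) - nrow(out))
  rownames(out) <- NULL
  out
}

#' Sensitivity subsets of the SNP weight table
#'
#' Implements the instrument-sensitivity subsets: dropping low-frequency
#' SNPs, restricting to well-imputed or directly genotyped SNPs, keeping one
#' SNP per distinct locus, or excluding SNPs carrying specified pleiotropy
#' annotation tags.
#'
#' @param weights a weight table.
#' @param rule one of `"maf-at-least"`, `"imputation-quality-at-least"`,
#'   `"one-per-locus"` (keeps, per `locus_group`, the SNP with the largest
#'   weight), `"genotyped-only"`, `"exclude-annotations"`.
#' @param threshold numeric threshold for the two `-at-least` rules.
#' @param tags character vector of annotation tags for
#'   `"exclude-annotations"` (a SNP is removed if any of its
#'   semicolon-delimited tags is in `tags`; an empty set removes nothing).
#' @return the filtered weight table.
#' @examples
#' \dontrun{
#' grs_subset(w, "maf-at-least", threshold = 0.05)
#' grs_subset(w, "exclude-annotations", tags = c("hormone-level"))
#' }
#' @export
grs_subset <- function(weights, rule, threshold = NULL, tags = NULL) {
  weights <- validate_weight_table(weights)
  rules <- c("maf-at-least", "imputation-quality-at-least", "one-per-locus",
             "genotyped-only", "exclude-annotations")
  if (!is.character(rule) || length(rule) != 1 || !(rule %in% rules)) {
    stop_bad_arg("rule", paste("must be one of:", paste(rules, collapse = ", ")))
  }
  keep <- switch(rule,
    "maf-at-least" = {
      if (is.null(threshold)) stop_bad_arg("threshold", "required for maf-at-least")
      weights$control_maf >= threshold
    },
    "imputation-quality-at-least" = {
      if (is.null(threshold)) {
        stop_bad_arg("threshold", "required for imputation-quality-at-least")
      }
      weights$genotyped | weights$imputation_r2 >= threshold
    },
    "one-per-locus" = {
      best <- tapply(seq_len(nrow(weights)), weights$locus_group,
                     function(i) i[which.max(weights$weight[i])])
      seq_len(nrow(weights)) %in% unlist(best)
    },
    "genotyped-only" = weights$genotyped,
    "exclude-annotations" = {
      tags <- tags %||% character()
      if (length(tags) == 0) rep(TRUE, nrow(weights)) else {
        snp_tags <- strsplit(ifelse(is.na(weights$annotations), "",
                                    weights$annotations), ";", fixed = TRUE)
        !vapply(snp_tags, function(tt) any(tt %in% tags), logical(1))
      }
    })
  out <- weights[keep, , drop = FALSE]
  hm_log("grs_subset[%s]: retained %d of %d SNPs", rule, nrow(out),
         nrow(weights))
  rownames(out) <- NULL
  out
}
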