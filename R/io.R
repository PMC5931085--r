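# Readers and writers for the pipeline's plain-text interchange formats:
# weight TSV, dosage TSV (plink-.raw-style headers), phenotype CSV,
# grouping-map TSV and estimate tables.

#' Read and write SNP weight tables
#'
#' Tab-separated with header columns `rsid`, `effect_allele`,
#' `other_allele`, `weight`, `genotyped`, `imputation_r2`, `control_maf`,
#' `locus_group`, `annotations` (semicolon-delimited tags). Weights are
#' re-oriented to the height-increasing allele on read.
#'
#' @param path file path.
#' @param weights weight table to write.
#' @return `read_weight_table` returns the validated weight table;
#'   `write_weight_table` returns `path` invisibly.
#' @export
read_weight_table <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(annotations = "character"))
  w$genotyped <- as.logical(w$genotyped)
  validate_weight_table(w)
}

#' @rdname read_weight_table
#' @export
write_weight_table <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write dosage matrices
#'
#' Tab-separated: first column `participant_id`, then one column per SNP
#' named `<rsid>_<counted allele>` (the allele whose expected count the
#' dosage reports), entries in \[0, 2\].
#'
#' @param path file path.
#' @param dosages numeric matrix with participant rownames, rsid colnames,
#'   and a `counted_allele` attribute.
#' @return `read_dosages` returns such a matrix; `write_dosages` returns
#'   `path` invisibly.
#' @export
read_dosages <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d$participant_id
  d$participant_id <- NULL
  header <- names(d)
  rsid <- sub("_[ACGT]$", "", header)
  allele <- sub("^.*_([ACGT])$", "\\1", header)
  m <- as.matrix(d)
  dimnames(m) <- list(ids, rsid)
  attr(m, "counted_allele") <- stats::setNames(allele, rsid)
  m
}

#' @rdname read_dosages
#' @export
write_dosages <- function(dosages, path) {
  counted <- attr(dosages, "counted_allele")
  header <- if (is.null(counted)) colnames(dosages) else {
    paste0(colnames(dosages), "_", counted[colnames(dosages)])
  }
  d <- as.data.frame(dosages)
  names(d) <- header
  d <- cbind(participant_id = rownames(dosages), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from a VCF with a per-genotype dosage field
#'
#' Extracts the `DS` FORMAT field (expected count of the ALT allele) from a
#' VCF; the ALT allele becomes the counted allele of each column. Requires
#' the `vcfR` package.
#'
#' @param path VCF path (plain or gzipped).
#' @param field FORMAT field holding the dosage (default `"DS"`).
#' @return a dosage matrix as in [read_dosages()].
#' @export
read_dosages_vcf <- function(path, field = "DS") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = field, as.numeric = TRUE)
  rsid <- v@fix[, "ID"]
  alt <- v@fix[, "ALT"]
  m <- t(ds)
  colnames(m) <- rsid
  attr(m, "counted_allele") <- stats::setNames(alt, rsid)
  m
}

#' Read and write phenotype/covariate tables
#'
#' Comma-separated with header; columns as produced by [simulate_cohort()]:
#' `participant_id`, `study`, `group`, `status`, `behaviour`, `histotype`,
#' `grade`, `site`, `height`, `age`, `PC1`..`PC5`, `parous`, `oc_use`,
#' `education_years`, `menarche_age`.
#'
#' @param path file path.
#' @param cohort phenotype data.frame.
#' @return `read_phenotypes` returns the data.frame; `write_phenotypes`
#'   returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the study grouping map
#'
#' Tab-separated, columns `study` and `group`.
#'
#' @param path file path.
#' @param grouping data.frame with `study`, `group`.
#' @return `read_grouping` returns the data.frame; `write_grouping` returns
#'   `path` invisibly.
#' @export
read_grouping <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_grouping
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(grouping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Generic TSV table writer/reader used for estimate, meta, forest and
# screen tables; a "#key=value" comment header carries provenance.
write_table_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("#%s=%s", k, provenance[[k]]), con)
    }
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
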