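#' Statistical power for Mendelian randomisation with a binary outcome
#'
#' Closed-form power of a two-sided Wald test of the causal effect in an MR
#' design with a binary outcome, via the noncentral chi-square
#' approximation: with case fraction `K` and odds ratio `OR` per standard
#' deviation of the exposure,
#' `b = K (OR / (1 + K (OR - 1)) - 1)` is the approximate risk-difference
#' slope, its variance is `v = (K (1 - K) - b^2) / (n_total r2_xz)` where
#' `r2_xz` is the variance in exposure explained by the instrument, the
#' noncentrality is `ncp = b^2 / v`, and power is the survival function of
#' the noncentral chi-square (1 df, `ncp`) at the central chi-square
#' critical value for `alpha`.
#'
#' @param n_total total number of participants (cases + controls).
#' @param case_fraction proportion of cases, in (0, 1).
#' @param r2_xz instrument-exposure variance explained, in (0, 1).
#' @param or_per_sd true odds ratio per SD of exposure (> 0).
#' @param alpha two-sided significance level, in (0, 1).
#' @return the power, a fraction in \[alpha, 1).
#' @examples
#' # a 39,398-participant design (41.6% cases) with an instrument explaining
#' # 17% of exposure variance has ~97% power for an OR of 1.10:
#' mr_power_binary(39398, 16395 / 39398, 0.17, 1.10)
#' @export
mr_power_binary <- function(n_total, case_fraction, r2_xz, or_per_sd,
                            alpha = 0.05) {
  if (!is_fraction(case_fraction, open = TRUE)) {
    stop_bad_arg("case_fraction", "must lie strictly inside (0, 1)")
  }
  if (!is_fraction(r2_xz, open = TRUE)) {
    stop_bad_arg("r2_xz", "must lie strictly inside (0, 1)")
  }
  if (!is_fraction(alpha, open = TRUE)) {
    stop_bad_arg("alpha", "must lie strictly inside (0, 1)")
  }
  if (!is.numeric(or_per_sd) || or_per_sd <= 0) {
    stop_bad_arg("or_per_sd", "must be > 0")
  }
  if (!is.numeric(n_total) || n_total <= 0) {
    stop_bad_arg("n_total", "must be > 0")
  }
  K <- case_fraction
  OR <- or_per_sd
  b <- K * (OR / (1 + K * (OR - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (n_total * r2_xz)
  if (v <= 0) {
    stop("degenerate parameters: implied variance is non-positive",
         call. = FALSE)
  }
  ncp <- b^2 / v
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
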