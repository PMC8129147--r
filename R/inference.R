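#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: `q_(i) = min_{k >= i} m p_(k) / k`, capped
#' at 1 and mapped back to the input order (a thin wrapper over
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    abort("p-values must lie in [0, 1]", class = "mrsuite_input_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Classify MR associations within an FDR family
#'
#' Appends q-values and the three-way classification used for reporting:
#' `significant` when `q < q_threshold`; `suggestive` when `p < alpha` but
#' the q-value does not clear the FDR bar; `null` otherwise. Rows with
#' missing p-values stay unclassified (`NA`) and do not consume FDR budget.
#'
#' @param results Data frame with a `pval` column (one row per exposure,
#'   e.g. a bind of [tidy.mr_result()] rows for the primary IVW analyses of
#'   one family).
#' @param alpha Nominal significance level for the suggestive band
#'   (default 0.05).
#' @param q_threshold FDR threshold (default 0.05).
#' @return The input tibble with `qval` and `classification` columns.
#' @export
classify <- function(results, alpha = 0.05, q_threshold = 0.05) {
  results <- as_tibble(results)
  stopifnot("pval" %in% names(results))
  q <- rep(NA_real_, nrow(results))
  ok <- !is.na(results$pval)
  q[ok] <- bh_fdr(results$pval[ok])
  mutate(results,
    qval = q,
    classification = case_when(
      is.na(.data$pval) ~ NA_character_,
      .data$qval < q_threshold ~ "significant",
      .data$pval < alpha ~ "suggestive",
      TRUE ~ "null"
    )
  )
}

#' Analytic power for two-sample MR
#'
#' Normal-approximation power for detecting a causal odds ratio `or_alt`
#' with a binary outcome: with `b = log(or_alt)`, the expected z-statistic
#' magnitude is `x = |b| sqrt(n_total r2 cf (1 - cf))` and two-sided power
#' at level `alpha` is `pnorm(-z + x) + pnorm(-z - x)` with
#' `z = qnorm(1 - alpha/2)`. At `or_alt = 1` this reduces to `alpha`
#' exactly, and power is symmetric in `or_alt` and `1/or_alt`.
#'
#' @param n_total Combined outcome-GWAS sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2 Variance in the exposure explained by the instruments, in
#'   (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
#' @examples
#' mr_power_binary(n_total = 63926, case_fraction = 21982 / 63926,
#'                 r2 = 0.02, or_alt = 1.10)
mr_power_binary <- function(n_total, case_fraction, r2, or_alt, alpha = 0.05) {
  if (!(case_fraction > 0 && case_fraction < 1)) {
    abort("case_fraction must lie in (0, 1)", class = "mrsuite_input_error")
  }
  if (!(r2 > 0 && r2 < 1)) abort("r2 must lie in (0, 1)", class = "mrsuite_input_error")
  if (!(or_alt > 0)) abort("or_alt must be > 0", class = "mrsuite_input_error")
  b <- log(or_alt)
  x <- abs(b) * sqrt(n_total * r2 * case_fraction * (1 - case_fraction))
  z <- qnorm(1 - alpha / 2)
  pnorm(-z + x) + pnorm(-z - x)
}

#' @rdname mr_power_binary
#' @param beta_alt Alternative-hypothesis effect size in standardized
#'   outcome units (continuous outcome).
#' @export
mr_power_continuous <- function(n_total, r2, beta_alt, alpha = 0.05) {
  if (!(r2 > 0 && r2 < 1)) abort("r2 must lie in (0, 1)", class = "mrsuite_input_error")
  x <- abs(beta_alt) * sqrt(n_total * r2)
  z <- qnorm(1 - alpha / 2)
  pnorm(-z + x) + pnorm(-z - x)
}
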