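new_mr_result <- function(method, estimate, se, pval, n_snps,
                          effects_model = "n/a", Q = NA_real_, Q_pval = NA_real_,
                          ci_low = NULL, ci_high = NULL, extra = list(),
                          exposure = "exposure", outcome = "outcome",
                          outcome_type = "continuous") {
  ci_low <- ci_low %||% (estimate - qnorm(0.975) * se)
  ci_high <- ci_high %||% (estimate + qnorm(0.975) * se)
  structure(list(
    method = method, exposure = exposure, outcome = outcome,
    outcome_type = outcome_type,
    estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
    pval = pval, n_snps = n_snps, effects_model = effects_model,
    Q = Q, Q_pval = Q_pval, extra = extra
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %s -> %s\n", x$method, x$exposure, x$outcome))
  est_line <- sprintf("  estimate %.4g (95%% CI %.4g, %.4g), p = %.3g, %d SNPs",
                      x$estimate, x$ci_low, x$ci_high, x$pval, x$n_snps)
  cat(est_line, "\n")
  if (x$outcome_type == "binary-logOR") {
    cat(sprintf("  OR %.4g (95%% CI %.4g, %.4g)\n",
                exp(x$estimate), exp(x$ci_low), exp(x$ci_high)))
  }
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity Q = %.3g (p = %.3g), %s effects\n",
                x$Q, x$Q_pval, x$effects_model))
  }
  invisible(x)
}

#' Tidy a Mendelian randomization result
#'
#' @param x An `mr_result` object.
#' @param ... Unused.
#' @return A one-row tibble with `exposure`, `outcome`, `method`, `n_snps`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`, `effects_model`, `Q`,
#'   `Q_pval`, and (for MR-Egger) `intercept`, `intercept_se`,
#'   `intercept_pval`. When the outcome is on the log-odds scale an `or`
#'   column with its CI is appended.
#' @export
tidy.mr_result <- function(x, ...) {
  out <- tibble(
    exposure = x$exposure, outcome = x$outcome, method = x$method,
    n_snps = x$n_snps, estimate = x$estimate, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    effects_model = x$effects_model, Q = x$Q, Q_pval = x$Q_pval,
    intercept = x$extra$intercept %||% NA_real_,
    intercept_se = x$extra$intercept_se %||% NA_real_,
    intercept_pval = x$extra$intercept_pval %||% NA_real_
  )
  if (identical(x$outcome_type, "binary-logOR")) {
    out <- mutate(out, or = exp(.data$estimate),
                  or_ci_low = exp(.data$ci_low), or_ci_high = exp(.data$ci_high))
  }
  out
}

#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate, se = x$se, pval = x$pval,
         n_snps = x$n_snps, Q = x$Q, Q_pval = x$Q_pval,
         effects_model = x$effects_model)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

na_mr_result <- function(method, exposure, outcome, outcome_type, n_snps = 0L,
                         note = "not applicable") {
  new_mr_result(method, NA_real_, NA_real_, NA_real_, n_snps,
                effects_model = "n/a", ci_low = NA_real_, ci_high = NA_real_,
                extra = list(note = note),
                exposure = exposure, outcome = outcome,
                outcome_type = outcome_type)
}
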