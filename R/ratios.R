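#' Per-variant Wald ratio estimates
#'
#' Computes the variant-specific causal estimate `theta_j = beta_y / beta_x`
#' with a delta-method standard error. The first-order SE,
#' `se_y / |beta_x|`, ignores uncertainty in the instrument-exposure effect
#' and makes inverse-variance weighting exactly equivalent to weighted
#' regression through the origin; the second-order SE,
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)`, adds it back.
#' Variants with `beta_x == 0` are dropped and listed in the `dropped`
#' attribute.
#'
#' @param h An `mr_harmonized` set (see [harmonize()] / [as_harmonized()]).
#' @param se_order `"first"` (default) or `"second"`.
#' @return An `mr_ratios` tibble with columns `snp`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `theta`, `se_theta`, `weight` (`1/se_theta^2`).
#' @export
#' @examples
#' h <- as_harmonized(data.frame(beta_x = 0.5, se_x = 0.01,
#'                               beta_y = 0.1, se_y = 0.05))
#' wald_ratios(h)  # theta = 0.2, se = 0.1
wald_ratios <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  df <- as_tibble(h)
  zero <- df$beta_x == 0
  if (all(zero)) {
    abort("all instrument-exposure effects are zero; Wald ratios undefined",
          class = "mrsuite_degenerate_error")
  }
  dropped <- df$snp[zero]
  df <- df[!zero, ]
  theta <- df$beta_y / df$beta_x
  se_theta <- switch(se_order,
    first = df$se_y / abs(df$beta_x),
    second = sqrt(df$se_y^2 / df$beta_x^2 +
                  df$beta_y^2 * df$se_x^2 / df$beta_x^4)
  )
  out <- tibble(
    snp = df$snp, beta_x = df$beta_x, se_x = df$se_x,
    beta_y = df$beta_y, se_y = df$se_y,
    theta = theta, se_theta = se_theta, weight = 1 / se_theta^2
  )
  structure(out,
    exposure_name = attr(h, "exposure_name"),
    outcome_name = attr(h, "outcome_name"),
    outcome_type = attr(h, "outcome_type"),
    se_order = se_order,
    dropped = dropped,
    class = c("mr_ratios", class(out))
  )
}
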