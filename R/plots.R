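#' Forest plot of per-exposure MR estimates
#'
#' One row per exposure (and method, if several are present), point
#' estimate with 95% CI, faceted by outcome. For binary outcomes pass
#' `exponentiate = TRUE` to draw odds ratios on a log axis.
#'
#' @param results Tibble of result rows (e.g. `study$families` or
#'   `study$results`) with `exposure`, `outcome`, `estimate`, `ci_low`,
#'   `ci_high`, and optionally `method`, `classification`.
#' @param exponentiate Draw `exp(estimate)` on a log scale.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, exponentiate = FALSE) {
  df <- filter(as_tibble(results), !is.na(.data$estimate))
  trans <- if (exponentiate) exp else identity
  df <- mutate(df,
    est = trans(.data$estimate), lo = trans(.data$ci_low), hi = trans(.data$ci_high)
  )
  colour_var <- if ("classification" %in% names(df)) "classification" else
    if ("method" %in% names(df)) "method" else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = trans(0), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = if (exponentiate) "Odds ratio (95% CI)" else
                    "Causal estimate (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  p <- if (is.null(colour_var)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_var]]))
  }
  if (exponentiate) p <- p + ggplot2::scale_x_log10()
  p
}

#' Scatter plot of variant associations colored by cluster
#'
#' Outcome against exposure per-variant associations with 95% CI bars,
#' the display behind mechanism-clustering figures.
#'
#' @param scatter A [cluster_scatter_table()] tibble (or any tibble with
#'   `beta_x`, `beta_y`, `ci_half_x`, `ci_half_y` and optionally `cluster`).
#' @return A ggplot object.
#' @export
plot_cluster_scatter <- function(scatter) {
  df <- as_tibble(scatter)
  aes_pt <- if ("cluster" %in% names(df)) {
    ggplot2::aes(x = .data$beta_x, y = .data$beta_y, colour = .data$cluster)
  } else {
    ggplot2::aes(x = .data$beta_x, y = .data$beta_y)
  }
  ggplot2::ggplot(df, aes_pt) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_y - .data$ci_half_y,
                                        ymax = .data$beta_y + .data$ci_half_y),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_x - .data$ci_half_x,
                                         xmax = .data$beta_x + .data$ci_half_x),
                            height = 0, alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Association with exposure",
                  y = "Association with outcome") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_clust_fit <- function(object, ...) {
  df <- object$assignments
  df$ci_half_x <- 0
  df$ci_half_y <- qnorm(0.975) * df$se_theta
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$probability,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Variant-specific causal estimate",
                  y = "Assignment probability", colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_study <- function(object, ...) {
  plot_forest(object$families, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
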