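#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Pools variant-specific causal estimates with weights `1/se_theta^2`.
#' Under first-order delta SEs this is numerically identical to weighted
#' least squares of `beta_y` on `beta_x` through the origin with weights
#' `1/se_y^2`. Heterogeneity is measured by Cochran's Q; with `model =
#' "auto"` a Q-derived p-value below 0.05 switches to a multiplicative
#' random-effects model whose SE is the fixed-effect SE inflated by
#' `max(1, sqrt(Q / (J - 1)))`, so the random-effects SE never falls below
#' the fixed one. With a single instrument Q is undefined (`NA`) and the
#' fixed model is forced; the result then equals the variant's Wald ratio.
#'
#' @param r An `mr_ratios` object from [wald_ratios()].
#' @param model `"auto"` (heterogeneity switch), `"fixed"`, or `"random"`.
#' @return An `mr_result`; p-value from the standard normal.
#' @export
mr_ivw <- function(r, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  J <- nrow(r)
  if (J == 0) {
    abort("empty ratio set", class = "mrsuite_degenerate_error")
  }
  w <- r$weight
  est <- sum(w * r$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (J == 1) {
    Q <- NA_real_; Q_pval <- NA_real_
    effects <- "fixed"; se <- se_fixed
  } else {
    Q <- sum(w * (r$theta - est)^2)
    Q_pval <- pchisq(Q, df = J - 1, lower.tail = FALSE)
    effects <- switch(model,
      fixed = "fixed",
      random = "random",
      auto = if (Q_pval < 0.05) "random" else "fixed"
    )
    se <- if (effects == "random") {
      se_fixed * max(1, sqrt(Q / (J - 1)))
    } else {
      se_fixed
    }
  }
  pval <- 2 * pnorm(-abs(est / se))
  new_mr_result("IVW", est, se, pval, J, effects_model = effects,
                Q = Q, Q_pval = Q_pval,
                exposure = attr(r, "exposure_name"),
                outcome = attr(r, "outcome_name"),
                outcome_type = attr(r, "outcome_type"))
}

weighted_median_est <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(r, estimator, n_boot, seed) {
  if (n_boot < 1) return(NA_real_)
  set.seed(seed)
  J <- nrow(r)
  reps <- vapply(seq_len(n_boot), function(b) {
    estimator(rnorm(J, r$theta, r$se_theta), r$weight)
  }, numeric(1))
  sd(reps)
}

#' Weighted median causal estimate
#'
#' Consistent when instruments carrying at least half the total weight are
#' valid. The estimate is the 50% crossing point of the standardized
#' cumulative weight function over the sorted Wald ratios, by linear
#' interpolation; the SE comes from a seeded parametric bootstrap that
#' redraws each ratio from `Normal(theta_j, se_theta_j)`.
#'
#' @param r An `mr_ratios` object with at least 3 variants.
#' @param n_boot Bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and reports `NA` SE/p (estimate only).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(r, n_boot = 1000, seed = 1) {
  if (nrow(r) < 3) {
    abort("weighted median requires at least 3 instruments",
          class = "mrsuite_insufficient_error")
  }
  est <- weighted_median_est(r$theta, r$weight)
  se <- boot_se(r, function(th, w) weighted_median_est(th, w), n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(est / se))
  new_mr_result("weighted median", est, se, pval, nrow(r),
                extra = list(n_boot = n_boot, seed = seed),
                exposure = attr(r, "exposure_name"),
                outcome = attr(r, "outcome_name"),
                outcome_type = attr(r, "outcome_type"))
}

mode_bandwidth <- function(theta, phi) {
  s <- sd(theta)
  iqr <- stats::IQR(theta) / 1.34
  core <- if (iqr > 0) min(s, iqr) else s
  phi * 0.9 * core * length(theta)^(-1 / 5)
}

weighted_mode_est <- function(theta, w, phi = 1, n_grid = 1000) {
  h <- mode_bandwidth(theta, phi)
  if (!is.finite(h) || h <= 0) return(theta[1])  # all ratios identical
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens <- colSums(w * dnorm(outer(theta, grid, "-") / h))
  grid[which.max(dens)]
}

#' Weighted mode causal estimate
#'
#' Consistent when the largest group of instruments sharing the same
#' asymptotic ratio estimate is valid, even if they are a minority. The
#' estimate is the argmax of a weighted Gaussian kernel density over the
#' Wald ratios, with bandwidth `phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)`
#' evaluated on a fine grid; SE by parametric bootstrap as in
#' [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth inflation factor (default 1).
#' @param n_grid Grid resolution for the density argmax.
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(r, phi = 1, n_boot = 1000, seed = 1, n_grid = 1000) {
  if (nrow(r) < 3) {
    abort("weighted mode requires at least 3 instruments",
          class = "mrsuite_insufficient_error")
  }
  est <- weighted_mode_est(r$theta, r$weight, phi, n_grid)
  se <- boot_se(r, function(th, w) weighted_mode_est(th, w, phi, n_grid),
                n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(est / se))
  new_mr_result("weighted mode", est, se, pval, nrow(r),
                extra = list(phi = phi, n_boot = n_boot, seed = seed),
                exposure = attr(r, "exposure_name"),
                outcome = attr(r, "outcome_name"),
                outcome_type = attr(r, "outcome_type"))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept, after orienting every variant so that
#' `beta_x >= 0`. The slope is the causal estimate under the InSIDE
#' assumption (instrument strength independent of direct effects); the
#' intercept estimates average directional pleiotropy and its test is the
#' Egger pleiotropy test. Coefficient SEs are inflated by the multiplicative
#' overdispersion factor `max(1, sqrt(RSS_w / (J - 2)))` and p-values use
#' the t distribution with `J - 2` degrees of freedom.
#'
#' @param h An `mr_harmonized` set with at least 3 variants.
#' @return An `mr_result` for the slope; `extra` carries `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  df <- as_tibble(h)
  J <- nrow(df)
  if (J < 3) {
    abort("MR-Egger requires at least 3 instruments",
          class = "mrsuite_insufficient_error")
  }
  flip <- sign(df$beta_x)
  flip[flip == 0] <- 1
  bx <- df$beta_x * flip
  by <- df$beta_y * flip
  wt <- 1 / df$se_y^2
  fit <- lm(by ~ bx, weights = wt)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(weighted RSS / (J - 2))
  infl <- max(1, sigma)
  se_unscaled <- sm$coefficients[, "Std. Error"] / sigma
  ses <- se_unscaled * infl
  coefs <- coef(fit)
  tvals <- coefs / ses
  pvals <- 2 * pt(-abs(tvals), df = J - 2)
  tcrit <- stats::qt(0.975, df = J - 2)
  new_mr_result("MR-Egger", unname(coefs["bx"]), unname(ses["bx"]),
                unname(pvals["bx"]), J,
                ci_low = unname(coefs["bx"] - tcrit * ses["bx"]),
                ci_high = unname(coefs["bx"] + tcrit * ses["bx"]),
                extra = list(
                  intercept = unname(coefs["(Intercept)"]),
                  intercept_se = unname(ses["(Intercept)"]),
                  intercept_pval = unname(pvals["(Intercept)"]),
                  overdispersion = infl
                ),
                exposure = attr(h, "exposure_name"),
                outcome = attr(h, "outcome_name"),
                outcome_type = attr(h, "outcome_type"))
}

#' Contamination-mixture causal estimate
#'
#' Profiles a two-component likelihood over a grid of candidate causal
#' effects: a valid instrument's Wald ratio is normal about the causal
#' effect with its delta-method SE, an invalid one is normal about zero
#' with variance inflated by `psi^2`. At each grid value every variant
#' contributes the larger of the two log-densities; the estimate is the
#' grid argmax and the 95% confidence set is the grid region within
#' `qchisq(0.95, 1) / 2` of the maximum, reported as a union of intervals
#' (multimodality is not forced away). The p-value is a likelihood-ratio
#' test of `theta = 0` against the profile maximum.
#'
#' @param r An `mr_ratios` object with at least 3 variants.
#' @param psi Standard deviation of invalid instruments' ratio estimates;
#'   default `1.5 * sd(theta)`.
#' @param n_grid Number of grid points (default 1000) spanning
#'   `[min(theta) - 2 max(se), max(theta) + 2 max(se)]`.
#' @return An `mr_result`; `extra` carries the interval union
#'   (`intervals` tibble), the per-variant `valid` assignment at the
#'   maximum, and `psi`.
#' @export
mr_conmix <- function(r, psi = NULL, n_grid = 1000) {
  J <- nrow(r)
  if (J < 3) {
    abort("contamination mixture requires at least 3 instruments",
          class = "mrsuite_insufficient_error")
  }
  psi <- psi %||% (1.5 * sd(r$theta))
  if (!is.finite(psi) || psi <= 0) psi <- max(r$se_theta)
  lo <- min(r$theta) - 2 * max(r$se_theta)
  hi <- max(r$theta) + 2 * max(r$se_theta)
  if (!(hi > lo) || n_grid < 10) {
    abort("degenerate contamination-mixture grid", class = "mrsuite_config_error")
  }
  grid <- seq(lo, hi, length.out = n_grid)
  se_inv <- sqrt(r$se_theta^2 + psi^2)
  ll_invalid <- dnorm(r$theta, 0, se_inv, log = TRUE)          # J
  ll_valid <- t(vapply(grid, function(th) dnorm(r$theta, th, r$se_theta, log = TRUE),
                       numeric(J)))                            # n_grid x J
  contrib <- pmax(ll_valid, rep(ll_invalid, each = n_grid))
  profile <- rowSums(contrib)
  imax <- which.max(profile)
  est <- grid[imax]
  inside <- profile >= max(profile) - qchisq(0.95, 1) / 2
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- tibble(
    lo = grid[starts[runs$values]],
    hi = grid[ends[runs$values]]
  )
  valid <- ll_valid[imax, ] >= ll_invalid
  ll0 <- sum(pmax(dnorm(r$theta, 0, r$se_theta, log = TRUE), ll_invalid))
  pval <- pchisq(2 * (profile[imax] - ll0), df = 1, lower.tail = FALSE)
  new_mr_result("contamination mixture", est, NA_real_, pval, J,
                ci_low = min(iv$lo), ci_high = max(iv$hi),
                extra = list(intervals = iv, valid = valid, psi = psi,
                             grid_step = grid[2] - grid[1]),
                exposure = attr(r, "exposure_name"),
                outcome = attr(r, "outcome_name"),
                outcome_type = attr(r, "outcome_type"))
}

#' MR-PRESSO global and per-variant outlier test
#'
#' The observed global residual sum of squares is
#' `sum_j w_j (beta_y_j - theta_hat(-j) * beta_x_j)^2` with `w_j = 1/se_y^2`
#' and `theta_hat(-j)` the leave-one-out IVW estimate. Its null distribution
#' is built by parametric simulation: outcome effects are redrawn as
#' `Normal(theta_hat(-j) * beta_x_j, se_y_j)` and the statistic recomputed
#' (including the leave-one-out estimates). The global empirical p-value is
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`; each variant's outlier
#' p-value is the empirical tail probability of its observed residual
#' contribution, Bonferroni-adjusted by the number of variants.
#'
#' @param h An `mr_harmonized` set with at least 4 variants.
#' @param n_sim Number of simulated null datasets (default 1000).
#' @param seed RNG seed.
#' @return A `presso_result` list: `global_rss_obs`, `global_pval`,
#'   `outliers` tibble (`snp`, `rss_contribution`, `pval`, `pval_adj`),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1) {
  df <- as_tibble(h)
  J <- nrow(df)
  if (J < 4) {
    abort("MR-PRESSO requires at least 4 instruments",
          class = "mrsuite_insufficient_error")
  }
  if (any(df$beta_x == 0)) {
    abort("MR-PRESSO requires nonzero instrument-exposure effects",
          class = "mrsuite_degenerate_error")
  }
  set.seed(seed)
  bx <- df$beta_x; by <- df$beta_y; sy <- df$se_y
  w_res <- 1 / sy^2                 # weights on outcome-scale residuals
  w_ivw <- bx^2 / sy^2              # first-order Wald weights
  theta <- by / bx

  loo <- function(th) {
    # leave-one-out IVW estimates for a vector (or matrix rows) of ratios
    (sum(w_ivw * th) - w_ivw * th) / (sum(w_ivw) - w_ivw)
  }
  theta_loo <- loo(theta)
  contrib_obs <- w_res * (by - theta_loo * bx)^2
  rss_obs <- sum(contrib_obs)

  # simulate under the leave-one-out fitted means
  mu <- theta_loo * bx
  by_star <- matrix(rnorm(n_sim * J, mean = rep(mu, each = n_sim),
                          sd = rep(sy, each = n_sim)), n_sim, J)
  th_star <- sweep(by_star, 2, bx, "/")
  s_all <- th_star %*% w_ivw
  th_loo_star <- (matrix(s_all, n_sim, J) - sweep(th_star, 2, w_ivw, "*")) /
    matrix(sum(w_ivw) - w_ivw, n_sim, J, byrow = TRUE)
  resid_star <- by_star - th_loo_star * matrix(bx, n_sim, J, byrow = TRUE)
  contrib_star <- sweep(resid_star^2, 2, w_res, "*")
  rss_star <- rowSums(contrib_star)

  global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + colSums(sweep(contrib_star, 2, contrib_obs, ">="))) / (n_sim + 1)
  structure(list(
    global_rss_obs = rss_obs,
    global_pval = global_pval,
    outliers = tibble(
      snp = df$snp, rss_contribution = contrib_obs,
      pval = outlier_p, pval_adj = pmin(1, outlier_p * J)
    ),
    n_sim = n_sim, seed = seed,
    exposure = attr(h, "exposure_name"),
    outcome = attr(h, "outcome_name")
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> %s -> %s: global RSS %.4g, p = %.3g (%d sims)\n",
              x$exposure, x$outcome, x$global_rss_obs, x$global_pval, x$n_sim))
  n_out <- sum(x$outliers$pval_adj < 0.05)
  cat(sprintf("  %d outlier variant(s) at adjusted p < 0.05\n", n_out))
  invisible(x)
}

#' @export
tidy.presso_result <- function(x, ...) x$outliers

#' @export
glance.presso_result <- function(x, ...) {
  tibble(global_rss_obs = x$global_rss_obs, global_pval = x$global_pval,
         n_outliers = sum(x$outliers$pval_adj < 0.05), n_sim = x$n_sim)
}
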