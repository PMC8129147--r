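# Shared fixtures and independent oracles used across the suite.

# Random harmonized set with heterogeneous SEs (no allele bookkeeping).
random_harmonized <- function(J, seed, theta = 0.2) {
  set.seed(seed)
  beta_x <- rnorm(J, 0.1, 0.03)
  beta_x[beta_x == 0] <- 0.01
  se_y <- runif(J, 0.01, 0.05)
  as_harmonized(data.frame(
    beta_x = beta_x,
    se_x = runif(J, 0.002, 0.01),
    beta_y = theta * beta_x + rnorm(J, 0, se_y),
    se_y = se_y
  ))
}

# Weighted least squares through the origin by explicit normal equations;
# the independent check for the IVW estimator under first-order SEs.
wls_origin_oracle <- function(h) {
  w <- 1 / h$se_y^2
  sxx <- sum(w * h$beta_x^2)
  list(coef = sum(w * h$beta_x * h$beta_y) / sxx, se = 1 / sqrt(sxx))
}

# WLS with intercept by explicit normal equations (coefficients only).
wls_intercept_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# Brute-force BH step-up: q_(i) = min_{k >= i} m p_(k) / k, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Weighted-median oracle: root of the standardized cumulative weight
# function (built as theta -> s, the inverse direction of the
# implementation's s -> theta interpolation).
weighted_median_oracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  s <- (cumsum(w[o]) - w[o] / 2) / sum(w)
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  sfun <- stats::approxfun(th, s, method = "linear", ties = "ordered")
  stats::uniroot(function(t) sfun(t) - 0.5, range(th), tol = 1e-12)$root
}
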