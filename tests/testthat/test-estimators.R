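test_that("Wald ratios and delta-method SEs follow the closed forms", {
  h <- as_harmonized(data.frame(beta_x = 0.5, se_x = 0.01,
                                beta_y = 0.1, se_y = 0.05))
  r <- wald_ratios(h)
  expect_equal(r$theta, 0.2)
  expect_equal(r$se_theta, 0.1)

  # zero exposure SE collapses the second-order SE onto the first-order one
  h2 <- as_harmonized(data.frame(beta_x = 1, se_x = 1e-300,
                                 beta_y = 0.3, se_y = 0.04))
  expect_equal(wald_ratios(h2, "first")$se_theta,
               wald_ratios(h2, "second")$se_theta, tolerance = 1e-12)

  # second-order SE dominates the first-order SE on random inputs
  set.seed(1)
  for (i in 1:50) {
    h3 <- random_harmonized(10, seed = i)
    expect_true(all(wald_ratios(h3, "second")$se_theta >=
                      wald_ratios(h3, "first")$se_theta))
  }

  # zero instrument effects are dropped; all-zero is degenerate
  h4 <- as_harmonized(data.frame(beta_x = c(0, 0.5), se_x = 0.01,
                                 beta_y = c(0.1, 0.1), se_y = 0.05))
  expect_equal(nrow(wald_ratios(h4)), 1)
  h5 <- as_harmonized(data.frame(beta_x = 0, se_x = 0.01,
                                 beta_y = 0.1, se_y = 0.05))
  expect_error(wald_ratios(h5), class = "mrsuite_degenerate_error")
})

test_that("IVW handles the single-variant and homogeneous limits", {
  h <- as_harmonized(data.frame(beta_x = 0.4, se_x = 0.01,
                                beta_y = 0.12, se_y = 0.02))
  res <- mr_ivw(wald_ratios(h))
  expect_equal(res$estimate, 0.3)
  expect_true(is.na(res$Q))
  expect_equal(res$effects_model, "fixed")

  # identical ratios: Q = 0 exactly, fixed model, common value recovered
  h2 <- as_harmonized(data.frame(beta_x = c(0.2, 0.4, 0.5), se_x = 0.01,
                                 beta_y = c(0.06, 0.12, 0.15), se_y = 0.02))
  res2 <- mr_ivw(wald_ratios(h2), model = "auto")
  expect_equal(res2$Q, 0)
  expect_equal(res2$Q_pval, 1)
  expect_equal(res2$effects_model, "fixed")
  expect_equal(res2$estimate, 0.3)
})

test_that("IVW equals weighted least squares through the origin", {
  for (i in 1:20) {
    h <- random_harmonized(sample(2:50, 1), seed = 100 + i)
    res <- mr_ivw(wald_ratios(h), model = "fixed")
    oracle <- wls_origin_oracle(h)
    expect_equal(res$estimate, oracle$coef, tolerance = 1e-10)
    expect_equal(res$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("weighted median matches hand values, limits, and the root-finding oracle", {
  r3 <- wald_ratios(as_harmonized(data.frame(
    beta_x = 1, se_x = 0.01, beta_y = c(0.1, 0.2, 0.9), se_y = 0.05
  )))
  expect_equal(mr_weighted_median(r3, n_boot = 0)$estimate, 0.2)

  # nearly all weight on one variant pins the estimate to its ratio
  rw <- wald_ratios(as_harmonized(data.frame(
    beta_x = 1, se_x = 0.01, beta_y = c(0.1, 0.5, 0.9),
    se_y = c(1e-4, 1, 1)
  )))
  expect_equal(mr_weighted_median(rw, n_boot = 0)$estimate, 0.1,
               tolerance = 1e-3)

  for (i in 1:20) {
    h <- random_harmonized(sample(3:40, 1), seed = 200 + i)
    r <- wald_ratios(h)
    expect_equal(mr_weighted_median(r, n_boot = 0)$estimate,
                 weighted_median_oracle(r$theta, r$weight), tolerance = 1e-8)
  }

  expect_error(mr_weighted_median(wald_ratios(as_harmonized(
    data.frame(beta_x = c(1, 1), se_x = 0.01, beta_y = c(0.1, 0.2), se_y = 0.05)
  ))), class = "mrsuite_insufficient_error")
})

test_that("weighted mode finds the dominant mode and agrees with a refined grid", {
  r <- wald_ratios(as_harmonized(data.frame(
    beta_x = 1, se_x = 0.01, beta_y = c(0.3, 0.3, 0.3, 5.0), se_y = 0.05
  )))
  expect_equal(mr_weighted_mode(r, n_boot = 0)$estimate, 0.3, tolerance = 0.05)

  # tight cluster among symmetric outliers stays within the cluster
  r2 <- wald_ratios(as_harmonized(data.frame(
    beta_x = 1, se_x = 0.01,
    beta_y = c(0.19, 0.2, 0.21, -3, 3.4), se_y = 0.05
  )))
  expect_equal(mr_weighted_mode(r2, n_boot = 0)$estimate, 0.2, tolerance = 0.05)

  # identical ratios: zero bandwidth degenerates to the common value
  r0 <- wald_ratios(as_harmonized(data.frame(
    beta_x = 1, se_x = 0.01, beta_y = c(0.2, 0.2, 0.2), se_y = 0.05
  )))
  expect_equal(mr_weighted_mode(r0, n_boot = 0)$estimate, 0.2)

  # independent KDE argmax on a 10x finer grid, within one coarse step
  for (i in 1:10) {
    h <- random_harmonized(sample(5:30, 1), seed = 300 + i)
    r <- wald_ratios(h)
    est <- mr_weighted_mode(r, n_boot = 0, n_grid = 1000)$estimate
    hbw <- mrsuite:::mode_bandwidth(r$theta, 1)
    fine <- seq(min(r$theta) - 3 * hbw, max(r$theta) + 3 * hbw,
                length.out = 10000)
    dens <- vapply(fine, function(g) sum(r$weight * dnorm((g - r$theta) / hbw)),
                   numeric(1))
    coarse_step <- (max(r$theta) - min(r$theta) + 6 * hbw) / 999
    expect_lt(abs(est - fine[which.max(dens)]), coarse_step + 1e-12)
  }
})

test_that("MR-Egger recovers slope and intercept exactly in the noiseless limit", {
  set.seed(4)
  bx <- runif(10, 0.05, 0.2)
  h <- as_harmonized(data.frame(
    beta_x = bx, se_x = 0.01, beta_y = 0.05 + 0.2 * bx, se_y = 0.02
  ))
  res <- mr_egger(h)
  expect_equal(res$estimate, 0.2, tolerance = 1e-8)
  expect_equal(res$extra$intercept, 0.05, tolerance = 1e-8)
})

test_that("MR-Egger coefficients match the weighted normal equations", {
  for (i in 1:20) {
    h <- random_harmonized(sample(3:40, 1), seed = 400 + i)
    res <- mr_egger(h)
    flip <- sign(h$beta_x)
    oracle <- wls_intercept_oracle(h$beta_x * flip, h$beta_y * flip, 1 / h$se_y^2)
    expect_equal(res$extra$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(res$estimate, oracle[2], tolerance = 1e-10)
  }
})

test_that("MR-Egger intercept test is calibrated under no pleiotropy", {
  pvals <- vapply(1:200, function(i) {
    h <- random_harmonized(20, seed = 5000 + i, theta = 0.1)
    mr_egger(h)$extra$intercept_pval
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("contamination mixture recovers a common effect with a single interval", {
  h <- as_harmonized(data.frame(
    beta_x = rep(0.2, 10), se_x = 0.001,
    beta_y = 0.4 * 0.2 + rnorm(10, 0, 1e-4), se_y = 0.002
  ))
  r <- wald_ratios(h)
  res <- mr_conmix(r)
  expect_equal(res$estimate, 0.4, tolerance = 0.01)
  expect_equal(nrow(res$extra$intervals), 1)
  expect_true(res$ci_low < 0.4 && res$ci_high > 0.4)
  expect_true(all(res$extra$valid))
})

test_that("contamination mixture is stable under grid refinement", {
  for (i in 1:5) {
    h <- random_harmonized(15, seed = 600 + i, theta = 0.25)
    r <- wald_ratios(h)
    coarse <- mr_conmix(r, n_grid = 1000)
    fine <- mr_conmix(r, n_grid = 10000)
    expect_lt(abs(coarse$estimate - fine$estimate),
              coarse$extra$grid_step + 1e-12)
  }
})

test_that("MR-PRESSO is quiet on proportional data and reproducible under a seed", {
  set.seed(7)
  bx <- runif(10, 0.05, 0.2)
  h <- as_harmonized(data.frame(
    beta_x = bx, se_x = 0.005, beta_y = 0.2 * bx + rnorm(10, 0, 1e-4),
    se_y = 0.02
  ))
  res <- mr_presso(h, n_sim = 500, seed = 11)
  expect_gt(res$global_pval, 0.5)
  expect_equal(sum(res$outliers$pval_adj < 0.05), 0)
  res2 <- mr_presso(h, n_sim = 500, seed = 11)
  expect_identical(res$global_pval, res2$global_pval)
  expect_identical(res$outliers, res2$outliers)
})

test_that("doubling the PRESSO simulation count stays within Monte-Carlo error", {
  h <- random_harmonized(15, seed = 71, theta = 0.2)
  h$beta_y[3] <- h$beta_y[3] + 4 * h$se_y[3]  # moderate signal, p not extreme
  p1 <- mr_presso(h, n_sim = 1000, seed = 1)$global_pval
  p2 <- mr_presso(h, n_sim = 2000, seed = 2)$global_pval
  band <- 1.96 * sqrt(p1 * (1 - p1) / 1000 + p2 * (1 - p2) / 2000)
  expect_lt(abs(p1 - p2), band + 1e-3)
})

test_that("bootstrap SEs are reproducible and sensitivity methods enforce the SNP gate", {
  r <- wald_ratios(random_harmonized(12, seed = 81, theta = 0.15))
  m1 <- mr_weighted_median(r, n_boot = 200, seed = 5)
  m2 <- mr_weighted_median(r, n_boot = 200, seed = 5)
  expect_identical(m1$se, m2$se)
  expect_error(mr_egger(as_harmonized(data.frame(
    beta_x = c(0.1, 0.2), se_x = 0.01, beta_y = c(0.01, 0.02), se_y = 0.02
  ))), class = "mrsuite_insufficient_error")
  expect_error(mr_presso(as_harmonized(data.frame(
    beta_x = c(0.1, 0.2, 0.3), se_x = 0.01,
    beta_y = c(0.01, 0.02, 0.03), se_y = 0.02
  ))), class = "mrsuite_insufficient_error")
})
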