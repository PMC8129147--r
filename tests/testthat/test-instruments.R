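make_exposure <- function(pvals, snps = paste0("rs", seq_along(pvals))) {
  sumstats(data.frame(
    snp = snps, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, pval = pvals, n = 1e5
  ), trait_name = "exposure")
}

ld_mat <- function(snps, r2 = 0) {
  m <- matrix(r2, length(snps), length(snps), dimnames = list(snps, snps))
  diag(m) <- 1
  m
}

# Independent re-enactment of the greedy clumping rule, written as a direct
# trace over the sorted candidate list rather than the package's set logic.
greedy_oracle <- function(snp, pval, ld, r2_threshold) {
  ord <- order(pval, snp)
  snp <- snp[ord]
  kept <- character(0)
  excluded <- rep(FALSE, length(snp))
  for (i in seq_along(snp)) {
    if (excluded[i]) next
    kept <- c(kept, snp[i])
    if (snp[i] %in% rownames(ld)) {
      for (j in seq_along(snp)) {
        if (j > i && !excluded[j] && snp[j] %in% colnames(ld) &&
            ld[snp[i], snp[j]] >= r2_threshold) {
          excluded[j] <- TRUE
        }
      }
    }
  }
  kept
}

test_that("independent significant variants are all retained", {
  exp <- make_exposure(c(1e-9, 1e-10, 1e-12))
  sel <- select_instruments(exp, 5e-8, ld_mat(exp$snp, 0), 0.01)
  expect_setequal(sel$snp, exp$snp)
})

test_that("of two correlated variants only the lowest-P survives", {
  exp <- make_exposure(c(1e-9, 1e-10), snps = c("rs_a", "rs_b"))
  sel <- select_instruments(exp, 5e-8, ld_mat(exp$snp, 0.5), 0.01)
  expect_equal(sel$snp, "rs_b")
})

test_that("greedy pruning matches the exhaustive trace oracle on block LD", {
  set.seed(42)
  for (rep in 1:5) {
    snps <- sprintf("rs%03d", sample(1:999, 50))
    pv <- 10^runif(50, -20, -8)
    m <- diag(1, 50)
    # random LD blocks
    starts <- sort(sample(1:46, 5))
    for (s in starts) {
      idx <- s:(s + 4)
      m[idx, idx] <- runif(1, 0, 0.9)
    }
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(snps, snps)
    exp <- make_exposure(pv, snps = snps)
    sel <- select_instruments(exp, 5e-8, m, 0.01)
    expect_equal(sel$snp, greedy_oracle(snps, pv, m, 0.01))
  }
})

test_that("selection is invariant to input row order and warns when empty", {
  exp <- make_exposure(10^runif(20, -12, -8.5))
  shuffled <- new_ss <- exp[sample(nrow(exp)), ]
  attr(shuffled, "trait_name") <- "exposure"
  m <- ld_mat(exp$snp, 0)
  m[1:3, 1:3] <- 0.8; diag(m) <- 1
  s1 <- select_instruments(exp, 5e-8, m, 0.01)
  s2 <- select_instruments(sumstats(as.data.frame(shuffled)), 5e-8, m, 0.01)
  expect_equal(s1$snp, s2$snp)

  expect_warning(sel0 <- select_instruments(make_exposure(c(0.5, 0.2))), "passes")
  expect_equal(nrow(sel0), 0)
})

test_that("harmonization resolves identical, transposed, flipped, and transposed-flipped alleles", {
  instruments <- sumstats(data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "G"),
    eaf = 0.3, beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.01,
    pval = 1e-9, n = 1e5
  ))
  outcome <- sumstats(data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("A", "G", "T", "C", "A"),
    other_allele = c("G", "A", "C", "T", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.3),
    beta = c(0.2, -0.2, 0.2, -0.2, 0.2), se = 0.02,
    pval = 0.01, n = 5e4
  ))
  h <- harmonize(instruments, outcome)
  a <- harmonization_audit(h)
  expect_equal(a$action[a$snp %in% c("s1", "s2", "s3", "s4")],
               c("kept", "beta_flipped", "strand_flipped",
                 "strand_flipped_beta_flipped"))
  expect_equal(h$beta_y[h$snp %in% c("s1", "s2", "s3", "s4")],
               rep(0.2, 4))  # all orientations recover the same +0.2 effect
  # s5 has an irreconcilable allele pair
  expect_equal(a$reason[a$snp == "s5"], "irreconcilable alleles")
})

test_that("palindromic variants are oriented by frequency or dropped in the window", {
  instruments <- sumstats(data.frame(
    snp = c("p1", "p2", "p3"),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.51, 0.2, 0.2), beta = 0.1, se = 0.01, pval = 1e-9, n = 1e5
  ))
  outcome <- sumstats(data.frame(
    snp = c("p1", "p2", "p3"),
    effect_allele = c("A", "A", "T"), other_allele = c("T", "T", "A"),
    eaf = c(0.51, 0.2, 0.8), beta = c(0.3, 0.3, -0.3), se = 0.02,
    pval = 0.01, n = 5e4
  ))
  h <- harmonize(instruments, outcome)
  a <- harmonization_audit(h)
  expect_equal(a$reason[a$snp == "p1"], "ambiguous palindrome")
  expect_equal(h$beta_y[h$snp == "p2"], 0.3)    # frequencies agree: keep
  expect_equal(h$beta_y[h$snp == "p3"], 0.3)    # mirrored EAF: flip back
})

test_that("variants missing from the outcome are dropped with a reason", {
  instruments <- make_exposure(c(1e-9, 1e-9), snps = c("in_both", "only_exp"))
  outcome <- make_exposure(0.5, snps = "in_both")
  h <- harmonize(instruments, outcome)
  a <- harmonization_audit(h)
  expect_equal(nrow(h), 1)
  expect_equal(a$reason[a$snp == "only_exp"], "missing in outcome")
})

test_that("harmonizing a dataset against itself is the identity with zero flips", {
  sim <- simulate_pair(sim_config(n_variants = 40, seed = 21))
  h <- harmonize(sim$exposure, sim$exposure)
  expect_equal(h$beta_y, h$beta_x)
  expect_true(all(harmonization_audit(h)$action == "kept"))
})

test_that("harmonization is idempotent", {
  sim <- simulate_pair(sim_config(
    n_variants = 60, theta_true = 0.2, seed = 22,
    allele_pathologies = c(swapped = 0.4, flipped = 0.3, palindromic = 0.2)
  ))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild the outcome in the orientation h1 established, then re-harmonize
  exp_df <- as.data.frame(sim$exposure)
  aligned <- exp_df[match(h1$snp, exp_df$snp), ]
  aligned$beta <- h1$beta_y
  aligned$se <- h1$se_y
  aligned$pval <- 0.5
  outcome2 <- sumstats(aligned, trait_name = "aligned_outcome")
  h2 <- harmonize(sim$exposure, outcome2)
  kept2 <- harmonization_audit(h2)
  expect_true(all(kept2$action[kept2$snp %in% h1$snp] %in% c("kept", "dropped")))
  common <- intersect(h1$snp, h2$snp)
  expect_equal(h2$beta_y[match(common, h2$snp)],
               h1$beta_y[match(common, h1$snp)])
})

test_that("audit action counts match the generator's pathology ground truth", {
  sim <- simulate_pair(sim_config(
    n_variants = 300, theta_true = 0.1, seed = 23,
    allele_pathologies = c(swapped = 0.25, flipped = 0.25, palindromic = 0.2),
    maf_dist = c(0.05, 0.35)  # keeps every EAF clear of the palindrome window
  ))
  h <- harmonize(sim$exposure, sim$outcome)
  a <- harmonization_audit(h)
  tr <- sim$truth
  expect_equal(sum(a$action == "beta_flipped"),
               sum(tr$swapped & !tr$flipped & !tr$palindromic))
  expect_equal(sum(a$action == "strand_flipped"),
               sum(!tr$swapped & tr$flipped & !tr$palindromic))
  expect_equal(sum(a$action == "strand_flipped_beta_flipped"),
               sum(tr$swapped & tr$flipped & !tr$palindromic))
  # palindromes: a swap leaves mirrored frequencies regardless of strand flips
  expect_equal(sum(a$action == "palindrome_flipped"),
               sum(tr$palindromic & tr$swapped))
  expect_equal(sum(a$action == "palindrome_oriented"),
               sum(tr$palindromic & !tr$swapped & tr$flipped))
  expect_equal(sum(a$action == "dropped"), 0)
  # harmonized outcome effects all recover the pre-pathology orientation
  clean <- simulate_pair(sim_config(
    n_variants = 300, theta_true = 0.1, seed = 23,
    allele_pathologies = c(swapped = 0, flipped = 0, palindromic = 0.2),
    maf_dist = c(0.05, 0.35)
  ))
  expect_equal(h$beta_y, clean$outcome$beta[match(h$snp, clean$outcome$snp)])
})
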