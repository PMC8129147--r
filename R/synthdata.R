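#' Configure a synthetic two-sample GWAS simulation
#'
#' Builds the generative specification for a pair of exposure/outcome
#' summary-statistics datasets with known ground truth. The generator
#' emulates the two-sample setting: per-variant instrument-exposure effects
#' are drawn once, then observed with independent noise in each sample, and
#' the outcome effect is `theta_true` times the true exposure effect plus an
#' optional pleiotropic shift `alpha_j`.
#'
#' Pleiotropy scenarios:
#' * `"none"`: `alpha_j = 0` for all variants.
#' * `"balanced"`: a fraction of variants get `alpha_j ~ N(0, sd)`.
#' * `"directional"`: a fraction get `alpha_j ~ N(mean, sd)` with `mean != 0`.
#' * `"clustered"`: mechanism specs `list(list(theta = , n = ), ...)` replace
#'   `theta_true` by `theta_k` for the `n_k` variants of mechanism `k`.
#'
#' Allele-coding pathologies (swapped effect/other alleles with negated beta
#' and reflected EAF; strand flips; palindromic A/T or C/G allele pairs) are
#' applied to the outcome dataset only, so harmonization is exercised against
#' a clean exposure reference.
#'
#' @param n_variants Number of variants.
#' @param theta_true Causal effect (outcome units per exposure unit).
#' @param beta_x_dist Length-2 numeric `(mean, sd)` of true
#'   instrument-exposure effects.
#' @param se_x,se_y Per-variant standard-error scales; scalars are recycled.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"clustered"`.
#' @param pleiotropy_params For balanced/directional: a list
#'   `list(mean = , sd = , frac = )` (mean and sd of `alpha_j`, fraction of
#'   invalid variants). For clustered: a list of mechanism specs
#'   `list(list(theta = , n = ), ...)`.
#' @param ld_blocks List of `list(size = , r2 = )` blocks of correlated
#'   variants; block sizes must sum to at most `n_variants`; remaining
#'   variants are independent.
#' @param allele_pathologies Named numeric with fractions `swapped`,
#'   `flipped`, `palindromic`, each in \[0, 1\].
#' @param maf_dist Length-2 numeric, uniform range for the effect-allele
#'   frequency, within (0, 0.5\].
#' @param palindrome_near_half If `TRUE`, palindromic variants get EAF drawn
#'   uniformly in (0.45, 0.55) so the ambiguous-palindrome drop rule fires.
#' @param binary_outcome If `TRUE` the outcome is flagged `binary-logOR`
#'   (metadata only; the generator itself is scale-agnostic).
#' @param n_exposure,n_outcome Nominal GWAS sample sizes (metadata columns).
#' @param seed Integer RNG seed; one seed governs all draws through a single
#'   stream, so identical configs reproduce byte-identical files.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 50, theta_true = 0.3, seed = 1)
#' sim <- simulate_pair(cfg)
#' sim$truth
sim_config <- function(n_variants = 50,
                       theta_true = 0,
                       beta_x_dist = c(0.1, 0.03),
                       se_x = 0.005,
                       se_y = 0.02,
                       pleiotropy_mode = c("none", "balanced", "directional", "clustered"),
                       pleiotropy_params = NULL,
                       ld_blocks = list(),
                       allele_pathologies = c(swapped = 0, flipped = 0, palindromic = 0),
                       maf_dist = c(0.05, 0.5),
                       palindrome_near_half = FALSE,
                       binary_outcome = FALSE,
                       n_exposure = 1e5,
                       n_outcome = 5e4,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg_error <- function(field, msg) {
    abort(paste0("invalid sim_config field `", field, "`: ", msg),
          class = "mrsuite_config_error")
  }
  if (!is.numeric(n_variants) || n_variants < 1) cfg_error("n_variants", "must be >= 1")
  n_variants <- as.integer(n_variants)
  if (length(beta_x_dist) != 2 || beta_x_dist[2] < 0) {
    cfg_error("beta_x_dist", "needs (mean, sd) with sd >= 0")
  }
  se_x <- rep_len(as.numeric(se_x), n_variants)
  se_y <- rep_len(as.numeric(se_y), n_variants)
  if (any(se_x <= 0)) cfg_error("se_x", "all SEs must be > 0")
  if (any(se_y <= 0)) cfg_error("se_y", "all SEs must be > 0")

  if (pleiotropy_mode %in% c("balanced", "directional")) {
    defaults <- list(mean = if (pleiotropy_mode == "directional") 0.05 else 0,
                     sd = 0.02, frac = 0.3)
    pleiotropy_params <- modifyList(defaults, pleiotropy_params %||% list())
    if (pleiotropy_params$frac < 0 || pleiotropy_params$frac > 1) {
      cfg_error("pleiotropy_params$frac", "fraction must lie in [0, 1]")
    }
    if (pleiotropy_params$sd < 0) cfg_error("pleiotropy_params$sd", "must be >= 0")
  }
  if (pleiotropy_mode == "clustered") {
    if (is.null(pleiotropy_params) || length(pleiotropy_params) == 0) {
      cfg_error("pleiotropy_params", "clustered mode needs mechanism specs list(theta=, n=)")
    }
    n_mech <- sum(vapply(pleiotropy_params, function(m) as.integer(m$n), integer(1)))
    if (n_mech > n_variants) {
      cfg_error("pleiotropy_params", "mechanism sizes exceed n_variants")
    }
  }

  if (length(ld_blocks) > 0) {
    sizes <- vapply(ld_blocks, function(b) as.integer(b$size), integer(1))
    r2s <- vapply(ld_blocks, function(b) as.numeric(b$r2), numeric(1))
    if (sum(sizes) > n_variants) cfg_error("ld_blocks", "block sizes sum beyond n_variants")
    if (any(r2s < 0 | r2s > 1)) cfg_error("ld_blocks", "r2 must lie in [0, 1]")
  }

  ap <- c(swapped = 0, flipped = 0, palindromic = 0)
  ap[names(allele_pathologies)] <- allele_pathologies
  if (any(ap < 0 | ap > 1)) {
    cfg_error("allele_pathologies", "fractions must lie in [0, 1]")
  }
  if (length(maf_dist) != 2 || maf_dist[1] <= 0 || maf_dist[2] > 0.5 ||
      maf_dist[1] > maf_dist[2]) {
    cfg_error("maf_dist", "must be an increasing range within (0, 0.5]")
  }

  structure(list(
    n_variants = n_variants, theta_true = theta_true, beta_x_dist = beta_x_dist,
    se_x = se_x, se_y = se_y, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_params = pleiotropy_params, ld_blocks = ld_blocks,
    allele_pathologies = ap, maf_dist = maf_dist,
    palindrome_near_half = isTRUE(palindrome_near_half),
    binary_outcome = isTRUE(binary_outcome),
    n_exposure = n_exposure, n_outcome = n_outcome,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Equicorrelated within-block noise: z = sqrt(r) * shared + sqrt(1 - r) * own,
# giving pairwise correlation r = sqrt(r2) between effect-noise draws.
block_noise <- function(cfg) {
  J <- cfg$n_variants
  block_id <- rep(0L, J)
  r_of_block <- numeric(0)
  i <- 1L
  for (k in seq_along(cfg$ld_blocks)) {
    b <- cfg$ld_blocks[[k]]
    block_id[i:(i + b$size - 1L)] <- k
    r_of_block[k] <- sqrt(b$r2)
    i <- i + as.integer(b$size)
  }
  draw <- function() {
    z <- rnorm(J)
    if (length(cfg$ld_blocks) > 0) {
      for (k in seq_along(cfg$ld_blocks)) {
        idx <- which(block_id == k)
        shared <- rnorm(1)
        r <- r_of_block[k]
        z[idx] <- sqrt(r) * shared + sqrt(1 - r) * z[idx]
      }
    }
    z
  }
  list(draw = draw, block_id = block_id)
}

ld_from_blocks <- function(cfg, snps) {
  J <- cfg$n_variants
  m <- diag(1, J)
  i <- 1L
  for (b in cfg$ld_blocks) {
    idx <- i:(i + b$size - 1L)
    m[idx, idx] <- b$r2
    i <- i + as.integer(b$size)
  }
  diag(m) <- 1
  dimnames(m) <- list(snps, snps)
  m
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Draws true instrument-exposure effects, observes them with noise in the
#' exposure sample, generates outcome effects under the configured causal
#' effect and pleiotropy scenario, applies allele-coding pathologies to the
#' outcome dataset, and returns both datasets together with the block LD
#' matrix and a per-variant ground-truth table.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `exposure`, `outcome`: [sumstats] tibbles,
#'   * `ld`: the block LD matrix (r-squared),
#'   * `truth`: tibble with `snp`, `beta_x_true`, `alpha`, `class`
#'     (`valid` / `pleiotropic` / `mechanism`), `mechanism`, and the
#'     pathology flags `swapped`, `flipped`, `palindromic`.
#' @export
simulate_pair <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be built by sim_config()", class = "mrsuite_config_error")
  }
  cfg <- config
  set.seed(cfg$seed)
  J <- cfg$n_variants
  snps <- sprintf("rs%06d", seq_len(J))

  beta_x_true <- rnorm(J, cfg$beta_x_dist[1], cfg$beta_x_dist[2])

  # pleiotropy assignment
  alpha <- numeric(J)
  class <- rep("valid", J)
  mechanism <- rep(NA_integer_, J)
  theta_j <- rep(cfg$theta_true, J)
  if (cfg$pleiotropy_mode %in% c("balanced", "directional")) {
    pp <- cfg$pleiotropy_params
    n_invalid <- round(pp$frac * J)
    idx <- sample(J, n_invalid)
    alpha[idx] <- rnorm(n_invalid, pp$mean, pp$sd)
    class[idx] <- "pleiotropic"
  } else if (cfg$pleiotropy_mode == "clustered") {
    pool <- sample(J)
    at <- 1L
    for (k in seq_along(cfg$pleiotropy_params)) {
      m <- cfg$pleiotropy_params[[k]]
      idx <- pool[at:(at + m$n - 1L)]
      theta_j[idx] <- m$theta
      class[idx] <- "mechanism"
      mechanism[idx] <- k
      at <- at + as.integer(m$n)
    }
  }

  noise <- block_noise(cfg)
  beta_x_obs <- beta_x_true + cfg$se_x * noise$draw()
  beta_y_obs <- theta_j * beta_x_true + alpha + cfg$se_y * noise$draw()

  # alleles and frequencies
  ap <- cfg$allele_pathologies
  palindromic <- runif(J) < ap["palindromic"]
  alleles <- matrix("", J, 2)
  n_pal <- sum(palindromic)
  if (n_pal > 0) {
    alleles[palindromic, ] <- PALINDROMIC_PAIRS[
      sample(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE), , drop = FALSE]
  }
  if (J - n_pal > 0) {
    alleles[!palindromic, ] <- NON_PALINDROMIC_PAIRS[
      sample(nrow(NON_PALINDROMIC_PAIRS), J - n_pal, replace = TRUE), , drop = FALSE]
  }
  eaf <- runif(J, cfg$maf_dist[1], cfg$maf_dist[2])
  if (cfg$palindrome_near_half && n_pal > 0) {
    eaf[palindromic] <- runif(n_pal, 0.45, 0.55)
  }

  exposure <- sumstats(
    tibble(
      snp = snps, chrom = "1", pos = seq_len(J) * 1000L,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta_x_obs, se = cfg$se_x,
      pval = pmax(2 * pnorm(-abs(beta_x_obs / cfg$se_x)), .Machine$double.xmin),
      n = cfg$n_exposure
    ),
    trait_name = "simulated_exposure", trait_type = "continuous"
  )

  # outcome starts aligned with the exposure, then pathologies are applied
  out_ea <- alleles[, 1]
  out_oa <- alleles[, 2]
  out_beta <- beta_y_obs
  out_eaf <- eaf
  swapped <- runif(J) < ap["swapped"]
  flipped <- runif(J) < ap["flipped"]
  if (any(swapped)) {
    tmp <- out_ea[swapped]
    out_ea[swapped] <- out_oa[swapped]
    out_oa[swapped] <- tmp
    out_beta[swapped] <- -out_beta[swapped]
    out_eaf[swapped] <- 1 - out_eaf[swapped]
  }
  if (any(flipped)) {
    out_ea[flipped] <- COMPLEMENT[out_ea[flipped]]
    out_oa[flipped] <- COMPLEMENT[out_oa[flipped]]
  }

  outcome <- sumstats(
    tibble(
      snp = snps, chrom = "1", pos = seq_len(J) * 1000L,
      effect_allele = out_ea, other_allele = out_oa,
      eaf = out_eaf, beta = out_beta, se = cfg$se_y,
      pval = pmax(2 * pnorm(-abs(out_beta / cfg$se_y)), .Machine$double.xmin),
      n = cfg$n_outcome
    ),
    trait_name = "simulated_outcome",
    trait_type = if (cfg$binary_outcome) "binary-logOR" else "continuous"
  )

  truth <- tibble(
    snp = snps, beta_x_true = beta_x_true, theta = theta_j, alpha = alpha,
    class = class, mechanism = mechanism,
    swapped = swapped, flipped = flipped, palindromic = palindromic
  )

  list(exposure = exposure, outcome = outcome,
       ld = ld_from_blocks(cfg, snps), truth = truth)
}

#' Write all artifacts of a simulated pair to a directory
#'
#' Emits `exposure.tsv`, `outcome.tsv` (canonical sumstats dialect with JSON
#' metadata sidecars), `ld.tsv`, and `truth.tsv`.
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld(sim$ld, file.path(dir, "ld.tsv"))
  truth <- sim$truth
  for (col in c("beta_x_true", "theta", "alpha")) {
    truth[[col]] <- format_full(truth[[col]])
  }
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
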