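#' Select genetic instruments by significance and greedy LD pruning
#'
#' Keeps variants with `pval < p_threshold`, then prunes for linkage
#' disequilibrium: repeatedly take the remaining variant with the lowest
#' p-value (ties broken by lexicographic snp ID) and discard all remaining
#' variants with r-squared at or above `r2_threshold` against it, until no
#' candidates remain. Variants absent from the LD matrix are treated as
#' independent and noted in the selection report.
#'
#' @param exposure A [sumstats] object.
#' @param p_threshold Genome-wide significance threshold; default `5e-8`.
#' @param ld Square r-squared matrix with snp dimnames, or `NULL` (all
#'   variants treated as independent).
#' @param r2_threshold Pruning threshold; default `0.01`.
#' @return A [sumstats] object containing the retained instruments, in
#'   selection order, with attribute `selection_report` (candidate count,
#'   pruned snps, snps missing from the LD matrix). If no variant passes the
#'   threshold an empty set is returned with a warning, not an error:
#'   zero- and single-instrument exposures are legitimate.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8,
                               ld = NULL, r2_threshold = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1, r2_threshold > 0, r2_threshold < 1)
  cand <- filter(exposure, .data$pval < p_threshold)
  if (nrow(cand) == 0) {
    warn(paste0("no variant in ", attr(exposure, "trait_name") %||% "exposure",
                " passes p < ", format(p_threshold)))
  }
  cand <- arrange(cand, .data$pval, .data$snp)
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(cand)) else cand$snp %in% rownames(ld)
  missing_from_ld <- cand$snp[!in_ld]

  kept <- character(0)
  remaining <- cand$snp
  while (length(remaining) > 0) {
    lead <- remaining[1]  # lowest p among remaining (pre-sorted)
    kept <- c(kept, lead)
    remaining <- remaining[-1]
    if (!is.null(ld) && lead %in% rownames(ld) && length(remaining) > 0) {
      covered <- intersect(remaining, colnames(ld))
      drop <- covered[ld[lead, covered] >= r2_threshold]
      remaining <- setdiff(remaining, drop)
    }
  }

  out <- cand[match(kept, cand$snp), ]
  new_sumstats(out,
    trait_name = attr(exposure, "trait_name"),
    trait_type = attr(exposure, "trait_type"),
    load_report = attr(exposure, "load_report")
  ) -> res
  attr(res, "selection_report") <- list(
    n_candidates = nrow(cand), n_selected = length(kept),
    pruned = setdiff(cand$snp, kept), missing_from_ld = missing_from_ld,
    p_threshold = p_threshold, r2_threshold = r2_threshold
  )
  res
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize effect alleles between exposure instruments and an outcome GWAS
#'
#' Aligns the outcome dataset's effect alleles to the exposure's coding.
#' Per shared variant, in order: identical alleles are kept as-is;
#' transposed alleles flip the sign of the outcome beta and reflect its EAF;
#' alleles matching after strand complement (A<->T, C<->G) are complemented
#' first and then treated the same way; palindromic variants (A/T or C/G
#' pairs) cannot be resolved by allele labels, so they are oriented by
#' allele frequency when both EAFs are available and both fall outside the
#' ambiguity window around 0.5, and dropped otherwise; irreconcilable allele
#' pairs are dropped. Variants missing from the outcome are dropped with
#' reason `"missing in outcome"`.
#'
#' @param instruments A [sumstats] of selected instruments (exposure coding
#'   is the reference orientation).
#' @param outcome A [sumstats] for the outcome trait.
#' @param palindrome_eaf_window Half-width `w` of the ambiguity window: a
#'   palindromic variant with either EAF inside `[0.5 - w, 0.5 + w]` is
#'   dropped as ambiguous. Default `0.08`.
#' @return An `mr_harmonized` tibble with columns `snp`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf`, `action`; attributes `exposure_name`,
#'   `outcome_name`, `outcome_type`, and `audit` (one row per candidate
#'   variant: `snp`, `action`, `reason`). Actions are `kept`,
#'   `beta_flipped`, `strand_flipped`, `strand_flipped_beta_flipped`,
#'   `palindrome_oriented`, `palindrome_flipped`, or `dropped`.
#' @export
harmonize <- function(instruments, outcome, palindrome_eaf_window = 0.08) {
  w <- palindrome_eaf_window
  stopifnot(w >= 0, w < 0.5)
  x <- as_tibble(instruments)
  y <- as_tibble(outcome)

  m <- left_join(x, y, by = "snp", suffix = c("_x", "_y"))
  action <- character(nrow(m))
  beta_y <- m$beta_y
  eaf_y <- m$eaf_y
  reason <- rep(NA_character_, nrow(m))

  for (i in seq_len(nrow(m))) {
    if (is.na(m$beta_y[i]) && !m$snp[i] %in% y$snp) {
      action[i] <- "dropped"; reason[i] <- "missing in outcome"; next
    }
    ea_x <- m$effect_allele_x[i]; oa_x <- m$other_allele_x[i]
    ea_y <- m$effect_allele_y[i]; oa_y <- m$other_allele_y[i]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # allele labels cannot distinguish strand from swap; orient by EAF
      same_pair <- (ea_y %in% c(ea_x, oa_x)) && (oa_y %in% c(ea_x, oa_x)) && ea_y != oa_y
      if (!same_pair) {
        action[i] <- "dropped"; reason[i] <- "irreconcilable alleles"; next
      }
      ex <- m$eaf_x[i]; ey <- m$eaf_y[i]
      if (is.na(ex) || is.na(ey) ||
          abs(ex - 0.5) <= w || abs(ey - 0.5) <= w) {
        action[i] <- "dropped"; reason[i] <- "ambiguous palindrome"; next
      }
      # frequencies agree -> same orientation; otherwise the outcome codes
      # the opposite allele as effect allele
      if (abs(ex - ey) <= abs(ex - (1 - ey))) {
        action[i] <- if (ea_y == ea_x) "kept" else "palindrome_oriented"
      } else {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "palindrome_flipped"
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "beta_flipped"
    } else {
      cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
      if (identical(cea, ea_x) && identical(coa, oa_x)) {
        action[i] <- "strand_flipped"
      } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "strand_flipped_beta_flipped"
      } else {
        action[i] <- "dropped"; reason[i] <- "irreconcilable alleles"
      }
    }
  }

  audit <- tibble(snp = m$snp, action = action, reason = reason)
  keep <- action != "dropped"
  h <- tibble(
    snp = m$snp[keep],
    beta_x = m$beta_x[keep], se_x = m$se_x[keep],
    beta_y = beta_y[keep], se_y = m$se_y[keep],
    eaf = m$eaf_x[keep],
    action = action[keep]
  )
  if (nrow(h) == 0) {
    warn("harmonization produced an empty set")
  }
  new_harmonized(h,
    exposure_name = attr(instruments, "trait_name") %||% "exposure",
    outcome_name = attr(outcome, "trait_name") %||% "outcome",
    outcome_type = attr(outcome, "trait_type") %||% "continuous",
    audit = audit
  )
}

new_harmonized <- function(x, exposure_name, outcome_name, outcome_type, audit) {
  structure(
    as_tibble(x),
    exposure_name = exposure_name,
    outcome_name = outcome_name,
    outcome_type = outcome_type,
    audit = audit,
    class = c("mr_harmonized", class(as_tibble(x)))
  )
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s, %d variants\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"), nrow(x)))
  NextMethod()
}

#' Harmonization audit log
#'
#' @param h An `mr_harmonized` object.
#' @return Tibble with one row per candidate variant (`snp`, `action`,
#'   `reason`); drop reasons are `missing in outcome`,
#'   `ambiguous palindrome`, or `irreconcilable alleles`.
#' @export
harmonization_audit <- function(h) attr(h, "audit")

#' Assemble a harmonized set directly from aligned effect columns
#'
#' Convenience constructor for already-aligned data (simulations, unit
#' tests, or pre-harmonized uploads); no allele reconciliation is performed.
#'
#' @param df Data frame with `beta_x`, `se_x`, `beta_y`, `se_y` and
#'   optionally `snp`, `eaf`.
#' @param exposure_name,outcome_name,outcome_type Metadata labels.
#' @return An `mr_harmonized` tibble.
#' @export
as_harmonized <- function(df, exposure_name = "exposure",
                          outcome_name = "outcome",
                          outcome_type = "continuous") {
  df <- as_tibble(df)
  stopifnot(all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(df)))
  if (!"snp" %in% names(df)) df$snp <- sprintf("rs%06d", seq_len(nrow(df)))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"action" %in% names(df)) df$action <- "kept"
  stopifnot(all(df$se_x > 0), all(df$se_y > 0))
  h <- df[, c("snp", "beta_x", "se_x", "beta_y", "se_y", "eaf", "action")]
  new_harmonized(h, exposure_name, outcome_name, outcome_type,
                 audit = tibble(snp = h$snp, action = h$action,
                                reason = NA_character_))
}
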