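#' Build and validate a study configuration
#'
#' Assembles the configuration for a full multi-exposure, multi-outcome MR
#' study. Each exposure entry is a list with either `path` (canonical
#' sumstats TSV) or `data` (an in-memory [sumstats] object), plus optional
#' `name`, `tier` (`"primary"` or `"secondary"`), `preselected` (skip
#' instrument selection — for exposures whose instruments were taken from
#' prior publications), `cluster` (run mechanism clustering), and
#' `column_map`. Outcome entries carry `path`/`data`, `name`, and
#' `trait_type`.
#'
#' @param exposures List of exposure entries.
#' @param outcomes List of outcome entries.
#' @param ld Optional LD matrix (r-squared) or path to one.
#' @param p_threshold,r2_threshold Instrument-selection thresholds
#'   (defaults 5e-8 and 0.01).
#' @param palindrome_eaf_window Harmonization ambiguity window (default 0.08).
#' @param n_boot Bootstrap replicates for median/mode SEs (default 1000).
#' @param n_sim MR-PRESSO simulation count (default 1000).
#' @param k_max,n_restarts Clustering controls.
#' @param fdr_family `"tier_outcome"` (default: one BH family per exposure
#'   tier and outcome) or `"tier"` (pool outcomes within a tier).
#' @param alpha,q_threshold Classification thresholds (default 0.05 each).
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @param out_dir Optional output directory for TSVs and the run manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(exposures, outcomes, ld = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.01,
                       palindrome_eaf_window = 0.08,
                       n_boot = 1000, n_sim = 1000,
                       k_max = 5, n_restarts = 20,
                       fdr_family = c("tier_outcome", "tier"),
                       alpha = 0.05, q_threshold = 0.05,
                       seed = 1, out_dir = NULL) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(p_threshold > 0, p_threshold < 1, r2_threshold > 0, r2_threshold < 1,
            alpha > 0, alpha < 1, q_threshold > 0, q_threshold < 1,
            n_boot >= 0, n_sim >= 1, k_max >= 0)
  norm_entry <- function(e, default_name, is_outcome = FALSE) {
    if (inherits(e, "sumstats")) e <- list(data = e)
    e$name <- e$name %||% (if (!is.null(e$data)) attr(e$data, "trait_name") else NULL) %||%
      (if (!is.null(e$path)) basename(e$path) else default_name)
    if (!is_outcome) {
      e$tier <- e$tier %||% "primary"
      stopifnot(e$tier %in% c("primary", "secondary"))
      e$preselected <- isTRUE(e$preselected)
      e$cluster <- isTRUE(e$cluster)
    } else {
      e$trait_type <- e$trait_type %||%
        (if (!is.null(e$data)) attr(e$data, "trait_type") else "continuous")
    }
    if (is.null(e$data)) {
      if (is.null(e$path)) {
        abort(paste0("entry `", e$name, "` has neither path nor data"),
              class = "mrsuite_config_error")
      }
      if (!file.exists(e$path)) {
        abort(paste0("file not found for `", e$name, "`: ", e$path),
              class = "mrsuite_config_error")
      }
    }
    e
  }
  exposures <- imap(exposures, function(e, i) norm_entry(e, paste0("exposure_", i)))
  outcomes <- imap(outcomes, function(e, i) norm_entry(e, paste0("outcome_", i), TRUE))
  if (is.character(ld)) {
    if (!file.exists(ld)) {
      abort(paste0("LD matrix file not found: ", ld), class = "mrsuite_config_error")
    }
  }
  structure(list(
    exposures = exposures, outcomes = outcomes, ld = ld,
    p_threshold = p_threshold, r2_threshold = r2_threshold,
    palindrome_eaf_window = palindrome_eaf_window,
    n_boot = n_boot, n_sim = n_sim, k_max = k_max, n_restarts = n_restarts,
    fdr_family = fdr_family, alpha = alpha, q_threshold = q_threshold,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

# Sensitivity battery trigger: >2 SNPs and (significant or suggestive
# association, or significant heterogeneity) in the primary IVW analysis.
needs_sensitivity <- function(n_snps, pval, q_pval) {
  isTRUE(n_snps > 2) &&
    ((!is.na(pval) && pval < 0.05) || (!is.na(q_pval) && q_pval < 0.05))
}

load_entry <- function(e, trait_type = NULL) {
  if (!is.null(e$data)) return(e$data)
  read_sumstats(e$path, column_map = e$column_map,
                trait_name = e$name, trait_type = trait_type)
}

#' Run the full two-sample MR study
#'
#' For every exposure-outcome pair: select instruments (unless the exposure
#' is flagged `preselected`), harmonize against the outcome, compute the
#' primary IVW estimate with the automatic fixed/random-effects switch,
#' and — for exposures with more than two instruments showing a nominally
#' significant or suggestive association or significant heterogeneity —
#' run the sensitivity battery (weighted median, weighted mode, MR-Egger,
#' contamination mixture, MR-PRESSO). Exposures flagged for cluster
#' exploration get mechanism clustering. BH-FDR q-values and the
#' significant/suggestive/null classification are computed within each
#' configured family. Degenerate pairs (no instruments, a single SNP where
#' a method needs more) yield `NA` rows and never abort the study.
#'
#' @param config A [run_config()].
#' @return An `mr_study` list: `results` (one row per exposure, outcome,
#'   and method, `NA`-filled where a method was not applicable), `families`
#'   (primary-IVW rows with `qval` and `classification`), `presso` (named
#'   list of `presso_result`), `clusters` and `scatter_tables` (named
#'   lists), `manifest`. When `config$out_dir` is set, `results.tsv`,
#'   `families.tsv`, per-pair `cluster_*.tsv`, and `manifest.json` are
#'   written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  ld <- config$ld
  if (is.character(ld)) ld <- read_ld(ld)

  rows <- list()
  presso_list <- list()
  clusters <- list()
  scatter_tables <- list()
  instrument_counts <- list()
  drop_counts <- list()
  stage_seed <- config$seed
  next_seed <- function() {
    stage_seed <<- (stage_seed + 7919L) %% .Machine$integer.max
    stage_seed
  }

  outcome_data <- map(config$outcomes, function(o) load_entry(o, o$trait_type))

  for (e in config$exposures) {
    exp_data <- load_entry(e)
    instruments <- if (e$preselected) {
      exp_data
    } else {
      select_instruments(exp_data, config$p_threshold, ld, config$r2_threshold)
    }
    instrument_counts[[e$name]] <- nrow(instruments)

    for (oi in seq_along(config$outcomes)) {
      o <- config$outcomes[[oi]]
      od <- outcome_data[[oi]]
      pair <- paste0(e$name, "|", o$name)
      pair_rows <- tryCatch({
        h <- suppressWarnings(
          harmonize(instruments, od, config$palindrome_eaf_window)
        )
        drop_counts[[pair]] <- sum(harmonization_audit(h)$action == "dropped")
        if (nrow(h) == 0) {
          abort("no harmonized variants", class = "mrsuite_degenerate_error")
        }
        r <- wald_ratios(h)
        ivw <- mr_ivw(r, model = "auto")
        out <- list(tidy(ivw) |> mutate(tier = e$tier))

        if (needs_sensitivity(ivw$n_snps, ivw$pval, ivw$Q_pval)) {
          battery <- list(
            function() mr_weighted_median(r, n_boot = config$n_boot,
                                          seed = next_seed()),
            function() mr_weighted_mode(r, n_boot = config$n_boot,
                                        seed = next_seed()),
            function() mr_egger(h),
            function() mr_conmix(r),
            function() {
              p <- mr_presso(h, n_sim = config$n_sim, seed = next_seed())
              presso_list[[pair]] <<- p
              na_mr_result("MR-PRESSO", e$name, o$name, o$trait_type,
                           n_snps = nrow(h),
                           note = sprintf("global p = %.4g, %d outlier(s)",
                                          p$global_pval,
                                          sum(p$outliers$pval_adj < 0.05)))
            }
          )
          methods <- c("weighted median", "weighted mode", "MR-Egger",
                       "contamination mixture", "MR-PRESSO")
          for (b in seq_along(battery)) {
            res <- tryCatch(battery[[b]](), mrsuite_insufficient_error = function(c) {
              na_mr_result(methods[b], e$name, o$name, o$trait_type,
                           n_snps = nrow(h))
            })
            out <- c(out, list(tidy(res) |> mutate(tier = e$tier)))
          }
        }

        if (e$cluster && nrow(r) >= 2) {
          cm <- fit_clusters(r, k_max = config$k_max,
                             n_restarts = config$n_restarts, seed = next_seed())
          clusters[[pair]] <- cm
          scatter_tables[[pair]] <- cluster_scatter_table(cm, h)
        }
        out
      }, error = function(c) {
        if (inherits(c, c("mrsuite_degenerate_error", "mrsuite_insufficient_error",
                          "mrsuite_empty_error", "rlang_error"))) {
          list(tidy(na_mr_result("IVW", e$name, o$name, o$trait_type,
                                 note = conditionMessage(c))) |>
                 mutate(tier = e$tier))
        } else {
          stop(c)
        }
      })
      rows <- c(rows, pair_rows)
    }
  }

  results <- bind_rows(rows)
  primary <- filter(results, .data$method == "IVW")
  fam_key <- if (config$fdr_family == "tier_outcome") {
    paste(primary$tier, primary$outcome, sep = " / ")
  } else {
    primary$tier
  }
  families <- primary |>
    mutate(family = fam_key) |>
    group_by(.data$family) |>
    group_modify(~ classify(.x, alpha = config$alpha,
                            q_threshold = config$q_threshold)) |>
    ungroup()

  manifest <- list(
    package = "mrsuite",
    version = as.character(utils::packageVersion("mrsuite")),
    seed = config$seed,
    thresholds = config[c("p_threshold", "r2_threshold",
                          "palindrome_eaf_window", "n_boot", "n_sim",
                          "k_max", "n_restarts", "fdr_family", "alpha",
                          "q_threshold")],
    exposures = map(config$exposures, function(e) {
      list(name = e$name, tier = e$tier, preselected = e$preselected,
           cluster = e$cluster, n_instruments = instrument_counts[[e$name]])
    }),
    outcomes = map(config$outcomes, function(o) {
      list(name = o$name, trait_type = o$trait_type)
    }),
    harmonization_drops = drop_counts,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  )

  study <- structure(list(
    results = results, families = families, presso = presso_list,
    clusters = clusters, scatter_tables = scatter_tables, manifest = manifest
  ), class = "mr_study")

  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' @export
print.mr_study <- function(x, ...) {
  n_pairs <- nrow(filter(x$results, .data$method == "IVW"))
  cat(sprintf("<mr_study> %d exposure-outcome pair(s), %d result row(s)\n",
              n_pairs, nrow(x$results)))
  counts <- count(filter(x$families, !is.na(.data$classification)),
                  .data$classification)
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("  %s: %d\n", counts$classification[i], counts$n[i]))
  }
  invisible(x)
}

write_tsv_stamped <- function(df, path, seed) {
  header <- sprintf("# mrsuite %s seed=%d",
                    as.character(utils::packageVersion("mrsuite")), seed)
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write the results bundle of a study
#'
#' @param study An `mr_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- study$manifest$seed
  write_tsv_stamped(study$results, file.path(dir, "results.tsv"), seed)
  write_tsv_stamped(study$families, file.path(dir, "families.tsv"), seed)
  for (pair in names(study$scatter_tables)) {
    fname <- paste0("cluster_", gsub("[^A-Za-z0-9]+", "_", pair), ".tsv")
    write_tsv_stamped(study$scatter_tables[[pair]], file.path(dir, fname), seed)
  }
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
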