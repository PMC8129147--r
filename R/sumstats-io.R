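#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a tibble of per-variant association records with
#' one row per variant and columns `snp`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. The trait name and type
#' (`"continuous"` or `"binary-logOR"`) travel as attributes so that
#' downstream results know whether `exp(estimate)` is an odds ratio.
#'
#' Validation drops (never repairs) offending rows: empty or non-ACGT
#' single-nucleotide alleles, identical alleles, non-positive standard
#' errors, p-values outside (0, 1], and effect-allele frequencies outside
#' the open interval (0, 1). Duplicate `snp` keys keep the first occurrence.
#' Every rejection is recorded in the load report (see [load_report()]).
#'
#' @param x A data frame with at least `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`. Missing optional columns
#'   (`chrom`, `pos`, `eaf`, `n`) are filled with `NA`.
#' @param trait_name Label for the trait the GWAS measured.
#' @param trait_type `"continuous"` or `"binary-logOR"`.
#'
#' @return A `sumstats` tibble with attributes `trait_name`, `trait_type`,
#'   and `load_report`.
#' @export
#' @examples
#' ss <- sumstats(
#'   data.frame(
#'     snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'     other_allele = c("G", "T"), beta = c(0.1, -0.2),
#'     se = c(0.02, 0.03), pval = c(1e-9, 1e-10)
#'   ),
#'   trait_name = "CRP", trait_type = "continuous"
#' )
sumstats <- function(x, trait_name = "trait", trait_type = c("continuous", "binary-logOR")) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mrsuite_format_error")
  }
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- x[, c("snp", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n")]
  x <- mutate(x,
    snp = as.character(.data$snp),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    across(c("eaf", "beta", "se", "pval"), as.numeric),
    n = as.numeric(.data$n)
  )

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  nt <- c("A", "C", "G", "T")
  reason <- flag(is.na(x$snp) | x$snp == "", "missing snp id")
  reason <- flag(!(x$effect_allele %in% nt) | !(x$other_allele %in% nt),
                 "non-SNP or invalid allele")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(is.na(x$beta), "missing beta")
  reason <- flag(!(x$se > 0), "nonpositive SE")
  reason <- flag(!(x$pval > 0 & x$pval <= 1), "p-value outside (0,1]")
  reason <- flag(!is.na(x$eaf) & !(x$eaf > 0 & x$eaf < 1), "EAF outside (0,1)")
  # Missing eaf is allowed; restore those rows unless another rule fired.
  reason[reason == "EAF outside (0,1)" & is.na(x$eaf)] <- NA_character_
  dup <- duplicated(x$snp)
  reason <- flag(dup & is.na(reason), "duplicate snp id (first kept)")

  rejected <- tibble(snp = x$snp[!is.na(reason)], reason = reason[!is.na(reason)])
  kept <- x[is.na(reason), ]

  report <- list(
    n_input = nrow(x),
    n_accepted = nrow(kept),
    n_rejected = nrow(rejected),
    rejections = rejected
  )
  new_sumstats(kept, trait_name = trait_name, trait_type = trait_type,
               load_report = report)
}

new_sumstats <- function(x, trait_name, trait_type, load_report = NULL) {
  structure(
    as_tibble(x),
    trait_name = trait_name,
    trait_type = trait_type,
    load_report = load_report,
    class = c("sumstats", class(as_tibble(x)))
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
}

#' Retrieve the load report of a summary-statistics table
#'
#' @param x A `sumstats` object.
#' @return A list with `n_input`, `n_accepted`, `n_rejected`, and a
#'   `rejections` tibble (`snp`, `reason`).
#' @export
load_report <- function(x) attr(x, "load_report")

#' Trait metadata accessors
#'
#' @param x A `sumstats` object.
#' @return The trait name or trait type string.
#' @export
trait_name <- function(x) attr(x, "trait_name")

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file into a validated [sumstats] object. The
#' canonical dialect is tab-separated with header
#' `snp chrom pos effect_allele other_allele eaf beta se pval n`; foreign
#' headers are adapted through `column_map`. A JSON sidecar written by
#' [write_sumstats()] (`<path>.meta.json`), when present, restores the trait
#' name and type.
#'
#' @param path Path to the delimited file (comment lines starting `#` are
#'   skipped).
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp = "MarkerName", beta = "Effect")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param trait_name,trait_type Trait metadata; the sidecar, when present,
#'   takes precedence.
#' @return A validated `sumstats` tibble; rejected rows are counted in the
#'   load report.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_name = NULL, trait_type = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mrsuite_format_error")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = "NA", col_types = readr::cols(.default = "c"))
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("chrom", "pos", "eaf", "n")
  for (canon in c(required, optional)) {
    from <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    if (from %in% names(raw) && from != canon) {
      raw[[canon]] <- raw[[from]]
    }
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mrsuite_format_error")
  }

  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    trait_name <- trait_name %||% meta$trait_name
    trait_type <- trait_type %||% meta$trait_type
  }
  out <- sumstats(raw, trait_name = trait_name %||% basename(path),
                  trait_type = trait_type %||% "continuous")
  if (nrow(out) == 0) {
    abort(paste0("no valid rows in ", path), class = "mrsuite_empty_error")
  }
  out
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-separated, canonical header, missing values as `NA`, full numeric
#' precision (17 significant digits, so read-write round-trips are exact).
#' Trait metadata goes to a `<path>.meta.json` sidecar.
#'
#' @param dataset A [sumstats] object (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  cols <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  df <- as.data.frame(dataset)[, cols]
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- format_full(df[[col]])
  }
  df$pos <- ifelse(is.na(df$pos), "NA", as.character(df$pos))
  df$chrom <- ifelse(is.na(df$chrom), "NA", as.character(df$chrom))
  readr::write_tsv(df, path, na = "NA")
  jsonlite::write_json(
    list(trait_name = attr(dataset, "trait_name") %||% "trait",
         trait_type = attr(dataset, "trait_type") %||% "continuous"),
    paste0(path, ".meta.json"), auto_unbox = TRUE
  )
  invisible(path)
}

format_full <- function(x) {
  out <- vapply(as.numeric(x), function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = NA, trim = TRUE)
  }, character(1))
  out
}

#' Read and write LD matrices
#'
#' The on-disk format is a tab-separated table whose first column and header
#' row carry the variant IDs; cells are pairwise r-squared values. On read
#' the matrix is validated: symmetric to 1e-12, unit diagonal, all values in
#' \[0, 1\].
#'
#' @param path File path.
#' @return `read_ld()`: a numeric matrix with `snp` dimnames.
#' @export
read_ld <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids) || nrow(m) != ncol(m)) {
    abort("LD matrix header/rows mismatch", class = "mrsuite_format_error")
  }
  rownames(m) <- ids
  validate_ld(m)
  m
}

#' @rdname read_ld
#' @param matrix Square symmetric numeric matrix of r-squared values with
#'   variant IDs as dimnames.
#' @export
write_ld <- function(matrix, path) {
  validate_ld(matrix)
  df <- as_tibble(matrix)
  df <- bind_cols(tibble(snp = rownames(matrix)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

validate_ld <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("LD matrix requires snp dimnames", class = "mrsuite_format_error")
  }
  if (max(abs(m - t(m))) > 1e-12) {
    abort("LD matrix not symmetric (tolerance 1e-12)", class = "mrsuite_format_error")
  }
  if (any(abs(diag(m) - 1) > 0)) {
    abort("LD matrix diagonal must be exactly 1", class = "mrsuite_format_error")
  }
  if (any(m < 0 | m > 1)) {
    abort("LD r-squared values must lie in [0, 1]", class = "mrsuite_format_error")
  }
  invisible(m)
}
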