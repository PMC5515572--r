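#' Read a sample table
#'
#' Reads a per-subsample isotope table in the canonical CSV schema. Required
#' columns: `sample_id`, `specimen_id`, `taxon`, `group`, `ecology`,
#' `material`, `locality_id`, `d18Op`. Optional columns: `d18Oc`,
#' `carbonate_wt_pct`. Values are permil V-SMOW for the deltas and weight
#' percent for the carbonate content. Empty cells, `NA` and `NaN` are treated
#' as missing; lines starting with `#` are metadata comments and skipped.
#'
#' Validation is total: every row is either accepted or rejected with a
#' specific reason. With `strict = TRUE` (default) any invalid row aborts the
#' read; with `strict = FALSE` invalid rows are dropped with a warning that
#' lists each rejection.
#'
#' Row-level checks: `d18Op` present, finite and within -5..40 permil;
#' `carbonate_wt_pct`, when present, within 0..100; `group`, `ecology` and
#' `material` drawn from their allowed category sets ("semi-aquatic" and
#' "semi aquatic" are normalised to `semi_aquatic`).
#'
#' @param path Path to a CSV file.
#' @param strict Abort on any invalid row (`TRUE`) or skip invalid rows with
#'   a warning (`FALSE`).
#' @return A tibble of validated samples, row order preserved.
#' @export
read_samples <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("samples file not found: ", path), class = "paleotherm_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", na = c("", "NA", "NaN"),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample_id", "specimen_id", "taxon", "group", "ecology",
                "material", "locality_id", "d18Op")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("samples file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "paleotherm_schema_error")
  }
  for (col in c("d18Oc", "carbonate_wt_pct")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }

  out <- tibble(
    sample_id        = raw$sample_id,
    specimen_id      = raw$specimen_id,
    taxon            = raw$taxon,
    group            = tolower(trimws(raw$group)),
    ecology          = normalise_ecology(raw$ecology),
    material         = tolower(trimws(raw$material)),
    locality_id      = raw$locality_id,
    d18Op            = parse_num(raw$d18Op),
    d18Oc            = parse_num(raw$d18Oc),
    carbonate_wt_pct = parse_num(raw$carbonate_wt_pct)
  )

  reasons <- validate_sample_rows(out, raw)
  bad <- !is.na(reasons)
  if (any(bad)) {
    msgs <- paste0("row ", which(bad), " (sample_id=", raw$sample_id[bad],
                   "): ", reasons[bad])
    if (strict) {
      abort(paste0("invalid sample rows:\n", paste(msgs, collapse = "\n")),
            class = "paleotherm_validation_error")
    }
    warn(paste0("skipped ", sum(bad), " invalid sample row(s):\n",
                paste(msgs, collapse = "\n")))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

parse_num <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(as.numeric(x))
}

# One rejection reason per row, NA where the row is valid.
validate_sample_rows <- function(s, raw) {
  n <- nrow(s)
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    hit <- cond & is.na(reason)
    reason[hit] <<- msg
  }
  flag(is.na(s$sample_id) | s$sample_id == "", "missing sample_id")
  flag(!is.na(raw$d18Op) & is.na(s$d18Op), "unparseable d18Op")
  flag(is.na(s$d18Op), "missing d18Op")
  flag(!is.na(s$d18Op) & (!is.finite(s$d18Op) | s$d18Op < -5 | s$d18Op > 40),
       "d18Op outside plausible range [-5, 40] permil")
  flag(!is.na(raw$d18Oc) & is.na(s$d18Oc), "unparseable d18Oc")
  flag(!is.na(raw$carbonate_wt_pct) & is.na(s$carbonate_wt_pct),
       "unparseable carbonate_wt_pct")
  flag(!is.na(s$carbonate_wt_pct) &
         (s$carbonate_wt_pct < 0 | s$carbonate_wt_pct > 100),
       "carbonate_wt_pct outside [0, 100]")
  flag(!s$group %in% PT_GROUPS,
       paste0("group not one of: ", paste(PT_GROUPS, collapse = ", ")))
  flag(!s$ecology %in% PT_ECOLOGIES,
       paste0("ecology not one of: ", paste(PT_ECOLOGIES, collapse = ", ")))
  flag(!s$material %in% PT_MATERIALS, "material must be 'bone' or 'tooth'")
  reason
}

#' Read a locality table
#'
#' Reads the locality CSV: `locality_id`, `palaeolat_deg` (signed degrees),
#' `palaeolat_sigma_deg` (degrees, from the palaeomagnetic A95 cone),
#' `time_bin` (one of `permian`, `early_mid_triassic`, `mid_late_triassic`)
#' and optional `region`. The absolute palaeolatitude `palaeolat_abs` is
#' derived; both hemispheres are treated symmetrically by the framework.
#'
#' @param path Path to a CSV file.
#' @return A tibble of localities.
#' @export
read_localities <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("localities file not found: ", path), class = "paleotherm_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", na = c("", "NA", "NaN"),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("locality_id", "palaeolat_deg", "time_bin")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("localities file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "paleotherm_schema_error")
  }
  if (!"palaeolat_sigma_deg" %in% names(raw)) raw$palaeolat_sigma_deg <- "0"
  if (!"region" %in% names(raw)) raw$region <- NA_character_

  loc <- tibble(
    locality_id = raw$locality_id,
    palaeolat_deg = parse_num(raw$palaeolat_deg),
    palaeolat_sigma_deg = parse_num(raw$palaeolat_sigma_deg),
    time_bin = tolower(trimws(raw$time_bin)),
    region = raw$region
  )
  loc$palaeolat_sigma_deg[is.na(loc$palaeolat_sigma_deg)] <- 0
  validate_localities(loc)
  loc$palaeolat_abs <- abs(loc$palaeolat_deg)
  loc
}

validate_localities <- function(loc) {
  dup <- loc$locality_id[duplicated(loc$locality_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate locality_id: ", paste(unique(dup), collapse = ", ")),
          class = "paleotherm_validation_error")
  }
  bad_bin <- setdiff(unique(loc$time_bin), PT_TIME_BINS)
  if (length(bad_bin) > 0) {
    abort(paste0("unknown time_bin label(s): ", paste(bad_bin, collapse = ", "),
                 "; expected one of: ", paste(PT_TIME_BINS, collapse = ", ")),
          class = "paleotherm_schema_error")
  }
  if (any(is.na(loc$palaeolat_deg)) || any(abs(loc$palaeolat_deg) > 90)) {
    abort("palaeolat_deg must be numeric within [-90, 90]",
          class = "paleotherm_validation_error")
  }
  if (any(loc$palaeolat_sigma_deg < 0)) {
    abort("palaeolat_sigma_deg must be >= 0", class = "paleotherm_validation_error")
  }
  invisible(loc)
}

#' Write a sample table
#'
#' Writes samples back to the canonical CSV schema, optionally preceded by a
#' `#`-prefixed metadata comment line (config hash, seed). The written file
#' re-reads with [read_samples()] to an identical table.
#'
#' @param samples A samples tibble.
#' @param path Output path.
#' @param meta Optional named character vector written as a comment line.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, meta = NULL) {
  cols <- c("sample_id", "specimen_id", "taxon", "group", "ecology",
            "material", "locality_id", "d18Op", "d18Oc", "carbonate_wt_pct")
  write_table_with_meta(samples[, cols], path, meta, delim = ",")
}

#' Write a tab-separated result table with a metadata header
#'
#' All pipeline outputs (screening results, taxon statistics, pair
#' differences, envelope grids, calls) are written through this helper so
#' each file carries its provenance as a leading `#` comment line.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Optional named character vector, rendered as
#'   `# key=value key=value`.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_table_with_meta <- function(x, path, meta = NULL, delim = "\t") {
  body <- readr::format_delim(x, delim = delim, na = "")
  lines <- character(0)
  if (!is.null(meta) && length(meta) > 0) {
    lines <- paste0("# ", paste0(names(meta), "=", meta, collapse = " "))
  }
  writeLines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read back a pipeline result table
#'
#' Reads a tab-separated table written by [write_table_with_meta()], skipping
#' metadata comment lines.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", na = c("", "NA"), show_col_types = FALSE)
}
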