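# Long-format audit CSV reading/writing with validation, and table-shaped
# report writers.

AUDIT_COLUMNS <- c("store_id", "store_type", "rater_id", "date",
                   "measure_id", "subitem_id", "healthier_available",
                   "species_count", "price_healthier", "price_regular",
                   "price_unit", "pct_acceptable")

STORE_TYPES <- c("large_supermarket", "convenience")

#' Write an audit table to CSV
#'
#' One row per (store, rater, measure, subitem); missing values are written
#' as empty fields. The file round-trips through [read_audits()].
#'
#' @param audits Long-format audit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audits <- function(audits, path) {
  audits <- as_tibble(audits)[, AUDIT_COLUMNS]
  readr::write_csv(audits, path, na = "")
  invisible(path)
}

#' Read and validate an audit table from CSV
#'
#' Expects the exact long-format header
#' `store_id,store_type,rater_id,date,measure_id,subitem_id,healthier_available,species_count,price_healthier,price_regular,price_unit,pct_acceptable`
#' (UTF-8). Store types are the study's two classes, split at 6000 m2 of
#' floor area: `large_supermarket` and `convenience`. Every validation
#' failure is reported with the offending file line number (header = line
#' 1).
#'
#' Checks: known `measure_id`/`subitem_id` (the instrument's closed
#' vocabulary), valid store type, `healthier_available` in {0, 1},
#' non-negative species counts and prices, `pct_acceptable` in \[0, 100\]
#' and only on quality-dimension measures, and no duplicate
#' (store, rater, measure, subitem) rows.
#'
#' @param path CSV file path.
#' @param instrument Instrument defining the measure vocabulary.
#' @return A validated audit tibble.
#' @export
read_audits <- function(path, instrument = nemss_instrument()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  hdr <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), ",")[[1]]
  if (!identical(hdr, AUDIT_COLUMNS))
    stop(sprintf("unexpected header: got '%s'; expected '%s'",
                 paste(hdr, collapse = ","),
                 paste(AUDIT_COLUMNS, collapse = ",")))
  audits <- readr::read_csv(
    path, na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      store_id = "c", store_type = "c", rater_id = "c", date = "c",
      measure_id = "c", subitem_id = "c", healthier_available = "i",
      species_count = "i", price_healthier = "d", price_regular = "d",
      price_unit = "c", pct_acceptable = "d"))
  if (nrow(audits) == 0L)
    stop(sprintf("audit file '%s' contains no data rows", path))
  issues <- validate_audits(audits, instrument)
  if (nrow(issues)) {
    msgs <- sprintf("line %d: %s", issues$line, issues$problem)
    stop(paste(c(sprintf("invalid audit file '%s':", path),
                 head(msgs, 20L),
                 if (length(msgs) > 20L)
                   sprintf("... and %d more", length(msgs) - 20L)),
               collapse = "\n  "))
  }
  audits
}

#' Validate audit rows against the instrument vocabulary and value ranges
#'
#' @param audits Audit tibble (as read from CSV; row i corresponds to file
#'   line i + 1).
#' @param instrument A `cnemss_instrument`.
#' @return A tibble of issues (`line`, `problem`); zero rows when valid.
#' @export
validate_audits <- function(audits, instrument = nemss_instrument()) {
  audits <- as_tibble(audits)
  line <- seq_len(nrow(audits)) + 1L
  issues <- list()
  add <- function(bad, fmt, ...) {
    if (any(bad, na.rm = TRUE)) {
      w <- which(!is.na(bad) & bad)
      issues[[length(issues) + 1L]] <<-
        tibble(line = line[w], problem = sprintf(fmt, ...))
    }
  }
  units <- scoring_units(instrument)
  known <- paste(units$measure_id,
                 ifelse(is.na(units$subitem_id), "", units$subitem_id))
  got <- paste(audits$measure_id,
               ifelse(is.na(audits$subitem_id), "", audits$subitem_id))
  bad_measure <- !audits$measure_id %in% units$measure_id
  add(bad_measure, "unknown measure_id '%s'", audits$measure_id[which(bad_measure)])
  bad_unit <- !bad_measure & !got %in% known
  add(bad_unit, "unknown (measure_id, subitem_id) pair '%s'",
      trimws(got[which(bad_unit)]))
  add(!audits$store_type %in% STORE_TYPES,
      "store_type must be one of: %s", paste(STORE_TYPES, collapse = ", "))
  add(!audits$healthier_available %in% c(0L, 1L),
      "healthier_available must be 0 or 1")
  add(audits$species_count < 0, "species_count must be non-negative")
  add(audits$price_healthier < 0, "price_healthier must be non-negative")
  add(audits$price_regular < 0, "price_regular must be non-negative")
  add(audits$pct_acceptable < 0 | audits$pct_acceptable > 100,
      "pct_acceptable must be in [0, 100]")
  qm <- quality_measures(instrument)
  add(!is.na(audits$pct_acceptable) & !audits$measure_id %in% qm,
      "pct_acceptable recorded for a measure with no quality dimension")
  key <- paste(audits$store_id, audits$rater_id, got, sep = "\r")
  add(duplicated(key), "duplicate (store, rater, measure, subitem) row")
  if (!length(issues)) return(tibble(line = integer(0), problem = character(0)))
  arrange(dplyr::bind_rows(issues), .data$line)
}

#' Write the validity report tables
#'
#' Assembles and writes the three known-groups validity tables per rater
#' (total-score comparison; availability by store type; healthier-vs-regular
#' prices) as CSV files in `dir`, plus a combined machine-readable JSON
#' summary when the jsonlite package is available.
#'
#' @param audits Long-format audit tibble with both raters.
#' @param instrument A `cnemss_instrument`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_validity_report <- function(audits, instrument, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tot <- total_score_comparison(audits, instrument)
  f <- file.path(dir, "total_score_by_store_type.csv")
  readr::write_csv(tot, f); files <- c(files, f)
  combined <- list(total_score = tot)
  for (r in sort(unique(audits$rater_id))) {
    av <- availability_table(audits, instrument, rater = r)
    pc <- price_comparison(audits, instrument, rater = r)
    fa <- file.path(dir, sprintf("availability_by_store_type_%s.csv", r))
    fp <- file.path(dir, sprintf("price_comparison_%s.csv", r))
    readr::write_csv(av, fa); readr::write_csv(pc, fp)
    files <- c(files, fa, fp)
    combined[[paste0("availability_", r)]] <- av
    combined[[paste0("prices_", r)]] <- pc
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    fj <- file.path(dir, "validity_report.json")
    jsonlite::write_json(combined, fj, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, fj)
  }
  invisible(files)
}
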