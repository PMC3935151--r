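.require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Report offending rows by file line number (header = line 1).
.reject_rows <- function(bad, what, why) {
  if (any(bad)) {
    stop(what, ": ", why, " at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
}

#' Read a diel time-series CSV
#'
#' Expected columns: `analyte`, `treatment`, `replicate`, `compartment`,
#' `time_h`, `value`, `unit`. Units must match the compartment (`ppm` for
#' `headspace`, `mmol_L` for `liquid`/`chamber_water`); malformed rows are
#' rejected with their line numbers. LF and CRLF files parse identically.
#'
#' @param path CSV file path.
#' @return A long tibble suitable for [phase_fluxes()].
#' @export
read_timeseries_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("analyte", "treatment", "replicate", "compartment",
                         "time_h", "value", "unit"), "time-series CSV")
  df$time_h <- suppressWarnings(as.numeric(df$time_h))
  df$value <- suppressWarnings(as.numeric(df$value))
  .reject_rows(is.na(df$time_h) | is.na(df$value), "time-series CSV",
               "non-numeric time_h/value")
  .reject_rows(!df$compartment %in% c("headspace", "liquid", "chamber_water"),
               "time-series CSV", "unknown compartment")
  expected_unit <- ifelse(df$compartment == "headspace", "ppm", "mmol_L")
  .reject_rows(df$unit != expected_unit, "time-series CSV",
               "unit does not match compartment")
  .reject_rows(df$value < 0, "time-series CSV", "negative concentration")
  df
}

#' @rdname read_timeseries_csv
#' @param ts A time-series tibble.
#' @export
write_timeseries_csv <- function(ts, path) {
  readr::write_csv(ts, path)
  invisible(path)
}

#' Write/read a flux summary CSV
#'
#' Columns: `species`, `treatment`, `phase`, `flux_mmol_m2`,
#' `sd_mmol_m2`, `n_replicates`.
#'
#' @param fluxes Output of [summarize_replicates()].
#' @param path CSV file path.
#' @export
write_flux_csv <- function(fluxes, path) {
  .require_columns(fluxes, c("species", "treatment", "phase",
                             "flux_mmol_m2", "sd_mmol_m2", "n_replicates"),
                   "flux table")
  readr::write_csv(fluxes, path)
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("species", "treatment", "phase", "flux_mmol_m2",
                         "sd_mmol_m2", "n_replicates"), "flux CSV")
  df
}

#' Read/write an OTU table TSV
#'
#' Layout: first column `otu_id`, last column `taxonomy`
#' (semicolon-delimited levels), intervening columns integer per-sample
#' counts.
#'
#' @param path TSV file path.
#' @return An OTU table tibble.
#' @export
read_otu_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("otu_id", "taxonomy"), "OTU TSV")
  samples <- setdiff(names(df), c("otu_id", "taxonomy"))
  if (length(samples) == 0) {
    stop("OTU TSV has no sample count columns", call. = FALSE)
  }
  for (s in samples) {
    x <- suppressWarnings(as.numeric(df[[s]]))
    .reject_rows(is.na(x) | x < 0 | x != floor(x), "OTU TSV",
                 paste0("non-integer count in sample '", s, "'"))
    df[[s]] <- as.integer(x)
  }
  dplyr::relocate(df, "taxonomy", .after = dplyr::last_col())
}

#' @rdname read_otu_tsv
#' @param table An OTU table tibble.
#' @export
write_otu_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read/write a NanoSIMS spot-count CSV
#'
#' Columns: `region_id`, `probe`, `treatment`, `counts_12C12C`,
#' `counts_13C12C`.
#'
#' @param path CSV file path.
#' @return A spot tibble.
#' @export
read_spot_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("region_id", "probe", "treatment",
                         "counts_12C12C", "counts_13C12C"), "spot CSV")
  .reject_rows(df$counts_12C12C < 0 | df$counts_13C12C < 0, "spot CSV",
               "negative ion count")
  df
}

#' @rdname read_spot_csv
#' @param spots A spot tibble.
#' @export
write_spot_csv <- function(spots, path) {
  readr::write_csv(spots, path)
  invisible(path)
}

#' Write an electron-balance report
#'
#' Writes the full-precision per-species rows and summary as CSV and a
#' human-readable text table rounded to 1 decimal.
#'
#' @param bal An [electron_balance()].
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @export
write_balance_report <- function(bal, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(bal, "electron_balance"))
  if (!is.null(csv_path)) {
    out <- dplyr::bind_rows(
      dplyr::mutate(tidy(bal), statistic = NA_character_, percent = NA_real_,
                    sd = NA_real_),
      dplyr::mutate(bal$summary, category = "summary")
    )
    readr::write_csv(out, csv_path)
  }
  if (!is.null(txt_path)) {
    lines <- utils::capture.output(print(bal))
    writeLines(lines, txt_path)
  }
  invisible(bal)
}
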