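#' Construct a synchronized PPG/ECG/ABP signal record
#'
#' A `bp_record` is the package's container for one subject's synchronized
#' waveforms: a photoplethysmogram (`ppg`), an electrocardiogram (`ecg`) and,
#' when available, an invasive arterial blood-pressure line (`abp`), all
#' sampled at a common rate `fs` (125 Hz for bedside-monitor exports).
#' Internally it is a tibble with columns `time`, `ppg`, `ecg`, `abp`, plus
#' attributes `record_id`, `fs`, `meta` and (for synthetic records) `truth`.
#'
#' @param ppg,ecg,abp Equal-length numeric vectors. `abp` may be `NULL` when
#'   no arterial line is available; it is then stored as `NA`.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Identifier string.
#' @param meta Named list of free-form metadata.
#' @param truth Optional ground-truth list for synthetic records (see
#'   [generate_record()]).
#'
#' @return A `bp_record` tibble with one row per sample.
#' @export
bp_record <- function(ppg, ecg, abp = NULL, fs = 125, record_id = "rec",
                      meta = list(), truth = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "bpci_parameter_error")
  }
  n <- length(ppg)
  if (is.null(abp)) abp <- rep(NA_real_, n)
  if (length(ecg) != n || length(abp) != n) {
    abort("All channels of a record must have the same length.",
          class = "bpci_format_error")
  }
  out <- tibble::tibble(
    time = seq_len(n) / fs - 1 / fs,  # 0-based sample index / fs
    ppg  = as.numeric(ppg),
    ecg  = as.numeric(ecg),
    abp  = as.numeric(abp)
  )
  structure(out,
            class = c("bp_record", class(out)),
            record_id = record_id, fs = fs, meta = meta, truth = truth)
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record '%s': %d samples @ %g Hz (%.1f s)%s>\n",
              attr(x, "record_id"), nrow(x), attr(x, "fs"),
              nrow(x) / attr(x, "fs"),
              if (!is.null(attr(x, "truth"))) ", synthetic truth attached" else ""))
  NextMethod()
}

record_fs <- function(record) attr(record, "fs")
record_id <- function(record) attr(record, "record_id")
record_truth <- function(record) attr(record, "truth")

#' Read a signal record from disk
#'
#' Supports two dialects: `"csv"`, a UTF-8 header-row file with columns
#' `time,ppg,ecg,abp` ('.' decimal separator), and `"rds"`, a column-oriented
#' native container holding the same channels plus metadata (the binary
#' round-trip format written by [write_record()]). Rows in which any channel
#' is `NA`/non-finite are dropped across *all* channels so that the PPG, ECG
#' and ABP streams stay aligned; the number of dropped rows is recorded in
#' the record metadata and reported as a message.
#'
#' @param path File path.
#' @param format `"csv"` or `"rds"`. Default guesses from the file extension.
#' @param fs Sampling rate in Hz used for CSV files without an `fs` attribute.
#' @param record_id Identifier; defaults to the file stem.
#'
#' @return A [bp_record()].
#' @export
load_record <- function(path, format = c("auto", "csv", "rds"), fs = 125,
                        record_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "bpci_input_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  record_id <- record_id %||% sub("\\.[^.]*$", "", basename(path))

  if (format == "rds") {
    obj <- readRDS(path)
    rec <- bp_record(obj$ppg, obj$ecg, obj$abp, fs = obj$fs,
                     record_id = obj$record_id %||% record_id,
                     meta = obj$meta %||% list(), truth = obj$truth)
    return(drop_nonfinite_rows(rec))
  }

  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Could not parse '%s' as CSV: %s",
                                      path, conditionMessage(e)),
                              class = "bpci_format_error")
  )
  if (nrow(df) == 0L) {
    abort(sprintf("File '%s' is empty.", path), class = "bpci_input_error")
  }
  required <- c("ppg", "ecg", "abp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "bpci_format_error")
  }
  rec <- bp_record(df$ppg, df$ecg, df$abp, fs = fs, record_id = record_id)
  drop_nonfinite_rows(rec)
}

# Drop sample indices that are non-finite in any channel, across all channels,
# so alignment is preserved (removal, not imputation).
drop_nonfinite_rows <- function(record) {
  keep <- is.finite(record$ppg) & is.finite(record$ecg) &
    (is.finite(record$abp) | is.na(record$abp))
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(sprintf("Dropped %d sample(s) with non-finite values from record '%s'.",
                   n_drop, record_id(record)))
    meta <- attr(record, "meta")
    meta$dropped_samples <- n_drop
    fs <- record_fs(record)
    record <- bp_record(record$ppg[keep], record$ecg[keep], record$abp[keep],
                        fs = fs, record_id = record_id(record), meta = meta,
                        truth = record_truth(record))
  }
  record
}

#' Write a signal record to disk
#'
#' Inverse of [load_record()]: `"csv"` writes the `time,ppg,ecg,abp` dialect,
#' `"rds"` writes the native column container (including metadata and, for
#' synthetic records, the ground truth).
#'
#' @param record A [bp_record()].
#' @param path Output path.
#' @param format `"csv"` or `"rds"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") {
    saveRDS(list(ppg = record$ppg, ecg = record$ecg, abp = record$abp,
                 fs = record_fs(record), record_id = record_id(record),
                 meta = attr(record, "meta"), truth = record_truth(record)),
            path)
  } else {
    readr::write_csv(as.data.frame(record)[, c("time", "ppg", "ecg", "abp")],
                     path, progress = FALSE)
  }
  invisible(path)
}

#' Extract a fixed-duration analysis window from a record
#'
#' The estimation pipeline works on short windows: by default a 20-s stretch
#' taken after the first 60 s of each record (2500 samples at 125 Hz), which
#' skips settling transients at the start of bedside recordings.
#'
#' @param record A [bp_record()].
#' @param start_s Window start in seconds (default 60).
#' @param duration_s Window length in seconds (default 20; must be > 0).
#'
#' @return A `bp_record` of exactly `duration_s * fs` samples with attribute
#'   `window = list(start_s, duration_s)`.
#' @export
extract_window <- function(record, start_s = 60, duration_s = 20) {
  fs <- record_fs(record)
  if (duration_s <= 0) {
    abort("`duration_s` must be positive (empty windows are rejected).",
          class = "bpci_input_error")
  }
  if (start_s < 0) abort("`start_s` must be >= 0.", class = "bpci_input_error")
  n_need <- round((start_s + duration_s) * fs)
  if (nrow(record) < n_need) {
    abort(sprintf(
      "Record '%s' is too short: %d samples available, %d required for a %g-s window starting at %g s.",
      record_id(record), nrow(record), n_need, duration_s, start_s),
      class = "bpci_length_error")
  }
  i0 <- round(start_s * fs)           # 0-based start index
  n  <- round(duration_s * fs)
  idx <- seq.int(i0 + 1L, i0 + n)
  win <- bp_record(record$ppg[idx], record$ecg[idx], record$abp[idx],
                   fs = fs, record_id = record_id(record),
                   meta = attr(record, "meta"), truth = record_truth(record))
  attr(win, "window") <- list(start_s = start_s, duration_s = duration_s)
  win
}

#' Exclusion bounds for physiologically implausible reference pressures
#'
#' Labeled samples whose reference pressures fall at or beyond these bounds
#' (SBP >= 200, SBP <= 70, DBP >= 150, DBP <= 40 mmHg) are treated as outliers
#' and excluded before model fitting. Bounds are exclusionary *inclusive of
#' the boundary itself*: a sample at exactly 200 mmHg SBP is removed.
#'
#' @param sbp_hi,sbp_lo,dbp_hi,dbp_lo Bounds in mmHg.
#' @return A `bp_range_policy` list.
#' @export
range_filter_policy <- function(sbp_hi = 200, sbp_lo = 70,
                                dbp_hi = 150, dbp_lo = 40) {
  if (sbp_hi <= sbp_lo || dbp_hi <= dbp_lo) {
    abort("Upper bounds must exceed lower bounds.", class = "bpci_parameter_error")
  }
  structure(list(sbp_hi = sbp_hi, sbp_lo = sbp_lo,
                 dbp_hi = dbp_hi, dbp_lo = dbp_lo),
            class = "bp_range_policy")
}

#' Filter labeled samples by blood-pressure range
#'
#' Keeps rows with `sbp_lo < sbp < sbp_hi` and `dbp_lo < dbp < dbp_hi`
#' (strict inequalities: boundary values are excluded), preserving row order.
#' Filtering is idempotent.
#'
#' @param data A data frame with numeric `sbp` and `dbp` columns in mmHg.
#' @param policy A [range_filter_policy()].
#' @return The filtered tibble, with attribute `n_excluded`.
#' @export
apply_range_filter <- function(data, policy = range_filter_policy()) {
  stopifnot(is.data.frame(data), all(c("sbp", "dbp") %in% names(data)))
  keep <- data$sbp > policy$sbp_lo & data$sbp < policy$sbp_hi &
    data$dbp > policy$dbp_lo & data$dbp < policy$dbp_hi
  keep[is.na(keep)] <- FALSE
  out <- dplyr::filter(tibble::as_tibble(data), keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
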