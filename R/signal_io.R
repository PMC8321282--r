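# Readers/writers for the two-file tabular ECG export: a sample table
# (Sample, <lead>, <lead>, ...) and an annotation table (Time, Sample, Type).
# Comma- and whitespace-delimited variants are accepted by the same parser
# (the delimiter is sniffed from the header line).

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return(",")
  if (grepl(",", header, fixed = TRUE)) "," else ""
}

read_table_sniffed <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  sep <- sniff_sep(path)
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    strip.white = TRUE, comment.char = "")
}

#' Read a sample table into a recording
#'
#' Parses the tabular signal export: a header row naming the columns, then
#' one row per sample with integer ADC values per lead. A leading sample
#' ordinal column named `Sample` (or `sample`) is recognized and dropped;
#' every remaining column is a lead. Cells must parse as integers in
#' `[0, 2047]`.
#'
#' @param path path to the sample table (CSV or whitespace-delimited).
#' @param sampling_rate sampling frequency in Hz (default 360).
#' @param record_id identifier for the recording; defaults to the file name
#'   without extension.
#' @return An [ecg_recording()] in ADC units.
#' @export
read_signal_table <- function(path, sampling_rate = 360,
                              record_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_table_sniffed(path)
  ord_col <- which(tolower(names(df)) %in% c("sample", "'sample #'", "sample #"))
  if (length(ord_col) > 0L) df <- df[, -ord_col[1L], drop = FALSE]
  if (ncol(df) == 0L) {
    stop(sprintf("'%s' contains no lead columns", path), call. = FALSE)
  }
  n <- nrow(df)
  mat <- matrix(NA_integer_, nrow = n, ncol = ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-integer value in column '%s' of '%s' at data row %d: '%s'",
        names(df)[j], path, bad[1L], as.character(col[bad[1L]])),
        call. = FALSE)
    }
    mat[, j] <- as.integer(num)
  }
  if (n > 0L && (min(mat) < 0L || max(mat) > 2047L)) {
    stop(sprintf("'%s' contains ADC values outside [0, 2047]", path),
         call. = FALSE)
  }
  ecg_recording(mat, sampling_rate = sampling_rate, record_id = record_id,
                unit_mode = "adc")
}

#' Write a recording as a sample table
#'
#' Emits the same layout [read_signal_table()] reads: a `Sample` ordinal
#' column (0-based) followed by one integer column per lead. ADC-mode
#' recordings are written as plain integers with no decimal point.
#'
#' @param rec an [ecg_recording()] in ADC units.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (rec$unit_mode != "adc") {
    stop("only ADC-mode recordings are written; convert explicitly first",
         call. = FALSE)
  }
  n <- nrow(rec$samples)
  df <- data.frame(Sample = if (n > 0L) 0:(n - 1L) else integer(),
                   check.names = FALSE)
  for (ld in rec$lead_names) df[[ld]] <- rec$samples[, ld]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation table
#'
#' Parses the annotation export with columns `Time`, `Sample`, `Type`
#' (case-insensitive; `Time` optional). Symbols are kept verbatim with no
#' case folding. Events arriving unsorted are sorted with a warning;
#' duplicate indices are kept with a warning.
#'
#' @param path path to the annotation table.
#' @param record_id identifier; defaults from the file name.
#' @return An [ecg_annotations()] track.
#' @export
read_annotation_table <- function(path,
                                  record_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_table_sniffed(path)
  nm <- tolower(names(df))
  s_col <- match("sample", nm)
  t_col <- match("type", nm)
  if (is.na(s_col) || is.na(t_col)) {
    stop(sprintf("'%s' must have 'Sample' and 'Type' columns", path),
         call. = FALSE)
  }
  time_col <- match("time", nm)
  idx <- suppressWarnings(as.numeric(df[[s_col]]))
  if (nrow(df) > 0L &&
      (anyNA(idx) || any(idx < 0) || any(idx != round(idx)))) {
    stop(sprintf("'%s': 'Sample' column must be nonnegative integers", path),
         call. = FALSE)
  }
  ecg_annotations(sample_index = as.integer(idx),
                  symbol = as.character(df[[t_col]]),
                  time_text = if (!is.na(time_col))
                    as.character(df[[time_col]]) else NULL,
                  record_id = record_id)
}

#' Write an annotation track
#'
#' Emits `Time,Sample,Type` rows readable by [read_annotation_table()].
#'
#' @param track an [ecg_annotations()] track.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(track, path) {
  stopifnot(inherits(track, "ecg_annotations"))
  ev <- track$events
  df <- data.frame(Time = ifelse(is.na(ev$time_text), "", ev$time_text),
                   Sample = ev$sample_index,
                   Type = ev$symbol, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
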