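#' Single- or multi-lead ECG recording
#'
#' An `ecg_recording` holds a digitized ambulatory ECG: an integer sample
#' matrix (one row per time point, one column per lead) in 11-bit ADC units
#' over a +/-5 mV range, where the code 1024 corresponds to 0 V. Values may
#' alternatively be carried in millivolts after an explicit conversion with
#' [adc_to_millivolts()]; the `unit_mode` attribute records which.
#'
#' @param samples integer matrix, one column per lead; in `"adc"` mode every
#'   value must lie in `[0, 2047]`.
#' @param lead_names character vector of unique lead names (e.g. `"MLII"`,
#'   `"V5"`), one per column.
#' @param sampling_rate sampling frequency in Hz (default 360, the MIT-BIH
#'   rate).
#' @param record_id identifier tying segments and annotations back to this
#'   recording.
#' @param unit_mode `"adc"` (raw integer codes) or `"mv"` (millivolts).
#' @return An object of class `ecg_recording`.
#' @examples
#' rec <- ecg_recording(cbind(MLII = c(995L, 1000L), V5 = c(1011L, 1008L)),
#'                      record_id = "100")
#' n_samples(rec)
#' @export
ecg_recording <- function(samples, lead_names = colnames(samples),
                          sampling_rate = 360, record_id = "record",
                          unit_mode = c("adc", "mv")) {
  unit_mode <- match.arg(unit_mode)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  if (is.null(lead_names)) {
    lead_names <- paste0("lead", seq_len(ncol(samples)))
  }
  lead_names <- as.character(lead_names)
  if (length(lead_names) != ncol(samples)) {
    stop("`lead_names` must name every column of `samples`", call. = FALSE)
  }
  if (anyDuplicated(lead_names)) {
    stop("lead names must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (unit_mode == "adc" && nrow(samples) > 0L) {
    if (any(samples != round(samples))) {
      stop("ADC-mode samples must be integers", call. = FALSE)
    }
    rng <- range(samples)
    if (rng[1L] < 0 || rng[2L] > 2047) {
      stop(sprintf("ADC values must lie in [0, 2047]; found range [%s, %s]",
                   rng[1L], rng[2L]), call. = FALSE)
    }
    storage.mode(samples) <- "integer"
  }
  colnames(samples) <- lead_names
  structure(
    list(record_id = as.character(record_id),
         sampling_rate = sampling_rate,
         lead_names = lead_names,
         samples = samples,
         unit_mode = unit_mode),
    class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording '%s'> %d samples x %d lead(s) [%s] @ %g Hz (%s)\n",
              x$record_id, nrow(x$samples), ncol(x$samples),
              paste(x$lead_names, collapse = ", "),
              x$sampling_rate, x$unit_mode))
  invisible(x)
}

#' Number of samples per lead in a recording
#' @param rec an [ecg_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  nrow(rec$samples)
}

#' Beat/rhythm annotation track attached to a recording
#'
#' Ordered expert annotations: each event marks a sample index (usually an
#' R peak) with a symbol such as `"N"` (normal beat) or `"V"` (premature
#' ventricular contraction). The optional clock-time text is carried verbatim
#' and never parsed; the sample index is the single source of truth for
#' position.
#'
#' @param sample_index nonnegative integer vector of event positions
#'   (0-based sample coordinates, matching the signal table's `Sample`
#'   column).
#' @param symbol character vector of non-empty annotation symbols.
#' @param time_text optional character vector of clock-time strings.
#' @param record_id identifier of the annotated recording.
#' @return An object of class `ecg_annotations` (a data frame of events
#'   sorted by `sample_index`).
#' @examples
#' ann <- ecg_annotations(c(77L, 370L), c("N", "N"), record_id = "100")
#' @export
ecg_annotations <- function(sample_index = integer(), symbol = character(),
                            time_text = NULL, record_id = "record") {
  if (length(sample_index) != length(symbol)) {
    stop("`sample_index` and `symbol` must have equal length", call. = FALSE)
  }
  if (length(sample_index) > 0L) {
    if (any(!is.finite(sample_index)) || any(sample_index < 0) ||
        any(sample_index != round(sample_index))) {
      stop("`sample_index` must be nonnegative integers", call. = FALSE)
    }
    if (any(!nzchar(symbol)) || anyNA(symbol)) {
      stop("every annotation symbol must be a non-empty string", call. = FALSE)
    }
  }
  if (is.null(time_text)) time_text <- rep(NA_character_, length(sample_index))
  ev <- data.frame(sample_index = as.integer(sample_index),
                   symbol = as.character(symbol),
                   time_text = as.character(time_text),
                   stringsAsFactors = FALSE)
  if (is.unsorted(ev$sample_index)) {
    warning("annotation events were not sorted by sample index; sorting",
            call. = FALSE)
    ev <- ev[order(ev$sample_index), , drop = FALSE]
  }
  if (anyDuplicated(ev$sample_index)) {
    warning("duplicate annotation sample indices; keeping all", call. = FALSE)
  }
  rownames(ev) <- NULL
  structure(list(record_id = as.character(record_id), events = ev),
            class = "ecg_annotations")
}

#' @export
print.ecg_annotations <- function(x, ...) {
  cat(sprintf("<ecg_annotations '%s'> %d events", x$record_id,
              nrow(x$events)))
  if (nrow(x$events) > 0L) {
    cat(sprintf(" [symbols: %s]",
                paste(sort(unique(x$events$symbol)), collapse = " ")))
  }
  cat("\n")
  invisible(x)
}

#' Convert 11-bit ADC codes to millivolts
#'
#' The digitization convention is 11 bits over a +/-5 mV range with the code
#' 1024 at 0 V, i.e. `mv = (value - 1024) * 10 / 2048`. The map is affine and
#' strictly increasing: 0 -> -5 mV, 1024 -> 0 mV, 2047 -> +4.99512 mV.
#'
#' @param value numeric vector of ADC codes in `[0, 2047]`.
#' @return numeric vector of millivolt values.
#' @examples
#' adc_to_millivolts(c(0, 1024, 2047))
#' @export
adc_to_millivolts <- function(value) {
  if (length(value) > 0L &&
      (any(!is.finite(value)) || any(value < 0) || any(value > 2047))) {
    stop("ADC values must lie in [0, 2047]", call. = FALSE)
  }
  (value - 1024) * 10 / 2048
}

#' Convert millivolts back to 11-bit ADC codes
#'
#' Inverse of [adc_to_millivolts()] with rounding to the nearest code and
#' clipping to the representable range `[0, 2047]`.
#'
#' @param mv numeric vector in millivolts.
#' @return integer vector of ADC codes.
#' @export
millivolts_to_adc <- function(mv) {
  v <- round(mv * 2048 / 10 + 1024)
  as.integer(pmin(pmax(v, 0), 2047))
}

#' Project a recording onto a single lead
#'
#' Most MIT-BIH recordings carry MLII as one of their two channels; analyses
#' here use that lead only, and recordings lacking it are excluded. Absence of
#' the requested lead raises a condition of class `lead_unavailable` so
#' callers can trap it to drop such recordings.
#'
#' @param rec an [ecg_recording()].
#' @param lead lead name to keep (default `"MLII"`).
#' @return A single-lead `ecg_recording` with provenance preserved.
#' @export
select_lead <- function(rec, lead = "MLII") {
  stopifnot(inherits(rec, "ecg_recording"))
  if (!lead %in% rec$lead_names) {
    stop(structure(
      class = c("lead_unavailable", "error", "condition"),
      list(message = sprintf(
             "recording '%s' has no lead '%s' (available: %s)",
             rec$record_id, lead, paste(rec$lead_names, collapse = ", ")),
           call = NULL)))
  }
  ecg_recording(rec$samples[, lead, drop = FALSE], lead_names = lead,
                sampling_rate = rec$sampling_rate,
                record_id = rec$record_id, unit_mode = rec$unit_mode)
}

#' Convert a recording's sample values to millivolts
#'
#' @param rec an [ecg_recording()] in `"adc"` mode (a `"mv"` recording is
#'   returned unchanged).
#' @return The same recording with `unit_mode = "mv"`.
#' @export
recording_to_millivolts <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (rec$unit_mode == "mv") return(rec)
  out <- rec
  out$samples <- adc_to_millivolts(rec$samples)
  colnames(out$samples) <- rec$lead_names
  out$unit_mode <- "mv"
  out
}
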