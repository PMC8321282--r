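# Fixed-window segmentation and annotation-driven binary labeling.
# A 15-s window at 360 Hz is 5400 samples; a window is anomalous as soon as
# one annotated event in it is anomalous, normal only if every event is
# normal. Rhythm-change and signal-quality annotations count as anomalous on
# the same footing as beat-level ones.

#' Default anomalous annotation symbols
#'
#' The 21 standard MIT-BIH/WFDB codes covering beat alterations (L, R, A, a,
#' J, S, V, F, !, e, j, E, /, f, x, Q), artifact and signal-quality events
#' (|, ~) and rhythm markers (+, [, ]). Normal beats are "N".
#'
#' @format character vector of length 21.
#' @export
MITBIH_ANOMALOUS_SYMBOLS <- c("L", "R", "A", "a", "J", "S", "V", "F", "!",
                              "e", "j", "E", "/", "f", "x", "Q", "|", "~",
                              "+", "[", "]")

#' Binary symbol classification map
#'
#' Partitions annotation symbols into a normal set and an anomalous set. A
#' symbol in neither set is an error at labeling time, never silently normal.
#'
#' @param normal_symbols character set of normal symbols (default `"N"`).
#' @param anomalous_symbols character set of anomalous symbols (default the
#'   21 MIT-BIH anomaly codes, [MITBIH_ANOMALOUS_SYMBOLS]).
#' @return An object of class `symbol_map`.
#' @export
symbol_map <- function(normal_symbols = "N",
                       anomalous_symbols = MITBIH_ANOMALOUS_SYMBOLS) {
  normal_symbols <- unique(as.character(normal_symbols))
  anomalous_symbols <- unique(as.character(anomalous_symbols))
  if (length(normal_symbols) == 0L || length(anomalous_symbols) == 0L) {
    stop("both symbol sets must be non-empty", call. = FALSE)
  }
  overlap <- intersect(normal_symbols, anomalous_symbols)
  if (length(overlap) > 0L) {
    stop(sprintf("symbols classified as both normal and anomalous: %s",
                 paste(overlap, collapse = " ")), call. = FALSE)
  }
  structure(list(normal_symbols = normal_symbols,
                 anomalous_symbols = anomalous_symbols),
            class = "symbol_map")
}

#' Cut a single-lead recording into fixed non-overlapping windows
#'
#' Windows are half-open `[i * seg_len, (i + 1) * seg_len)` in 0-based sample
#' coordinates, left-aligned and contiguous; a trailing partial window is
#' dropped, so the count is `floor(n_samples / seg_len)`.
#'
#' @param rec a single-lead [ecg_recording()].
#' @param window_seconds window length in seconds (default 15).
#' @return A list of unlabeled segments, each a list with `record_id`,
#'   `segment_index` (0-based), and `samples` (length `seg_len`).
#' @export
fragment <- function(rec, window_seconds = 15) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (ncol(rec$samples) != 1L) {
    stop("`fragment()` requires a single-lead recording; use select_lead()",
         call. = FALSE)
  }
  seg_len <- window_seconds * rec$sampling_rate
  if (!is.finite(seg_len) || seg_len <= 0 || seg_len != round(seg_len)) {
    stop("window_seconds x sampling_rate must be a positive integer",
         call. = FALSE)
  }
  seg_len <- as.integer(seg_len)
  n_seg <- nrow(rec$samples) %/% seg_len
  lapply(seq_len(n_seg) - 1L, function(i) {
    list(record_id = rec$record_id,
         segment_index = i,
         samples = rec$samples[(i * seg_len + 1L):((i + 1L) * seg_len), 1L])
  })
}

#' Attach annotation symbols to their containing windows
#'
#' An event at sample index `s` belongs to window `floor(s / seg_len)`;
#' events beyond the covered range (including any in a dropped trailing
#' partial window) are dropped with a warning.
#'
#' @param segments output of [fragment()].
#' @param track an [ecg_annotations()] for the same recording.
#' @param seg_len window length in samples.
#' @return `segments` with `symbols_present` (character vector, may repeat)
#'   and `annotated` (logical) filled in.
#' @export
assign_annotations <- function(segments, track, seg_len) {
  stopifnot(inherits(track, "ecg_annotations"))
  if (length(segments) > 0L &&
      !identical(segments[[1L]]$record_id, track$record_id)) {
    stop(sprintf("annotation track is for record '%s', segments for '%s'",
                 track$record_id, segments[[1L]]$record_id), call. = FALSE)
  }
  ev <- track$events
  win <- ev$sample_index %/% seg_len
  dropped <- win >= length(segments)
  if (any(dropped)) {
    warning(sprintf(
      "%d annotation event(s) beyond the segmented range were dropped",
      sum(dropped)), call. = FALSE)
  }
  for (i in seq_along(segments)) {
    segments[[i]]$symbols_present <- ev$symbol[win == (i - 1L)]
    segments[[i]]$annotated <- length(segments[[i]]$symbols_present) > 0L
  }
  segments
}

#' Label one window from the symbols it contains
#'
#' Anomalous if at least one contained symbol is anomalous; normal if every
#' symbol is normal. An empty symbol set labels normal (the window carries no
#' evidence either way; callers see `annotated = FALSE`). A symbol the map
#' does not classify raises an error of class `unknown_symbol`.
#'
#' @param symbols_present character vector of symbols in the window.
#' @param map a [symbol_map()].
#' @return `"normal"` or `"anomalous"`.
#' @export
label_segment <- function(symbols_present, map = symbol_map()) {
  stopifnot(inherits(map, "symbol_map"))
  known <- c(map$normal_symbols, map$anomalous_symbols)
  unknown <- setdiff(unique(symbols_present), known)
  if (length(unknown) > 0L) {
    stop(structure(
      class = c("unknown_symbol", "error", "condition"),
      list(message = sprintf("unclassified annotation symbol(s): %s",
                             paste(unknown, collapse = " ")),
           call = NULL)))
  }
  if (any(symbols_present %in% map$anomalous_symbols)) "anomalous" else "normal"
}

#' Labeled fixed-window segment dataset
#'
#' Container for the per-window rows of the analysis table: an
#' `n_segments x seg_len` sample matrix plus label, provenance and the
#' annotation symbols each window contained.
#'
#' @param samples numeric matrix, one row per segment.
#' @param label character/factor vector in `{normal, anomalous}`.
#' @param record_id character vector of source recording ids.
#' @param segment_index integer vector of 0-based window ordinals.
#' @param symbols list of per-segment symbol vectors.
#' @param annotated logical vector; `FALSE` marks windows with no events.
#' @param seg_len window length in samples.
#' @param lead_name name of the source lead (default `"MLII"`).
#' @return An object of class `segment_dataset`.
#' @export
segment_dataset <- function(samples, label, record_id, segment_index,
                            symbols = NULL, annotated = NULL,
                            seg_len = ncol(samples), lead_name = "MLII") {
  n <- nrow(samples)
  stopifnot(length(label) == n, length(record_id) == n,
            length(segment_index) == n, ncol(samples) == seg_len)
  label <- factor(as.character(label), levels = c("normal", "anomalous"))
  if (anyNA(label)) {
    stop("labels must be 'normal' or 'anomalous'", call. = FALSE)
  }
  key <- paste(record_id, segment_index, sep = "#")
  if (anyDuplicated(key)) {
    stop("duplicate (record_id, segment_index) pairs", call. = FALSE)
  }
  if (is.null(symbols)) symbols <- rep(list(character()), n)
  if (is.null(annotated)) annotated <- lengths(symbols) > 0L
  structure(list(samples = samples, label = label,
                 record_id = as.character(record_id),
                 segment_index = as.integer(segment_index),
                 symbols = symbols, annotated = as.logical(annotated),
                 seg_len = as.integer(seg_len),
                 lead_name = lead_name),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf(
    "<segment_dataset> %d segments of %d samples (%d normal, %d anomalous) from %d recording(s)\n",
    nrow(x$samples), x$seg_len, tab[["normal"]], tab[["anomalous"]],
    length(unique(x$record_id))))
  invisible(x)
}

#' Number of segments in a dataset
#' @param ds a [segment_dataset()].
#' @return integer count.
#' @export
n_segments <- function(ds) {
  stopifnot(inherits(ds, "segment_dataset"))
  nrow(ds$samples)
}

#' Subset a segment dataset by row index
#' @param ds a [segment_dataset()].
#' @param i integer or logical index vector.
#' @return A `segment_dataset` with the selected rows.
#' @export
subset_segments <- function(ds, i) {
  stopifnot(inherits(ds, "segment_dataset"))
  segment_dataset(ds$samples[i, , drop = FALSE], ds$label[i],
                  ds$record_id[i], ds$segment_index[i],
                  symbols = ds$symbols[i], annotated = ds$annotated[i],
                  seg_len = ds$seg_len, lead_name = ds$lead_name)
}

#' Combine segment datasets
#' @param ... `segment_dataset` objects with equal `seg_len`.
#' @return The row-wise concatenation.
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "segment_dataset")) {
    parts <- parts[[1L]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1L), "segment_dataset")))
  seg_len <- unique(vapply(parts, function(p) p$seg_len, integer(1L)))
  if (length(seg_len) != 1L) {
    stop("all datasets must share seg_len", call. = FALSE)
  }
  segment_dataset(
    do.call(rbind, lapply(parts, function(p) p$samples)),
    unlist(lapply(parts, function(p) as.character(p$label))),
    unlist(lapply(parts, function(p) p$record_id)),
    unlist(lapply(parts, function(p) p$segment_index)),
    symbols = do.call(c, lapply(parts, function(p) p$symbols)),
    annotated = unlist(lapply(parts, function(p) p$annotated)),
    seg_len = seg_len, lead_name = parts[[1L]]$lead_name)
}

#' Build the labeled segment table for one recording
#'
#' Composes [fragment()], [assign_annotations()] and [label_segment()]: cuts
#' the lead into fixed windows, attaches each annotation to its window and
#' labels every window. Windows with no annotations are labeled normal,
#' flagged `annotated = FALSE` and (optionally) excluded.
#'
#' @param rec a single- or multi-lead [ecg_recording()]; multi-lead input is
#'   projected with [select_lead()] onto `lead`.
#' @param track the matching [ecg_annotations()].
#' @param map a [symbol_map()].
#' @param window_seconds window length in seconds (default 15).
#' @param lead lead to analyse (default `"MLII"`).
#' @param drop_unannotated drop windows containing no events (default FALSE:
#'   they are kept, labeled normal, and counted in a message).
#' @return A [segment_dataset()].
#' @export
build_segment_dataset <- function(rec, track, map = symbol_map(),
                                  window_seconds = 15, lead = "MLII",
                                  drop_unannotated = FALSE) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (ncol(rec$samples) > 1L) rec <- select_lead(rec, lead)
  seg_len <- as.integer(window_seconds * rec$sampling_rate)
  segs <- assign_annotations(fragment(rec, window_seconds), track, seg_len)
  if (length(segs) == 0L) {
    return(segment_dataset(matrix(integer(), 0L, seg_len), character(),
                           character(), integer(), seg_len = seg_len,
                           lead_name = rec$lead_names[1L]))
  }
  labels <- vapply(segs, function(s) label_segment(s$symbols_present, map),
                   character(1L))
  annotated <- vapply(segs, `[[`, logical(1L), "annotated")
  if (any(!annotated)) {
    message(sprintf("record '%s': %d window(s) with no annotations labeled normal%s",
                    rec$record_id, sum(!annotated),
                    if (drop_unannotated) " and dropped" else ""))
  }
  keep <- if (drop_unannotated) annotated else rep(TRUE, length(segs))
  segment_dataset(
    do.call(rbind, lapply(segs[keep], `[[`, "samples")),
    labels[keep],
    vapply(segs[keep], `[[`, character(1L), "record_id"),
    vapply(segs[keep], `[[`, integer(1L), "segment_index"),
    symbols = lapply(segs[keep], `[[`, "symbols_present"),
    annotated = annotated[keep],
    seg_len = seg_len, lead_name = rec$lead_names[1L])
}

#' Write a segment dataset as the per-window analysis table
#'
#' One row per window with columns `<lead>_0 ... <lead>_(seg_len-1)` and a
#' final `Type` column (`N` / `A`), plus provenance columns `record_id` and
#' `segment_index` so patient-wise operations survive a round trip.
#'
#' @param ds a [segment_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(ds, path) {
  stopifnot(inherits(ds, "segment_dataset"))
  df <- as.data.frame(ds$samples)
  names(df) <- paste0(ds$lead_name, "_", seq_len(ds$seg_len) - 1L)
  df$Type <- ifelse(ds$label == "anomalous", "A", "N")
  df$record_id <- ds$record_id
  df$segment_index <- ds$segment_index
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-window analysis table written by [write_segment_table()]
#'
#' @param path CSV path.
#' @return A [segment_dataset()].
#' @export
read_segment_table <- function(path) {
  df <- read_table_sniffed(path)
  sample_cols <- grep("_[0-9]+$", names(df))
  sample_cols <- setdiff(sample_cols, which(names(df) == "segment_index"))
  if (length(sample_cols) == 0L || !"Type" %in% names(df)) {
    stop(sprintf("'%s' is not a segment table", path), call. = FALSE)
  }
  lead <- sub("_[0-9]+$", "", names(df)[sample_cols[1L]])
  mat <- as.matrix(df[, sample_cols, drop = FALSE])
  dimnames(mat) <- NULL
  n <- nrow(df)
  segment_dataset(
    mat,
    ifelse(df$Type == "A", "anomalous", "normal"),
    if ("record_id" %in% names(df)) as.character(df$record_id)
      else rep("record", n),
    if ("segment_index" %in% names(df)) df$segment_index else seq_len(n) - 1L,
    seg_len = length(sample_cols), lead_name = lead)
}
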