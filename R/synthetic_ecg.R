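# Annotated synthetic single-lead ECG. A beat is a sum of five Gaussian
# bumps (P, Q, R, S, T) placed relative to the R peak; beats are laid out by
# a jittered RR process; per-beat anomalies (premature ventricular beats,
# premature atrial beats, artifact bursts) fire as independent Bernoulli
# draws on a dedicated random stream so event placement and signal noise are
# separately reproducible. The goal is format fidelity and class
# separability, not physiological realism.

normal_morphology <- function() {
  # amplitude (mV), center offset from R (s), width (s)
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amplitude = c(0.12, -0.12, 1.00, -0.25, 0.35),
             center = c(-0.200, -0.040, 0.000, 0.030, 0.250),
             width = c(0.025, 0.010, 0.018, 0.012, 0.060))
}

pvc_morphology <- function() {
  # wide, inverted, large QRS with discordant T and no P wave
  data.frame(wave = c("R", "T"),
             amplitude = c(-1.30, 0.60),
             center = c(0.000, 0.280),
             width = c(0.050, 0.090))
}

#' Default per-beat anomaly specification
#'
#' Three event types: `"V"` (premature ventricular contraction: premature,
#' widened, inverted large beat followed by a compensatory pause), `"A"`
#' (premature atrial beat: premature timing, normal shape) and `"|"`
#' (isolated artifact burst replacing the beat waveform).
#'
#' @param v_rate,a_rate,artifact_rate per-beat firing probabilities.
#' @return A list of anomaly descriptors.
#' @export
default_anomalies <- function(v_rate = 0, a_rate = 0, artifact_rate = 0) {
  list(list(symbol = "V", rate = v_rate, kind = "pvc"),
       list(symbol = "A", rate = a_rate, kind = "premature_normal"),
       list(symbol = "|", rate = artifact_rate, kind = "artifact"))
}

#' Synthetic recording configuration
#'
#' @param duration_s recording length in seconds.
#' @param sampling_rate Hz (default 360).
#' @param mean_rr_s mean RR interval in seconds (default 0.8, i.e. 75 bpm).
#' @param rr_jitter_sd per-beat RR standard deviation in seconds
#'   (default 0.04).
#' @param noise_sd_mv white baseline noise standard deviation in mV
#'   (default 0.02).
#' @param morphology data frame (amplitude, center, width) of the normal
#'   beat's Gaussian components.
#' @param anomalies list from [default_anomalies()] (all rates 0 by default:
#'   a clean normal recording).
#' @param premature_factor fraction of the preceding RR kept by a premature
#'   beat (default 0.6); the stolen interval is returned as a compensatory
#'   pause after the beat.
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 60, sampling_rate = 360,
                             mean_rr_s = 0.8, rr_jitter_sd = 0.04,
                             noise_sd_mv = 0.02,
                             morphology = normal_morphology(),
                             anomalies = default_anomalies(),
                             premature_factor = 0.6, seed = 1L) {
  stopifnot(duration_s > 0, sampling_rate > 0, mean_rr_s > 0,
            rr_jitter_sd >= 0, noise_sd_mv >= 0,
            premature_factor > 0, premature_factor < 1)
  if (mean_rr_s > duration_s) {
    stop("mean RR interval exceeds the recording duration", call. = FALSE)
  }
  for (a in anomalies) {
    if (a$rate < 0 || a$rate > 1) {
      stop(sprintf("anomaly rate for '%s' outside [0, 1]", a$symbol),
           call. = FALSE)
    }
  }
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 mean_rr_s = mean_rr_s, rr_jitter_sd = rr_jitter_sd,
                 noise_sd_mv = noise_sd_mv, morphology = morphology,
                 anomalies = anomalies, premature_factor = premature_factor,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

add_beat <- function(signal_mv, t_grid, r_time, morph) {
  lo <- r_time - 0.45
  hi <- r_time + 0.55
  ix <- which(t_grid >= lo & t_grid <= hi)
  if (length(ix) == 0L) return(signal_mv)
  tt <- t_grid[ix]
  for (w in seq_len(nrow(morph))) {
    signal_mv[ix] <- signal_mv[ix] + morph$amplitude[w] *
      exp(-(tt - r_time - morph$center[w])^2 / (2 * morph$width[w]^2))
  }
  signal_mv
}

#' Simulate an annotated single-lead recording
#'
#' Produces the signal, the R-peak-anchored annotation track, and the
#' ground-truth 15-s window labels implied by the event list (a window is
#' anomalous iff it contains at least one non-"N" event). Sub-seeds derived
#' from `cfg$seed` drive three independent streams: beat timing, anomaly
#' draws, and baseline noise.
#'
#' @param cfg a [synthetic_config()].
#' @param record_id identifier for the emitted recording.
#' @param lead_name lead label (default `"MLII"`).
#' @return A list `(recording, annotations, truth)`; `truth` is a data frame
#'   of `record_id, segment_index, label` for 15-s windows (empty if the
#'   recording is shorter than one window).
#' @export
simulate_recording <- function(cfg, record_id = "sim", lead_name = "MLII") {
  stopifnot(inherits(cfg, "synthetic_config"))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration_s * fs)
  t_grid <- (seq_len(n) - 1L) / fs

  # stream 1: base beat schedule
  rr <- with_seed(cfg$seed, {
    n_max <- ceiling(cfg$duration_s / cfg$mean_rr_s) + 10L
    pmax(cfg$mean_rr_s + stats::rnorm(n_max, 0, cfg$rr_jitter_sd),
         0.3 * cfg$mean_rr_s)
  })

  # stream 2: per-beat anomaly draws (first matching symbol wins)
  n_beats_max <- length(rr)
  symbols <- with_seed(cfg$seed + 1000003L, {
    sym <- rep("N", n_beats_max)
    for (a in cfg$anomalies) {
      if (a$rate <= 0) next
      fire <- stats::runif(n_beats_max) < a$rate
      sym[fire & sym == "N"] <- a$symbol
    }
    sym
  })

  # premature beats steal (1 - factor) of the preceding RR and give it back
  # as a compensatory pause after themselves; rr[i - 1] is the interval
  # ending at beat i
  premature <- symbols %in% c("V", "A")
  for (i in which(premature)) {
    if (i < 2L) next
    stolen <- rr[i - 1L] * (1 - cfg$premature_factor)
    rr[i - 1L] <- rr[i - 1L] - stolen
    rr[i] <- rr[i] + stolen
  }

  r_times <- cfg$mean_rr_s / 2 + cumsum(c(0, rr))[seq_len(n_beats_max)]
  keep <- r_times < cfg$duration_s - 0.1
  r_times <- r_times[keep]
  symbols <- symbols[keep]

  signal_mv <- numeric(n)
  artifact_windows <- list()
  for (i in seq_along(r_times)) {
    kind <- "normal"
    for (a in cfg$anomalies) if (a$symbol == symbols[i]) kind <- a$kind
    if (kind == "pvc") {
      signal_mv <- add_beat(signal_mv, t_grid, r_times[i], pvc_morphology())
    } else if (kind == "artifact") {
      artifact_windows[[length(artifact_windows) + 1L]] <- r_times[i]
    } else {
      signal_mv <- add_beat(signal_mv, t_grid, r_times[i], cfg$morphology)
    }
  }

  # stream 3: baseline noise, then artifact bursts on the same stream
  signal_mv <- with_seed(cfg$seed + 2000003L, {
    if (cfg$noise_sd_mv > 0) {
      signal_mv <- signal_mv + stats::rnorm(n, 0, cfg$noise_sd_mv)
    }
    for (w in artifact_windows) {
      ix <- which(t_grid >= w - 0.1 & t_grid <= w + 0.1)
      signal_mv[ix] <- signal_mv[ix] + stats::runif(length(ix), -0.8, 0.8)
    }
    signal_mv
  })

  samples <- matrix(millivolts_to_adc(signal_mv), ncol = 1L,
                    dimnames = list(NULL, lead_name))
  rec <- ecg_recording(samples, sampling_rate = fs, record_id = record_id)
  r_samples <- pmin(round(r_times * fs), n - 1L)
  track <- ecg_annotations(
    sample_index = r_samples, symbol = symbols,
    time_text = sprintf("%d:%06.3f", floor(r_times / 60), r_times %% 60),
    record_id = record_id)

  seg_len <- as.integer(15 * fs)
  n_seg <- n %/% seg_len
  truth <- if (n_seg > 0L) {
    win <- as.integer(r_samples) %/% seg_len
    lab <- vapply(seq_len(n_seg) - 1L, function(i) {
      if (any(symbols[win == i] != "N")) "anomalous" else "normal"
    }, character(1L))
    data.frame(record_id = record_id, segment_index = seq_len(n_seg) - 1L,
               label = lab, stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = character(), segment_index = integer(),
               label = character(), stringsAsFactors = FALSE)
  }
  list(recording = rec, annotations = track, truth = truth)
}

#' Write a benchmark of synthetic recordings plus a truth manifest
#'
#' Generates `n_records` recordings — a leading block of clean (all-normal)
#' records followed by records carrying premature ventricular beats at
#' `pvc_rate` — and writes for each the sample table, the annotation table
#' and one combined truth manifest (`truth.csv`: per-segment ground-truth
#' labels; `records.csv`: per-record status).
#'
#' @param out_dir output directory (created if needed).
#' @param n_records number of recordings (default 4).
#' @param n_clean how many are clean (default half, rounded down).
#' @param duration_s per-record duration in seconds (default 300).
#' @param pvc_rate per-beat PVC probability in the anomalous block
#'   (default 0.3).
#' @param seed integer seed; record `i` uses `seed + i`.
#' @param ... further arguments passed to [synthetic_config()].
#' @return Invisibly, the truth manifest data frame.
#' @export
make_benchmark <- function(out_dir, n_records = 4L,
                           n_clean = n_records %/% 2L, duration_s = 300,
                           pvc_rate = 0.3, seed = 1L, ...) {
  stopifnot(n_records >= 1, n_clean >= 0, n_clean <= n_records)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  records <- list()
  for (i in seq_len(n_records)) {
    clean <- i <= n_clean
    cfg <- synthetic_config(
      duration_s = duration_s,
      anomalies = default_anomalies(v_rate = if (clean) 0 else pvc_rate),
      seed = seed + i, ...)
    rid <- sprintf("rec%02d", i)
    sim <- simulate_recording(cfg, record_id = rid)
    write_signal_table(sim$recording, file.path(out_dir, paste0(rid, ".csv")))
    write_annotation_table(sim$annotations,
                           file.path(out_dir, paste0(rid, "_ann.csv")))
    truth[[i]] <- sim$truth
    records[[i]] <- data.frame(
      record_id = rid,
      status = if (any(sim$truth$label == "anomalous")) "anomalous"
               else "normal",
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, records),
                   file.path(out_dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(truth)
}

#' Simulate a labeled segment dataset in memory
#'
#' Convenience composition of [simulate_recording()] and
#' [build_segment_dataset()] over several records: a clean block and a
#' PVC-carrying block, as in [make_benchmark()] but without touching disk.
#'
#' @inheritParams make_benchmark
#' @return A [segment_dataset()].
#' @export
simulate_dataset <- function(n_records = 4L, n_clean = n_records %/% 2L,
                             duration_s = 300, pvc_rate = 0.3, seed = 1L,
                             ...) {
  parts <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    clean <- i <= n_clean
    cfg <- synthetic_config(
      duration_s = duration_s,
      anomalies = default_anomalies(v_rate = if (clean) 0 else pvc_rate),
      seed = seed + i, ...)
    sim <- simulate_recording(cfg, record_id = sprintf("rec%02d", i))
    parts[[i]] <- suppressMessages(
      build_segment_dataset(sim$recording, sim$annotations))
  }
  bind_segments(parts)
}
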