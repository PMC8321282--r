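# Shared in-code fixtures: tiny recordings, datasets and model configs kept
# deliberately small so unit tests stay fast; realistic scales live only in
# the acceptance tests.

# recording with a known deterministic ramp on each lead
make_ramp_recording <- function(n = 720, leads = c("MLII", "V5"),
                                record_id = "ramp", sampling_rate = 360) {
  mat <- sapply(seq_along(leads), function(j) {
    as.integer(1000 + ((seq_len(n) + 13L * j) %% 60L))
  })
  colnames(mat) <- leads
  ecg_recording(mat, sampling_rate = sampling_rate, record_id = record_id)
}

# labeled dataset with dummy waveforms: class is encoded in the amplitude so
# even a tiny network can separate it
make_toy_dataset <- function(n_normal, n_anomalous, seg_len = 360,
                             n_records = 4, seed = 1) {
  n <- n_normal + n_anomalous
  label <- c(rep("normal", n_normal), rep("anomalous", n_anomalous))
  set.seed(seed)
  t_grid <- seq_len(seg_len) / seg_len
  samples <- t(vapply(seq_len(n), function(i) {
    base <- if (label[i] == "normal") {
      0.3 * sin(2 * pi * 5 * t_grid)
    } else {
      1.8 * sin(2 * pi * 5 * t_grid) * (t_grid %% 0.2 < 0.05)
    }
    millivolts_to_adc(base + rnorm(seg_len, 0, 0.05))
  }, numeric(seg_len)))
  rec_of <- rep_len(sprintf("r%02d", seq_len(n_records)), n)
  seg_ix <- stats::ave(seq_len(n), rec_of, FUN = seq_along) - 1L
  segment_dataset(samples, label, rec_of, seg_ix, seg_len = seg_len)
}

# small but real architecture for fast end-to-end training tests
tiny_model_config <- function(seg_len = 360) {
  model_config(input_length = seg_len,
               blocks = list(conv_block_spec(16L, 4L, 8L, 2L),
                             conv_block_spec(4L, 1L, 8L, 2L)),
               avg_pool_size = 2L, dropout_rate = 0.3)
}
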