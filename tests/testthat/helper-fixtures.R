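# Shared in-code fixtures: all synthetic, built at test time.

# A small simulated cohort of recordings plus their true label sequences.
make_closure_cohort <- function(n_subjects, duration_s, seed = 11,
                                snr = 2, mean_dwell_ms = 70, rate = 256) {
  truth <- ground_truth(snr = snr, mean_dwell_ms = mean_dwell_ms, seed = seed)
  seqs <- recs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    seqs[[i]] <- simulate_state_sequence(truth, duration_s, rate,
                                         seed = seed * 1000 + i)
    recs[[i]] <- synthesize_recording(truth, seqs[[i]], rate,
                                      seed = seed * 1000 + 500 + i)
  }
  names(recs) <- sprintf("S%02d", seq_len(n_subjects))
  list(truth = truth, sequences = seqs, recordings = recs)
}

# Sinusoidal single-channel-pattern recording for filter tests.
make_sine_recording <- function(freq_hz, rate = 256, duration_s = 4,
                                n_channels = 4, amplitude = 10) {
  t_s <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  wave <- amplitude * sin(2 * pi * freq_hz * t_s)
  data <- matrix(rep(wave, each = n_channels), nrow = n_channels)
  data <- data * (1 + 0.1 * seq_len(n_channels))  # distinct gains per channel
  ms_recording(data, rate = rate,
               channel_names = paste0("Ch", seq_len(n_channels)))
}

# Mean per-subject metric table (long) for a list of true sequences.
mean_true_metrics <- function(seqs, rate = 256) {
  dplyr::bind_rows(lapply(seqs, function(s) {
    tidy(true_sequence_metrics(s, rate))
  })) |>
    dplyr::group_by(.data$metric, .data$class) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}
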