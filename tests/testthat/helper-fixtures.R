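# Small fixtures shared across test files. Everything is generated in code;
# sample rates are reduced where the assertion does not depend on them.

# a compact but fully featured config: 250 Hz keeps all components
# (5, 7, 10, 14, 12 Hz) far below Nyquist while trials stay light
tiny_config <- function(...) {
  defaults <- list(n_participants = 2, n_trials_per_condition = 4,
                   sample_rate = 250, noise_sd = 0.5, artifact_rate = 0,
                   seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# noise-free config with the nonlinearities disabled: the pipeline should
# recover the programmed suppression exactly
clean_config <- function(...) {
  defaults <- list(n_participants = 1, n_trials_per_condition = 1,
                   sample_rate = 250, noise_sd = 0, harmonic_gain = 0,
                   im_gain = 0, transient_amplitude = 0, artifact_rate = 0,
                   seed = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built single-waveform container (epoch starts at onset by default)
make_waveforms <- function(waves, sample_rate, onset_index, offset_index,
                           condition, participant = "P001") {
  structure(list(
    waveforms = waves, sample_rate = sample_rate,
    onset_index = as.integer(onset_index),
    offset_index = as.integer(offset_index),
    condition = condition, participant_id = participant,
    group_label = NA_character_, channels = "Oz"
  ), class = "ssvep_waveforms")
}

# pooled-style suppression tibble from a participant x time matrix
make_courses <- function(m, times) {
  ids <- sprintf("P%03d", seq_len(nrow(m)))
  tibble::tibble(
    participant = rep(ids, each = length(times)),
    time_s = rep(times, times = nrow(m)),
    ratio_db = as.vector(t(m))
  )
}

# independent brute-force DFT oracle (plain loop, no shared code path)
naive_coefficient <- function(x, f, fs) {
  acc <- 0 + 0i
  for (n in seq_along(x)) {
    acc <- acc + x[n] * exp(-2i * pi * f * (n - 1) / fs)
  }
  2 * acc / length(x)
}
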