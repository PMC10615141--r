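#' Exponentially reweighted suppressive weight
#'
#' The forward model's latent weight trajectory: constant at `w0` before
#' stimulus onset, then relaxing exponentially towards `w_inf` with time
#' constant `tau`, i.e. `w(t) = w0 + (w_inf - w0) * (1 - exp(-t / tau))`
#' for `t > 0`.
#'
#' @param t Time in seconds relative to stimulus onset (vectorised).
#' @param w0 Weight at onset.
#' @param w_inf Asymptotic weight.
#' @param tau Time constant in seconds (> 0).
#' @return Numeric vector of weights, same length as `t`.
#' @examples
#' suppression_weight(c(0, 1.5, Inf), w0 = 0.2, w_inf = 1, tau = 1.5)
#' @export
suppression_weight <- function(t, w0, w_inf, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  w <- w0 + (w_inf - w0) * (1 - exp(-pmax(t, 0) / tau))
  w[t <= 0] <- w0
  w
}

# Divisive gain applied to a tagged component when a competitor with drive
# `m` is present: g(t) = 1 / (1 + w(t) * m).
divisive_gain <- function(t, w0, w_inf, tau, m) {
  1 / (1 + suppression_weight(t, w0, w_inf, tau) * m)
}

asymptote_for <- function(cfg, mask_type) {
  switch(mask_type,
    monocular = cfg$w_inf_mon,
    dichoptic = cfg$w_inf_dich,
    abort(sprintf("Unknown mask type '%s'.", mask_type))
  )
}

#' Programmed suppression of the forward model, in dB
#'
#' The ground-truth quantity the analysis pipeline estimates:
#' `20 * log10(1 + w(t) * m)`, the dB ratio between the alone-condition
#' amplitude (gain 1) and the masked amplitude (gain `1/(1 + w(t) m)`).
#' When `window_s` is supplied, the gain is averaged over a centred
#' rectangular window first, matching the expectation of a sliding-window
#' amplitude estimate.
#'
#' @param cfg A [sim_config()].
#' @param t Window-centre times in seconds relative to onset.
#' @param mask_type `"monocular"` or `"dichoptic"`.
#' @param window_s Optional analysis window length in seconds.
#' @return Numeric vector of dB values.
#' @export
true_suppression_db <- function(cfg, t, mask_type = "monocular", window_s = NULL) {
  w_inf <- asymptote_for(cfg, mask_type)
  if (is.null(window_s)) {
    return(20 * log10(1 + suppression_weight(t, cfg$w0, w_inf, cfg$tau) * cfg$mask_drive))
  }
  dt <- 1 / cfg$sample_rate
  vapply(t, function(tc) {
    tt <- seq(tc - window_s / 2, tc + window_s / 2 - dt, by = dt)
    g <- divisive_gain(tt, cfg$w0, w_inf, cfg$tau, cfg$mask_drive)
    -20 * log10(mean(g))
  }, numeric(1))
}

# 1/f^beta noise, one column per realisation, unit marginal SD (in
# expectation). The DC bin is zeroed; amplitude gains are normalised so the
# integrated power equals that of unit white noise.
pink_noise <- function(n, k, beta) {
  w <- matrix(rnorm(n * k), n, k)
  if (beta == 0) return(w)
  j <- 0:(n - 1)
  f <- pmin(j, n - j)           # bin frequency in cycles per record
  gain <- c(0, f[-1]^(-beta / 2))
  gain <- gain / sqrt(mean(gain^2))
  x <- mvfft(mvfft(w) * gain, inverse = TRUE) / n
  Re(x)
}

epoch_geometry <- function(cfg) {
  fs <- cfg$sample_rate
  n_pre <- round(cfg$epoch_pre * fs)
  n_stim <- round(cfg$trial_duration * fs)
  n_post <- round(cfg$epoch_post * fs)
  list(
    n_samples = n_pre + n_stim + n_post,
    onset_index = n_pre + 1L,
    offset_index = n_pre + n_stim + 1L
  )
}

default_channel_names <- function(n) {
  base <- c("Oz", "POz", "O1", "O2")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("ch", seq_len(n - 4) + 4))
}

#' Draw participant-level forward-model parameters
#'
#' Samples the fundamental response amplitudes (independently for the two
#' tagged frequencies, truncated below at 10% of the mean) and the five
#' component phases for one participant, using the current RNG state.
#'
#' @param cfg A [sim_config()].
#' @return Named list with amplitudes `a1`, `a2` (uV) and phases `ph1`,
#'   `ph2`, `ph_h1`, `ph_h2`, `ph_im` (rad).
#' @export
draw_participant_params <- function(cfg) {
  a <- rnorm(2, cfg$response_amplitude_mean, cfg$response_amplitude_sd)
  a <- pmax(a, 0.1 * cfg$response_amplitude_mean)
  ph <- runif(5, 0, 2 * pi)
  list(a1 = a[1], a2 = a[2],
       ph1 = ph[1], ph2 = ph[2], ph_h1 = ph[3], ph_h2 = ph[4], ph_im = ph[5])
}

# Deterministic (noise-free) epoch signal for one condition: fundamentals,
# second harmonics, intermodulation term, divisive gain trajectory and the
# multiplicative onset transient. Returns a length-n_samples vector.
condition_signal <- function(cfg, condition, pars) {
  geo <- epoch_geometry(cfg)
  fs <- cfg$sample_rate
  t <- (seq_len(geo$n_samples) - geo$onset_index) / fs
  stim <- t >= 0 & t < cfg$trial_duration
  env <- ifelse(stim, 1 + cfg$transient_amplitude * exp(-pmax(t, 0) / cfg$transient_decay), 0)

  has_f1 <- condition %in% c("alone_f1", "plaid_mon", "plaid_dich")
  has_f2 <- condition %in% c("alone_f2", "plaid_mon", "plaid_dich")
  plaid <- condition %in% c("plaid_mon", "plaid_dich")
  if (!condition %in% ssvep_conditions()) {
    abort(sprintf("Unknown condition label '%s'.", condition))
  }
  mask_type <- if (condition == "plaid_dich") "dichoptic" else "monocular"
  g <- if (plaid) {
    divisive_gain(t, cfg$w0, asymptote_for(cfg, mask_type), cfg$tau, cfg$mask_drive)
  } else {
    rep(1, length(t))
  }

  sig <- numeric(geo$n_samples)
  add_comp <- function(sig, amp, f, phase) {
    sig + amp * env * g * sin(2 * pi * f * t + phase)
  }
  if (has_f1) {
    sig <- add_comp(sig, pars$a1, cfg$f1, pars$ph1)
    sig <- add_comp(sig, cfg$harmonic_gain * pars$a1, 2 * cfg$f1, pars$ph_h1)
  }
  if (has_f2) {
    sig <- add_comp(sig, pars$a2, cfg$f2, pars$ph2)
    sig <- add_comp(sig, cfg$harmonic_gain * pars$a2, 2 * cfg$f2, pars$ph_h2)
  }
  if (plaid && cfg$im_gain > 0) {
    sig <- sig + cfg$im_gain * sqrt(pars$a1 * pars$a2) * env * g *
      sin(2 * pi * (cfg$f1 + cfg$f2) * t + pars$ph_im)
  }
  sig
}

# SD profile over the epoch: noise_sd during stimulation, elevated outside.
noise_profile <- function(cfg) {
  geo <- epoch_geometry(cfg)
  prof <- rep(cfg$noise_sd * cfg$iti_noise_multiplier, geo$n_samples)
  prof[geo$onset_index:(geo$offset_index - 1L)] <- cfg$noise_sd
  prof
}

#' Generate a single synthetic trial
#'
#' Builds one trial of the forward model (signal plus `1/f^beta` noise) for
#' a given condition, using the current RNG state. Mostly useful for
#' inspecting the model; [generate_participant()] and [generate_dataset()]
#' are the bulk interfaces.
#'
#' @param cfg A [sim_config()].
#' @param condition One of [ssvep_conditions()].
#' @param pars Participant parameters from [draw_participant_params()].
#' @return Numeric matrix, channels x samples (uV).
#' @export
generate_trial <- function(cfg, condition, pars) {
  sig <- condition_signal(cfg, condition, pars)
  geo <- epoch_geometry(cfg)
  prof <- noise_profile(cfg)
  noise <- pink_noise(geo$n_samples, cfg$n_channels, cfg$noise_exponent)
  out <- matrix(sig, cfg$n_channels, geo$n_samples, byrow = TRUE) +
    t(noise * prof)
  rownames(out) <- default_channel_names(cfg$n_channels)
  out
}

#' Generate all trials for one participant
#'
#' Draws participant-level amplitudes and phases, then simulates
#' `n_trials_per_condition` trials of each of the four conditions. A
#' fraction `artifact_rate` of trials is replaced by broadband artifacts
#' with 10 times the noise amplitude and no signal.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Identifier stored in the recording.
#' @param seed Integer seed for this participant's draws.
#' @param group_label Optional group label (e.g. `"high"`, `"autistic"`).
#' @return A list with `recording` (an [ssvep_epochs] object) and
#'   `ground_truth` (participant parameters plus artifact trial indices).
#' @export
generate_participant <- function(cfg, participant_id, seed, group_label = NA_character_) {
  set.seed(seed)
  pars <- draw_participant_params(cfg)
  geo <- epoch_geometry(cfg)
  conds <- rep(ssvep_conditions(), each = cfg$n_trials_per_condition)
  n_trials <- length(conds)
  artifact <- runif(n_trials) < cfg$artifact_rate
  prof <- noise_profile(cfg)

  data <- array(0, dim = c(n_trials, cfg$n_channels, geo$n_samples))
  for (cond in ssvep_conditions()) {
    idx <- which(conds == cond)
    sig <- condition_signal(cfg, cond, pars)
    for (ch in seq_len(cfg$n_channels)) {
      noise <- pink_noise(geo$n_samples, length(idx), cfg$noise_exponent) * prof
      data[idx, ch, ] <- t(noise) + matrix(sig, length(idx), geo$n_samples, byrow = TRUE)
    }
  }
  for (i in which(artifact)) {
    data[i, , ] <- matrix(rnorm(cfg$n_channels * geo$n_samples,
                                sd = 10 * cfg$noise_sd),
                          cfg$n_channels, geo$n_samples)
  }

  rec <- ssvep_epochs(
    data = data, sample_rate = cfg$sample_rate,
    onset_index = geo$onset_index, offset_index = geo$offset_index,
    condition = conds, channel_names = default_channel_names(cfg$n_channels),
    participant_id = participant_id, group_label = group_label
  )
  gt <- list(
    participant_id = participant_id,
    params = pars,
    artifact_trials = tibble(
      participant = participant_id,
      trial = which(artifact),
      condition = conds[artifact]
    )
  )
  list(recording = rec, ground_truth = gt)
}

#' Generate a full synthetic SSVEP dataset
#'
#' Simulates `n_participants` epoched recordings from the dynamic
#' normalization forward model, reproducibly from `cfg$seed`, together with
#' the ground truth needed to validate the analysis pipeline.
#'
#' @param cfg A [sim_config()].
#' @param group_labels Optional character vector (length `n_participants`)
#'   of group labels attached to the recordings.
#' @return An object of class `ssvep_dataset`: a list with `recordings`
#'   (list of [ssvep_epochs]) and `ground_truth`, which holds the config,
#'   per-participant amplitudes/phases, artifact trial flags, and the true
#'   asymptotic suppression in dB per mask type.
#' @examples
#' ds <- generate_dataset(sim_config(n_participants = 2,
#'                                   n_trials_per_condition = 2,
#'                                   sample_rate = 250, seed = 7))
#' length(ds$recordings)
#' @export
generate_dataset <- function(cfg, group_labels = NULL) {
  validate_sim_config(cfg)
  if (is.null(group_labels)) {
    group_labels <- rep(NA_character_, cfg$n_participants)
  }
  stopifnot(length(group_labels) == cfg$n_participants)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  sims <- purrr::map(seq_len(cfg$n_participants), function(i) {
    generate_participant(cfg, ids[i], seeds[i], group_labels[i])
  })
  params <- purrr::map_dfr(sims, function(s) {
    p <- s$ground_truth$params
    tibble(
      participant = s$ground_truth$participant_id,
      frequency_hz = c(cfg$f1, cfg$f2),
      amplitude = c(p$a1, p$a2),
      phase = c(p$ph1, p$ph2)
    )
  })
  structure(list(
    recordings = purrr::map(sims, "recording"),
    ground_truth = list(
      config = cfg,
      participants = params,
      artifact_trials = purrr::map_dfr(sims, ~ .x$ground_truth$artifact_trials),
      asymptotic_db = tibble(
        mask_type = c("monocular", "dichoptic"),
        db = 20 * log10(1 + c(cfg$w_inf_mon, cfg$w_inf_dich) * cfg$mask_drive)
      ),
      tau = cfg$tau
    )
  ), class = "ssvep_dataset")
}

#' @export
print.ssvep_dataset <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf("<ssvep_dataset> %d participants x %d trials x 4 conditions (%d flagged artifacts)\n",
              length(x$recordings), cfg$n_trials_per_condition,
              nrow(x$ground_truth$artifact_trials)))
  invisible(x)
}
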