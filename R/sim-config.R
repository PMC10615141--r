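#' Simulation configuration for the synthetic SSVEP generator
#'
#' Bundles every knob of the dynamic-normalization forward model used by
#' [generate_dataset()]. Defaults mirror a two-frequency dichoptic masking
#' experiment: 5 and 7 Hz sinusoidal on/off flicker, 6-s trials with a 3-s
#' inter-trial interval, 48 repetitions of each of four conditions
#' (`alone_f1`, `alone_f2`, `plaid_mon`, `plaid_dich`), sampled at 1 kHz.
#'
#' Suppression is divisive: each tagged component's amplitude is scaled by
#' `g(t) = 1 / (1 + w(t) * m)` where `m` is the competing component's drive
#' (0 in the `alone` conditions, `mask_drive` in the plaid conditions) and
#' the suppressive weight follows a single exponential
#' `w(t) = w0 + (w_inf - w0) * (1 - exp(-t / tau))` from stimulus onset,
#' with a separate asymptote per mask type. The true suppression in dB is
#' therefore `20 * log10(1 + w(t) * m)`.
#'
#' @param f1,f2 Flicker frequencies in Hz. Each must complete an integer
#'   number of cycles in 1 s so that a 1-s analysis window is an exact bin.
#' @param sample_rate Sampling rate in Hz.
#' @param trial_duration Stimulation duration in seconds.
#' @param iti_duration Inter-trial interval in seconds (context only; epochs
#'   are padded by `epoch_pre`/`epoch_post`).
#' @param epoch_pre,epoch_post Seconds of epoch retained before onset and
#'   after offset.
#' @param n_participants Number of simulated participants.
#' @param n_trials_per_condition Trials per condition per participant.
#' @param response_amplitude_mean,response_amplitude_sd Mean and SD (in uV,
#'   across participants) of the fundamental response amplitude drawn
#'   independently per participant and tagged frequency (truncated at 10% of
#'   the mean to keep amplitudes positive).
#' @param w0 Initial suppressive weight (dimensionless).
#' @param w_inf_mon,w_inf_dich Asymptotic suppressive weights for monocular
#'   and dichoptic mask arrangements.
#' @param tau Reweighting time constant in seconds (> 0).
#' @param mask_drive Drive `m` of the competing component in plaid
#'   conditions.
#' @param harmonic_gain Second-harmonic amplitude as a fraction of the
#'   fundamental.
#' @param im_gain Amplitude of the sum intermodulation component at
#'   `f1 + f2` (plaid conditions only) as a fraction of the geometric-mean
#'   fundamental amplitude.
#' @param noise_exponent Spectral exponent `beta` of the additive
#'   `1/f^beta` noise.
#' @param noise_sd Noise standard deviation in uV during stimulation.
#' @param iti_noise_multiplier Factor (>= 1) applied to the noise SD outside
#'   the stimulation period, emulating elevated broadband activity between
#'   trials.
#' @param transient_amplitude Peak fractional amplitude boost of the
#'   multiplicative onset transient (0 disables it).
#' @param transient_decay Decay time constant of the onset transient in
#'   seconds.
#' @param artifact_rate Fraction of trials replaced by large-amplitude
#'   broadband artifacts (10 times the noise SD), in `[0, 1)`.
#' @param n_channels Number of recorded channels. The first four channel
#'   names are `Oz`, `POz`, `O1`, `O2`; all channels share the same signal
#'   and receive independent noise.
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_participants = 2, n_trials_per_condition = 4,
#'                   sample_rate = 250, seed = 1)
#' cfg$f1
#' @export
sim_config <- function(f1 = 5,
                       f2 = 7,
                       sample_rate = 1000,
                       trial_duration = 6,
                       iti_duration = 3,
                       epoch_pre = 1.5,
                       epoch_post = 1.5,
                       n_participants = 10,
                       n_trials_per_condition = 48,
                       response_amplitude_mean = 2,
                       response_amplitude_sd = 0.5,
                       w0 = 0.05,
                       w_inf_mon = 0.1885,
                       w_inf_dich = 0.30,
                       tau = 1.5,
                       mask_drive = 1,
                       harmonic_gain = 0.25,
                       im_gain = 0.2,
                       noise_exponent = 1,
                       noise_sd = 1,
                       iti_noise_multiplier = 2,
                       transient_amplitude = 0.5,
                       transient_decay = 0.5,
                       artifact_rate = 0.02,
                       n_channels = 1,
                       seed = 1L) {
  cfg <- list(
    f1 = f1, f2 = f2, sample_rate = sample_rate,
    trial_duration = trial_duration, iti_duration = iti_duration,
    epoch_pre = epoch_pre, epoch_post = epoch_post,
    n_participants = as.integer(n_participants),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    response_amplitude_mean = response_amplitude_mean,
    response_amplitude_sd = response_amplitude_sd,
    w0 = w0, w_inf_mon = w_inf_mon, w_inf_dich = w_inf_dich,
    tau = tau, mask_drive = mask_drive,
    harmonic_gain = harmonic_gain, im_gain = im_gain,
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    iti_noise_multiplier = iti_noise_multiplier,
    transient_amplitude = transient_amplitude,
    transient_decay = transient_decay,
    artifact_rate = artifact_rate,
    n_channels = as.integer(n_channels),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$f1 == cfg$f2) abort("`f1` and `f2` must differ.")
  for (f in c(cfg$f1, cfg$f2)) {
    if (abs(f - round(f)) > 1e-9) {
      abort("Flicker frequencies must complete an integer number of cycles in 1 s.")
    }
  }
  if (cfg$tau <= 0) abort("`tau` must be > 0.")
  durs <- c(cfg$trial_duration, cfg$iti_duration, cfg$epoch_pre,
            cfg$epoch_post, cfg$sample_rate)
  if (any(durs <= 0)) abort("Durations and sample rate must be positive.")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate >= 1) {
    abort("`artifact_rate` must lie in [0, 1).")
  }
  if (cfg$iti_noise_multiplier < 1) abort("`iti_noise_multiplier` must be >= 1.")
  if (cfg$n_channels < 1) abort("`n_channels` must be >= 1.")
  nyq <- cfg$sample_rate / 2
  if (max(2 * cfg$f1, 2 * cfg$f2, cfg$f1 + cfg$f2) >= nyq) {
    abort("Sample rate too low: harmonics and intermodulation must lie below Nyquist.")
  }
  if (cfg$n_participants < 1 || cfg$n_trials_per_condition < 1) {
    abort("Participant and trial counts must be >= 1.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  tagging: %g Hz / %g Hz @ %g Hz sampling\n", x$f1, x$f2, x$sample_rate))
  cat(sprintf("  trial: %g s stim, epoch -%g..+%g s, %d trials x 4 conditions x %d participants\n",
              x$trial_duration, x$epoch_pre, x$epoch_post,
              x$n_trials_per_condition, x$n_participants))
  cat(sprintf("  reweighting: w0 = %g -> mon %g / dich %g, tau = %g s\n",
              x$w0, x$w_inf_mon, x$w_inf_dich, x$tau))
  cat(sprintf("  noise: 1/f^%g, sd %g uV (x%g in ITI), artifacts %g%%\n",
              x$noise_exponent, x$noise_sd, x$iti_noise_multiplier,
              100 * x$artifact_rate))
  invisible(x)
}

#' Condition labels recognised by the generator and pipeline
#' @return Character vector of the four condition labels.
#' @export
ssvep_conditions <- function() {
  c("alone_f1", "alone_f2", "plaid_mon", "plaid_dich")
}
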