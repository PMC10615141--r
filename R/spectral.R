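#' Exact-frequency Fourier coefficient of a segment
#'
#' Computes `(2/N) * sum(s[n] * exp(-i 2 pi f n / fs))` over a waveform
#' segment, so that the modulus equals a sinusoid's amplitude whenever the
#' segment spans an integer number of cycles of `f` (an "on-bin"
#' frequency).
#'
#' @param segment Numeric vector of samples (uV).
#' @param f Analysis frequency in Hz (must be below Nyquist).
#' @param sample_rate Sampling rate in Hz.
#' @return A single complex coefficient.
#' @examples
#' x <- 2 * sin(2 * pi * 5 * (0:999) / 1000)
#' Mod(fourier_coefficient(x, 5, 1000))
#' @export
fourier_coefficient <- function(segment, f, sample_rate) {
  if (length(segment) < 2) abort("Segment must contain at least 2 samples.")
  if (f >= sample_rate / 2) {
    abort(sprintf("Frequency %g Hz is at or above Nyquist (%g Hz).",
                  f, sample_rate / 2))
  }
  n <- seq_along(segment) - 1
  (2 / length(segment)) * sum(segment * exp(-2i * pi * f * n / sample_rate))
}

#' Coherent (phase-locked) average across trials
#'
#' Pointwise mean of the trial waveforms within each condition, preserving
#' phase-locked components and attenuating non-phase-locked noise by about
#' `1/sqrt(K)` for `K` trials.
#'
#' @param x An `ssvep_waveforms` object (see [average_channels()]) or a
#'   trials x samples numeric matrix.
#' @return For `ssvep_waveforms` input, an `ssvep_waveforms` object with
#'   one waveform per condition (attribute `n_trials` records the trial
#'   counts); for a matrix, a numeric vector.
#' @export
coherent_average <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 1) abort("Need at least one trial to average.")
    return(colMeans(x))
  }
  if (!inherits(x, "ssvep_waveforms")) {
    abort("`x` must be an `ssvep_waveforms` object or a matrix.")
  }
  if (nrow(x$waveforms) < 1) abort("Need at least one trial to average.")
  conds <- unique(x$condition)
  avg <- t(vapply(conds, function(cc) {
    colMeans(x$waveforms[x$condition == cc, , drop = FALSE])
  }, numeric(ncol(x$waveforms))))
  out <- x
  out$waveforms <- avg
  out$condition <- conds
  attr(out, "n_trials") <- as.integer(table(factor(x$condition, levels = conds)))
  out
}

# Window geometry shared by the sliding analyses. Returns centre times
# (s, relative to onset) and 1-based window start samples for a half-open
# window [t_c - window/2, t_c + window/2). Edge windows that would leave
# the epoch are dropped.
window_grid <- function(n_samples, sample_rate, onset_index, window_s, step_s) {
  wlen <- round(window_s * sample_rate)
  if (wlen > n_samples) abort("Analysis window is longer than the epoch.")
  if (wlen < 2) abort("Analysis window must contain at least 2 samples.")
  step <- round(step_s * sample_rate)
  if (step < 1) abort("`step_s` must be at least one sample.")
  half <- wlen %/% 2
  # centres on the step grid: c = onset + k * step
  k_min <- ceiling((1 + half - onset_index) / step)
  k_max <- floor((n_samples - (wlen - half) + 1 - onset_index) / step)
  if (k_max < k_min) abort("No analysis window fits inside the epoch.")
  k <- k_min:k_max
  centers <- onset_index + k * step
  list(wlen = wlen, starts = centers - half,
       times = k * step / sample_rate)
}

# Complex coefficients for all windows of one waveform, phase-referenced to
# absolute epoch time (t = 0 at onset): rows = windows.
window_coefficients <- function(wave, f, sample_rate, grid, onset_index) {
  n <- 0:(grid$wlen - 1)
  basis <- exp(-2i * pi * f * n / sample_rate)
  idx <- outer(grid$starts, n, "+")
  seg <- matrix(wave[idx], nrow = length(grid$starts))
  coef <- (2 / grid$wlen) * as.vector(seg %*% basis)
  t_start <- (grid$starts - onset_index) / sample_rate
  coef * exp(-2i * pi * f * t_start)
}

check_window_frequency <- function(f, window_s) {
  if (abs(f * window_s - round(f * window_s)) > 1e-9) {
    warn(sprintf(
      "f * window_s = %g is not an integer: %g Hz is off-bin for a %g-s window and will leak.",
      f * window_s, f, window_s))
  }
}

#' Sliding-window amplitude time course
#'
#' For each window centre on the step grid, the modulus of the
#' exact-frequency Fourier coefficient over a centred rectangular window
#' (default 1 s, for which integer frequencies are exact bins). Windows
#' extending beyond the epoch are dropped.
#'
#' @param avg An `ssvep_waveforms` object, typically the per-condition
#'   [coherent_average()].
#' @param freqs Analysis frequencies in Hz.
#' @param window_s Window length in seconds (default 1).
#' @param step_s Step between window centres in seconds (default 0.01).
#' @return A tibble with columns `participant`, `condition`,
#'   `frequency_hz`, `time_s` (window centre, s from onset), `amplitude`
#'   (uV).
#' @export
sliding_timecourse <- function(avg, freqs, window_s = 1, step_s = 0.01) {
  stopifnot(inherits(avg, "ssvep_waveforms"))
  grid <- window_grid(ncol(avg$waveforms), avg$sample_rate, avg$onset_index,
                      window_s, step_s)
  for (f in freqs) {
    if (f >= avg$sample_rate / 2) {
      abort(sprintf("Frequency %g Hz is at or above Nyquist.", f))
    }
    check_window_frequency(f, window_s)
  }
  n <- 0:(grid$wlen - 1)
  basis <- vapply(freqs, function(f) exp(-2i * pi * f * n / avg$sample_rate),
                  complex(grid$wlen))
  idx <- outer(grid$starts, n, "+")
  nc <- length(grid$times)
  purrr::map_dfr(seq_len(nrow(avg$waveforms)), function(i) {
    seg <- matrix(avg$waveforms[i, ][idx], nrow = nc)
    amp <- Mod((2 / grid$wlen) * seg %*% basis)
    tibble(
      participant = avg$participant_id,
      condition = avg$condition[i],
      frequency_hz = rep(freqs, each = nc),
      time_s = rep(grid$times, times = length(freqs)),
      amplitude = as.vector(amp)
    )
  })
}

#' Estimate a frequency's phase from the whole-trial coefficient
#'
#' Returns the phase `phi` such that the stimulation-period waveform is
#' best described by `A * sin(2 pi f t + phi)` with `t` in seconds from
#' onset.
#'
#' @param avg An `ssvep_waveforms` object (one waveform per condition).
#' @param f Frequency in Hz.
#' @param condition Condition whose waveform to use (default: first).
#' @return Phase in radians.
#' @export
estimate_phase <- function(avg, f, condition = avg$condition[1]) {
  i <- match(condition, avg$condition)
  if (is.na(i)) abort(sprintf("No waveform for condition '%s'.", condition))
  seg <- avg$waveforms[i, avg$onset_index:(avg$offset_index - 1L)]
  coef <- fourier_coefficient(seg, f, avg$sample_rate)
  Arg(coef) + pi / 2
}

#' Fixed-phase amplitude time course
#'
#' Alternative to [sliding_timecourse()] in which each window's signal is
#' projected onto a sine of fixed frequency and phase (in absolute epoch
#' time) rather than taking the modulus of the complex coefficient:
#' `(2/N) * sum(s(t) * sin(2 pi f t + phase))`. For a phase-locked signal
#' whose phase matches, this equals the modulus-based course; signals in
#' quadrature project to zero.
#'
#' @inheritParams sliding_timecourse
#' @param f Analysis frequency in Hz.
#' @param phase Projection phase in radians; if `NULL`, estimated once per
#'   condition from the whole-trial coefficient via [estimate_phase()].
#' @return A tibble like [sliding_timecourse()]'s (the `amplitude` column
#'   is signed).
#' @export
fixed_phase_timecourse <- function(avg, f, phase = NULL, window_s = 1,
                                   step_s = 0.01) {
  stopifnot(inherits(avg, "ssvep_waveforms"))
  if (f >= avg$sample_rate / 2) abort("Frequency is at or above Nyquist.")
  check_window_frequency(f, window_s)
  grid <- window_grid(ncol(avg$waveforms), avg$sample_rate, avg$onset_index,
                      window_s, step_s)
  purrr::map_dfr(seq_len(nrow(avg$waveforms)), function(i) {
    ph <- phase %||% estimate_phase(avg, f, avg$condition[i])
    coef <- window_coefficients(avg$waveforms[i, ], f, avg$sample_rate,
                                grid, avg$onset_index)
    # (2/N) sum s sin(wt + ph) = Im(exp(i ph) * Conj(coef))
    tibble(
      participant = avg$participant_id,
      condition = avg$condition[i],
      frequency_hz = f,
      time_s = grid$times,
      amplitude = Im(exp(1i * ph) * Conj(coef))
    )
  })
}

#' Amplitude spectrum of the stimulation period
#'
#' Modulus of the DFT of the whole stimulation-period waveform (resolution
#' `1/duration` Hz), scaled as `2 |X| / N` so an on-bin sinusoid of
#' amplitude `A` appears as a peak of height `A`.
#'
#' @param avg An `ssvep_waveforms` object.
#' @param fmax Highest frequency to return (Hz).
#' @return A tibble with `participant`, `condition`, `frequency_hz`,
#'   `amplitude`.
#' @export
full_trial_spectrum <- function(avg, fmax = 40) {
  stopifnot(inherits(avg, "ssvep_waveforms"))
  idx <- avg$onset_index:(avg$offset_index - 1L)
  n <- length(idx)
  freqs <- (seq_len(n) - 1) * avg$sample_rate / n
  keep <- freqs > 0 & freqs <= fmax
  purrr::map_dfr(seq_len(nrow(avg$waveforms)), function(i) {
    amp <- 2 * Mod(fft(avg$waveforms[i, idx])) / n
    tibble(
      participant = avg$participant_id,
      condition = avg$condition[i],
      frequency_hz = freqs[keep],
      amplitude = amp[keep]
    )
  })
}

#' Cubic smoothing spline for display
#'
#' Smooths a time-course tibble with [stats::smooth.spline()], evaluated on
#' the input grid, separately within each participant x condition x
#' frequency (x mask type) group. The result is flagged as smoothed and is
#' rejected by every statistical routine in the package; it exists for
#' plotting only.
#'
#' @param tc A time-course tibble (from [sliding_timecourse()],
#'   [suppression_ratio()], ...). Numeric value columns among `amplitude`,
#'   `ratio`, `ratio_db`, `im_index` are smoothed.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (`NULL` for generalised cross-validation).
#' @return A tibble like `tc`, with attribute `smoothed = TRUE`.
#' @export
spline_smooth <- function(tc, spar = NULL) {
  value_cols <- intersect(c("amplitude", "ratio", "ratio_db", "im_index"),
                          names(tc))
  if (!length(value_cols)) abort("No smoothable value column found.")
  group_cols <- intersect(c("participant", "condition", "frequency_hz",
                            "mask_type"), names(tc))
  smooth_one <- function(df) {
    if (nrow(df) < 4) abort("Spline smoothing needs at least 4 time points.")
    for (vc in value_cols) {
      y <- df[[vc]]
      fit <- if (is.null(spar)) {
        smooth.spline(df$time_s, y)
      } else {
        smooth.spline(df$time_s, y, spar = spar)
      }
      df[[vc]] <- predict(fit, df$time_s)$y
    }
    df
  }
  out <- tc |>
    group_by(across(all_of(group_cols))) |>
    dplyr::group_modify(~ smooth_one(.x)) |>
    ungroup()
  attr(out, "smoothed") <- TRUE
  out
}

# Statistical routines call this to honour the display-only contract.
assert_unsmoothed <- function(tc, what) {
  if (isTRUE(attr(tc, "smoothed"))) {
    abort(sprintf("%s requires unsmoothed time courses; got spline-smoothed input.",
                  what))
  }
  invisible(tc)
}

#' Per-trial complex coefficients over the stimulation period
#'
#' One exact-frequency Fourier coefficient per trial and frequency,
#' computed on the full stimulation period (the basis for trial-level
#' outlier rejection).
#'
#' @param wf An `ssvep_waveforms` object (one waveform per trial).
#' @param freqs Frequencies in Hz (typically the two tagged fundamentals).
#' @return A tibble with `participant`, `trial`, `condition`,
#'   `frequency_hz`, `re`, `im`, `amplitude`, `phase`.
#' @export
trial_coefficients <- function(wf, freqs) {
  stopifnot(inherits(wf, "ssvep_waveforms"))
  idx <- wf$onset_index:(wf$offset_index - 1L)
  n <- length(idx)
  seg <- wf$waveforms[, idx, drop = FALSE]
  for (f in freqs) {
    if (f >= wf$sample_rate / 2) abort("Frequency is at or above Nyquist.")
  }
  basis <- vapply(freqs, function(f) {
    exp(-2i * pi * f * (seq_len(n) - 1) / wf$sample_rate)
  }, complex(n))
  coef <- as.vector((2 / n) * seg %*% basis)  # trials fastest, then freq
  tibble(
    participant = wf$participant_id,
    trial = rep(seq_len(nrow(seg)), times = length(freqs)),
    condition = rep(wf$condition, times = length(freqs)),
    frequency_hz = rep(freqs, each = nrow(seg)),
    re = Re(coef), im = Im(coef),
    amplitude = Mod(coef), phase = Arg(coef)
  )
}
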