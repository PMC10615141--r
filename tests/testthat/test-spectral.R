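test_that("exact-frequency coefficients recover on-bin sinusoid amplitudes", {
  fs <- 1000
  t <- (0:999) / fs
  expect_equal(Mod(fourier_coefficient(2 * sin(2 * pi * 5 * t), 5, fs)), 2,
               tolerance = 1e-12)
  expect_equal(Mod(fourier_coefficient(numeric(1000), 5, fs)), 0)
  # 5 Hz and 7 Hz are orthogonal over 1 s: the 7 Hz estimate ignores the 5 Hz tone
  mix <- 2 * sin(2 * pi * 5 * t + 0.4) + 1 * sin(2 * pi * 7 * t + 1.2)
  expect_equal(Mod(fourier_coefficient(mix, 7, fs)), 1, tolerance = 1e-12)
  expect_error(fourier_coefficient(mix, 500, fs), "Nyquist")
  expect_error(fourier_coefficient(c(1), 5, fs), "2 samples")
})

test_that("coherent averaging is the pointwise mean and suppresses noise as 1/sqrt(K)", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(coherent_average(m), c(1, 2, 3))
  expect_equal(coherent_average(rbind(c(1, -1), c(-1, 1))), c(0, 0))
  expect_error(coherent_average(m[0, , drop = FALSE]), "at least one")

  # 1/sqrt(K) law against white noise, checked by simulation
  set.seed(7)
  K <- 100
  n <- 2000
  signal <- sin(2 * pi * 5 * (0:(n - 1)) / 1000)
  trials <- matrix(signal, K, n, byrow = TRUE) + matrix(rnorm(K * n), K, n)
  resid <- coherent_average(trials) - signal
  expect_equal(stats::sd(resid), 1 / sqrt(K), tolerance = 0.1)
})

test_that("sliding windows track amplitude steps the way a direct DFT says they should", {
  fs <- 1000
  n <- 6000
  t <- (0:(n - 1)) / fs
  a <- 1; b <- 3; t0 <- 3
  wave <- ifelse(t < t0, a, b) * sin(2 * pi * 5 * t)
  wf <- make_waveforms(matrix(wave, 1), fs, 1, n + 1, "alone_f1")

  tc <- sliding_timecourse(wf, 5, window_s = 1, step_s = 0.01)
  # flat before and after the step once the window clears it
  expect_equal(tc$amplitude[tc$time_s == t0 - 0.5], a, tolerance = 1e-9)
  expect_equal(tc$amplitude[tc$time_s == t0 + 0.5], b, tolerance = 1e-9)
  # at the step, the window sees half of each amplitude
  expect_equal(tc$amplitude[tc$time_s == t0], (a + b) / 2, tolerance = 1e-9)
  # spot-check three centres against the brute-force oracle
  for (tc_time in c(2.8, 3.0, 3.3)) {
    seg <- wave[(tc_time * fs - 500 + 1):(tc_time * fs + 500)]
    expect_equal(tc$amplitude[abs(tc$time_s - tc_time) < 1e-9],
                 Mod(naive_coefficient(seg, 5, fs)), tolerance = 1e-9)
  }
  # constant-amplitude sinusoid: flat course, invariant to window phase
  wave2 <- 3 * sin(2 * pi * 5 * t + 0.9)
  wf2 <- make_waveforms(matrix(wave2, 1), fs, 1, n + 1, "alone_f1")
  tc2 <- sliding_timecourse(wf2, 5, step_s = 0.013)
  expect_lt(diff(range(tc2$amplitude)), 1e-10)
  expect_equal(mean(tc2$amplitude), 3, tolerance = 1e-12)

  expect_error(sliding_timecourse(wf, 5, window_s = 10), "longer than the epoch")
  expect_warning(sliding_timecourse(wf, 5.5, window_s = 1), "off-bin")
})

test_that("fixed-phase projection agrees with the modulus course when phases match", {
  fs <- 500
  n <- 4000
  t <- (0:(n - 1)) / fs
  phi <- 2.1317  # arbitrary signal phase
  wave <- 1.7 * sin(2 * pi * 7 * t + phi)
  wf <- make_waveforms(matrix(wave, 1), fs, 1, n + 1, "alone_f2")

  mod_tc <- sliding_timecourse(wf, 7, step_s = 0.02)
  fp_tc <- fixed_phase_timecourse(wf, 7, phase = phi, step_s = 0.02)
  expect_equal(fp_tc$amplitude, mod_tc$amplitude, tolerance = 1e-9)
  # quadrature projection vanishes
  quad <- fixed_phase_timecourse(wf, 7, phase = phi + pi / 2, step_s = 0.02)
  expect_lt(max(abs(quad$amplitude)), 1e-9)
  # estimating the phase from the whole trial reproduces the modulus course
  est <- fixed_phase_timecourse(wf, 7, phase = NULL, step_s = 0.02)
  expect_equal(est$amplitude, mod_tc$amplitude, tolerance = 1e-6)
  expect_equal(estimate_phase(wf, 7) %% (2 * pi), phi %% (2 * pi),
               tolerance = 1e-9)
})

test_that("stimulation-period spectra reflect the mean gain trajectory", {
  cfg <- clean_config(harmonic_gain = 0, im_gain = 0, w0 = 0.05,
                      w_inf_mon = 0.4, tau = 1.5)
  ds <- generate_dataset(cfg)
  avg <- coherent_average(average_channels(ds$recordings[[1]]))
  sp <- full_trial_spectrum(avg, fmax = 30)
  a1 <- ds$ground_truth$participants$amplitude[1]

  # alone condition: full amplitude at 5 Hz
  sp_alone <- dplyr::filter(sp, condition == "alone_f1")
  expect_equal(sp_alone$amplitude[sp_alone$frequency_hz == 5], a1,
               tolerance = 1e-6)
  # plaid condition: amplitude = a1 * mean over the trial of g(t)
  tt <- seq(0, cfg$trial_duration - 1 / cfg$sample_rate, by = 1 / cfg$sample_rate)
  g_mean <- mean(1 / (1 + suppression_weight(tt, 0.05, 0.4, 1.5)))
  sp_plaid <- dplyr::filter(sp, condition == "plaid_mon")
  expect_equal(sp_plaid$amplitude[sp_plaid$frequency_hz == 5], a1 * g_mean,
               tolerance = 0.01)
})

test_that("spline smoothing is display-only and near-exact on smooth inputs", {
  t <- seq(0, 5, by = 0.05)
  tc <- tibble::tibble(participant = "P001", condition = "alone_f1",
                       frequency_hz = 5, time_s = t,
                       amplitude = 2 + 0.3 * t - 0.04 * t^2)
  sm <- spline_smooth(tc)
  expect_equal(sm$amplitude, tc$amplitude, tolerance = 1e-3)
  expect_true(isTRUE(attr(sm, "smoothed")))

  const <- dplyr::mutate(tc, amplitude = 1.5)
  expect_equal(spline_smooth(const)$amplitude, const$amplitude,
               tolerance = 1e-9)

  expect_error(spline_smooth(tc[1:3, ]), "at least 4")

  # statistical operations refuse smoothed input
  sup <- tibble::tibble(participant = rep(c("a", "b", "c"), each = length(t)),
                        time_s = rep(t, 3), ratio_db = rnorm(3 * length(t)))
  attr(sup, "smoothed") <- TRUE
  expect_error(window_effect_size(sup), "unsmoothed")
  expect_error(trend_t_series(sup), "unsmoothed")
  expect_error(cluster_test_increase(sup), "unsmoothed")
})
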