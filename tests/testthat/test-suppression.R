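amp_course <- function(amps, times = seq(0, 5, 0.5), participant = "P001",
                       frequency = 5, condition = "alone_f1") {
  tibble::tibble(participant = participant, condition = condition,
                 frequency_hz = frequency, time_s = times, amplitude = amps)
}

test_that("suppression ratios follow the dB identities", {
  tt <- seq(0, 5, 0.5)
  a <- amp_course(rep(2, length(tt)))
  expect_equal(suppression_ratio(a, a)$ratio_db, rep(0, length(tt)))

  half <- amp_course(rep(1, length(tt)), condition = "plaid_mon")
  sr <- suppression_ratio(a, half, mask_type = "monocular")
  expect_equal(sr$ratio_db, rep(20 * log10(2), length(tt)), tolerance = 1e-12)
  expect_equal(sr$ratio, rep(2, length(tt)))

  # 1.122 uV over 1.0 uV is almost exactly +1 dB
  sr2 <- suppression_ratio(amp_course(rep(1.122, length(tt))),
                           amp_course(rep(1, length(tt))))
  expect_equal(sr2$ratio_db, rep(1, length(tt)), tolerance = 2e-4)

  # exact antisymmetry, including floored points
  set.seed(2)
  x <- amp_course(runif(length(tt), 0, 2))
  y <- amp_course(runif(length(tt), 0, 2))
  expect_equal(suppression_ratio(x, y)$ratio_db,
               -suppression_ratio(y, x)$ratio_db, tolerance = 1e-13)

  expect_error(suppression_ratio(a, half[-1, ]), "different lengths")
  b <- amp_course(rep(1, length(tt)), times = tt + 0.1)
  expect_error(suppression_ratio(a, b), "time grid")
})

test_that("pooling averages dB values and is order-invariant", {
  tt <- seq(0, 3, 0.5)
  mk <- function(db, f, mask) {
    tibble::tibble(participant = "P001", frequency_hz = f, mask_type = mask,
                   time_s = tt, ratio = 10^(db / 20), ratio_db = db)
  }
  s1 <- mk(rep(2, length(tt)), 5, "monocular")
  s2 <- mk(rep(0, length(tt)), 7, "monocular")
  pooled <- pool_timecourses(dplyr::bind_rows(s1, s2))
  expect_equal(pooled$ratio_db, rep(1, length(tt)))
  # identical courses pool to themselves
  same <- pool_timecourses(dplyr::bind_rows(s1, s1))
  expect_equal(same$ratio_db, s1$ratio_db)
  # order does not matter
  p2 <- pool_timecourses(dplyr::bind_rows(s2, s1))
  expect_equal(p2$ratio_db, pooled$ratio_db)
  # pooling only over frequency keeps mask_type
  pf <- pool_timecourses(dplyr::bind_rows(s1, s2), over = "frequency_hz")
  expect_true("mask_type" %in% names(pf))
  expect_error(pool_timecourses(s1[0, ]), "empty")
})

test_that("windowed Cohen's d matches hand computation and its symmetries", {
  tt <- seq(0, 4.5, 0.5)
  # three participants with early->late increases of 0.2, 0.4, 0.6 dB
  mk <- function(id, d) {
    tibble::tibble(participant = id, time_s = tt,
                   ratio_db = ifelse(tt < 2, 1, 1 + d))
  }
  sup <- dplyr::bind_rows(mk("a", 0.2), mk("b", 0.4), mk("c", 0.6))
  es <- window_effect_size(sup, early = c(0, 1), late = c(3, 4))
  # mean 0.4, sd 0.2 -> d = 2
  expect_equal(es$cohen_d, 2, tolerance = 1e-12)
  g <- glance(es)
  expect_equal(g$mean_diff_db, 0.4)
  expect_equal(g$sd_diff_db, 0.2)

  # sign flip of all courses negates d
  flipped <- dplyr::mutate(sup, ratio_db = -ratio_db)
  expect_equal(window_effect_size(flipped)$cohen_d, -2, tolerance = 1e-12)

  # all-zero differences hit the degenerate path
  flat <- dplyr::bind_rows(mk("a", 0), mk("b", 0), mk("c", 0))
  expect_error(window_effect_size(flat), class = "ssvep_degenerate_error")

  expect_error(window_effect_size(sup, early = c(0, 2), late = c(1, 3)),
               "overlap")
  expect_error(window_effect_size(mk("a", 0.2)), "2 participants")

  # pooled-SD flavour uses the window SDs
  es2 <- window_effect_size(sup, method = "pooled")
  expect_equal(es2$cohen_d,
               0.4 / sqrt((stats::var(c(1, 1, 1)) +
                           stats::var(c(1.2, 1.4, 1.6))) / 2))
})

test_that("pooling then effect size equals effect size of pooled courses", {
  set.seed(8)
  tt <- seq(0, 4.5, 0.25)
  rows <- purrr::map_dfr(sprintf("P%02d", 1:6), function(id) {
    purrr::map_dfr(c(5, 7), function(f) {
      purrr::map_dfr(c("monocular", "dichoptic"), function(m) {
        db <- 1.5 * (1 - exp(-tt / 1.5)) + rnorm(length(tt), sd = 0.1)
        tibble::tibble(participant = id, frequency_hz = f, mask_type = m,
                       time_s = tt, ratio = 10^(db / 20), ratio_db = db)
      })
    })
  })
  d_pooled <- window_effect_size(pool_timecourses(rows))$cohen_d
  # manual linear pooling of window means gives the same d
  per <- rows |>
    dplyr::mutate(win = dplyr::case_when(time_s >= 0 & time_s < 1 ~ "early",
                                         time_s >= 3 & time_s < 4 ~ "late")) |>
    dplyr::filter(!is.na(win)) |>
    dplyr::group_by(participant, win) |>
    dplyr::summarise(db = mean(ratio_db), .groups = "drop") |>
    tidyr::pivot_wider(names_from = win, values_from = db) |>
    dplyr::mutate(diff = late - early)
  expect_equal(d_pooled, mean(per$diff) / stats::sd(per$diff),
               tolerance = 1e-12)
})

test_that("intermodulation indices are proportional increases over baseline", {
  tt <- seq(0, 3, 0.5)
  mk <- function(cond, amps) amp_course(amps, times = tt, frequency = 12,
                                        condition = cond)
  tc <- dplyr::bind_rows(
    mk("alone_f1", rep(0.5, length(tt))),
    mk("alone_f2", rep(0.3, length(tt))),
    mk("plaid_mon", rep(0.4, length(tt))),   # equals baseline mean
    mk("plaid_dich", rep(0.8, length(tt)))   # twice baseline
  )
  im <- intermodulation_timecourse(tc, f_im = 12)
  expect_equal(im$im_index[im$condition == "plaid_mon"], rep(0, length(tt)))
  expect_equal(im$im_index[im$condition == "plaid_dich"], rep(1, length(tt)))
  expect_true(all(im$im_index >= -1))
  expect_error(intermodulation_timecourse(tc, f_im = 24), "No amplitude course")
})

test_that("simulated intermodulation appears during stimulation only", {
  cfg <- sim_config(n_participants = 2, n_trials_per_condition = 12,
                    sample_rate = 250, im_gain = 0.4, noise_sd = 0.4,
                    artifact_rate = 0, seed = 31)
  res <- analyze_dataset(generate_dataset(cfg), step_s = 0.1,
                         freqs = c(5, 7, 12))
  im <- res$intermodulation
  stim <- dplyr::filter(im, time_s > 0.5, time_s < 5.5)
  iti <- dplyr::filter(im, time_s < -0.7)
  expect_gt(mean(stim$im_index), 0.5)
  expect_lt(abs(mean(iti$im_index)), 0.4)
})

test_that("exponential fits recover programmed rise parameters on clean courses", {
  tt <- seq(0.5, 5.5, 0.05)
  db <- 0.2 + (1.5 - 0.2) * (1 - exp(-tt / 1.5))
  sup <- tibble::tibble(participant = "P001", time_s = tt, ratio_db = db)
  fit <- fit_reweighting(sup)
  g <- glance(fit)
  expect_equal(g$tau_s, 1.5, tolerance = 1e-6)
  expect_equal(g$asymptote_db, 1.5, tolerance = 1e-6)
  expect_equal(g$d0_db, 0.2, tolerance = 1e-6)
  expect_equal(nrow(tidy(fit)), 3)
})
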