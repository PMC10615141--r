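make_coeffs <- function(re, im, condition = "alone_f1", participant = "P001",
                        frequency = 5, trial = seq_along(re)) {
  tibble::tibble(participant = participant, trial = trial,
                 condition = condition, frequency_hz = frequency,
                 re = re, im = im,
                 amplitude = sqrt(re^2 + im^2), phase = atan2(im, re))
}

test_that("complex Mahalanobis distances behave geometrically", {
  # a trial sitting exactly at the sample mean has distance 0
  cf <- make_coeffs(re = c(1, 3, 2, 2, 2), im = c(1, 1, 0, 2, 1))
  d <- complex_mahalanobis(cf, 5)
  expect_equal(d$distance[5], 0, tolerance = 1e-12)
  expect_true(all(d$distance >= 0))

  # invariance to a common affine map of the complex plane
  set.seed(3)
  cf2 <- make_coeffs(re = rnorm(40), im = rnorm(40, sd = 2))
  z <- complex(real = cf2$re, imaginary = cf2$im)
  zt <- (1.7 - 2.3i) * z + (4 + 5i)  # rotation + scaling + offset
  cf2t <- make_coeffs(re = Re(zt), im = Im(zt))
  expect_equal(complex_mahalanobis(cf2t, 5)$distance,
               complex_mahalanobis(cf2, 5)$distance, tolerance = 1e-8)

  # condition-local: perturbing another condition leaves distances alone
  other <- make_coeffs(re = rnorm(10), im = rnorm(10),
                       condition = "plaid_mon", trial = 41:50)
  d_before <- complex_mahalanobis(dplyr::bind_rows(cf2, other), 5)
  other2 <- dplyr::mutate(other, re = re * 100 + 7)
  d_after <- complex_mahalanobis(dplyr::bind_rows(cf2, other2), 5)
  sel <- d_before$condition == "alone_f1"
  expect_equal(d_after$distance[sel], d_before$distance[sel])

  expect_error(complex_mahalanobis(cf, 9), "No coefficients")
  expect_error(complex_mahalanobis(cf[1:2, ], 5), "at least 3")
})

test_that("threshold-3 exclusion matches the chi-square tail on Gaussian trials", {
  set.seed(11)
  n <- 20000
  cf <- make_coeffs(re = rnorm(n, 3, 0.7), im = rnorm(n, -1, 1.4))
  frac <- mean(complex_mahalanobis(cf, 5)$distance > 3)
  expect_equal(frac, exp(-4.5), tolerance = 0.3)  # 0.011 +/- ~30%
})

test_that("outlier rejection flags injected artifacts and spares clean trials", {
  cfg <- sim_config(n_participants = 1, n_trials_per_condition = 60,
                    sample_rate = 250, artifact_rate = 0.05, seed = 21)
  ds <- generate_dataset(cfg)
  wf <- average_channels(ds$recordings[[1]])
  res <- reject_outliers(wf, freqs = c(5, 7), threshold = 3)

  truth <- ds$ground_truth$artifact_trials$trial
  expect_gt(length(truth), 3)
  flagged <- dplyr::filter(res$report, excluded) |> dplyr::pull(trial) |> unique()
  expect_gte(mean(truth %in% flagged), 0.95)
  clean_fpr <- mean(setdiff(seq_len(240), truth) %in% flagged)
  expect_lte(clean_fpr, 0.03)
  # retained trials keep their original order
  expect_identical(res$waveforms$condition,
                   wf$condition[setdiff(seq_len(240), flagged)])
  g <- glance(res$report)
  expect_equal(g$n_trials, 240)
  expect_equal(g$exclusion_fraction, length(flagged) / 240)
})

test_that("degenerate and edge cases follow the documented contracts", {
  cfg <- tiny_config(n_participants = 1)
  wf <- average_channels(generate_dataset(cfg)$recordings[[1]])

  # infinite threshold keeps everything
  res <- reject_outliers(wf, threshold = Inf)
  expect_equal(nrow(res$waveforms$waveforms), nrow(wf$waveforms))
  expect_false(any(res$report$excluded))

  # identical trials: singular covariance is regularised, none excluded
  dup <- wf
  dup$waveforms <- matrix(wf$waveforms[1, ], 4, ncol(wf$waveforms),
                          byrow = TRUE)
  dup$condition <- rep("alone_f1", 4)
  res2 <- suppressWarnings(reject_outliers(dup, threshold = 3))
  expect_false(any(res2$report$excluded))
  expect_warning(complex_mahalanobis(trial_coefficients(dup, 5), 5), "Singular")

  # an absurdly small threshold excludes everything -> error
  expect_error(suppressWarnings(reject_outliers(wf, threshold = 1e-12)),
               "All trials")
  expect_error(reject_outliers(wf, threshold = -1), "threshold")
})

test_that("the joint 4-D rule is available and agrees on obvious outliers", {
  set.seed(5)
  n <- 50
  cf5 <- make_coeffs(re = rnorm(n), im = rnorm(n), frequency = 5)
  cf7 <- make_coeffs(re = rnorm(n), im = rnorm(n), frequency = 7)
  # blow up trial 10 at both frequencies (20 marginal SDs)
  cf5$re[10] <- 20; cf7$im[10] <- 20
  coeffs <- dplyr::bind_rows(cf5, cf7)
  wf <- make_waveforms(matrix(rnorm(n * 100), n), 250, 1, 101,
                       rep("alone_f1", n))

  per_freq <- reject_outliers(wf, freqs = c(5, 7), coeffs = coeffs)
  joint <- reject_outliers(wf, freqs = c(5, 7), coeffs = coeffs, joint = TRUE)
  expect_true(10 %in% dplyr::filter(per_freq$report, excluded)$trial)
  expect_true(10 %in% dplyr::filter(joint$report, excluded)$trial)
})
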