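# Mahalanobis distances of rows of a 2 (or 2k) column matrix from their
# sample mean, with a ridge fallback when the sample covariance is
# singular (e.g. duplicated trials).
mahal_distances <- function(X) {
  if (nrow(X) < 3) abort("Need at least 3 trials to estimate a covariance.")
  mu <- colMeans(X)
  S <- stats::cov(X)
  d2 <- tryCatch(
    mahalanobis(X, mu, S),
    error = function(e) {
      eps <- 1e-8 * mean(diag(S))
      if (!is.finite(eps) || eps <= 0) eps <- 1e-12
      warn("Singular coefficient covariance; using ridge-regularised estimate.")
      mahalanobis(X, mu, S + diag(eps, ncol(X)))
    }
  )
  sqrt(pmax(d2, 0))
}

#' Mahalanobis distance of complex Fourier coefficients
#'
#' Treats each trial's coefficient at one frequency as a (real, imaginary)
#' 2-vector and computes its Mahalanobis distance from the sample mean,
#' using the sample covariance over trials of the same condition. Under a
#' bivariate Gaussian null, squared distances are approximately
#' chi-squared with 2 df, so a threshold of 3 excludes about
#' `exp(-4.5) ~ 1.1%` of clean trials.
#'
#' @param coeffs A coefficient tibble from [trial_coefficients()].
#' @param frequency Frequency (Hz) whose coefficients to score.
#' @return A tibble with `participant`, `trial`, `condition`,
#'   `frequency_hz`, `distance`.
#' @export
complex_mahalanobis <- function(coeffs, frequency) {
  cf <- filter(coeffs, .data$frequency_hz == frequency)
  if (!nrow(cf)) abort(sprintf("No coefficients at %g Hz.", frequency))
  grp <- interaction(cf$participant, cf$condition, drop = TRUE)
  cf$distance <- NA_real_
  for (g in split(seq_len(nrow(cf)), grp)) {
    cf$distance[g] <- mahal_distances(cbind(cf$re[g], cf$im[g]))
  }
  select(cf, "participant", "trial", "condition", "frequency_hz", "distance")
}

#' Reject outlier trials on complex Fourier coefficients
#'
#' Excludes a trial when the Mahalanobis distance of its complex
#' coefficient exceeds `threshold` at any analysed frequency (default), or
#' when the joint distance over the stacked (re, im) pairs of all
#' frequencies exceeds it (`joint = TRUE`). Distances are always computed
#' within a trial's own condition, so decisions are condition-local.
#'
#' @param wf An `ssvep_waveforms` object with one waveform per trial.
#' @param freqs Frequencies (Hz) entering the QC rule; typically the two
#'   tagged fundamentals.
#' @param threshold Exclusion threshold on the distance (default 3).
#' @param joint Use one joint distance over all frequencies instead of the
#'   per-frequency exclude-if-any rule.
#' @param coeffs Optional precomputed [trial_coefficients()] tibble.
#' @return A list with `waveforms` (retained trials, order preserved) and
#'   `report`, a tibble of class `ssvep_outlier_report` with one row per
#'   trial x frequency (`distance`, `excluded`). Use [glance()] on the
#'   report for exclusion fractions.
#' @export
reject_outliers <- function(wf, freqs = c(5, 7), threshold = 3,
                            joint = FALSE, coeffs = NULL) {
  stopifnot(inherits(wf, "ssvep_waveforms"))
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0.")
  coeffs <- coeffs %||% trial_coefficients(wf, freqs)

  if (joint) {
    wide <- coeffs |>
      select("participant", "trial", "condition", "frequency_hz", "re", "im") |>
      tidyr::pivot_wider(names_from = "frequency_hz",
                         values_from = c("re", "im"))
    dist_tbl <- wide |>
      group_by(.data$participant, .data$condition) |>
      dplyr::group_modify(function(df, key) {
        X <- as.matrix(select(df, -"trial"))
        df$distance <- mahal_distances(X)
        df
      }) |>
      ungroup() |>
      mutate(frequency_hz = NA_real_) |>
      select("participant", "trial", "condition", "frequency_hz", "distance")
  } else {
    dist_tbl <- purrr::map_dfr(freqs, ~ complex_mahalanobis(coeffs, .x))
  }

  flags <- dist_tbl |>
    group_by(.data$trial) |>
    summarise(excluded = any(.data$distance > threshold), .groups = "drop")
  report <- dist_tbl |>
    left_join(flags, by = "trial") |>
    arrange(.data$trial, .data$frequency_hz)
  class(report) <- c("ssvep_outlier_report", class(report))
  attr(report, "threshold") <- threshold

  excluded_trials <- flags$trial[flags$excluded]
  keep <- setdiff(seq_len(nrow(wf$waveforms)), excluded_trials)
  if (!length(keep)) {
    abort("All trials were excluded; downstream averages are undefined.")
  }
  list(waveforms = subset_trials(wf, keep), report = report)
}

#' Exclusion-rate summary of an outlier report
#'
#' @param x An `ssvep_outlier_report` from [reject_outliers()].
#' @param ... Unused.
#' @return A one-row tibble with the trial counts, overall exclusion
#'   fraction, and threshold.
#' @method glance ssvep_outlier_report
#' @export
glance.ssvep_outlier_report <- function(x, ...) {
  per_trial <- distinct(x, .data$trial, .data$excluded)
  tibble(
    n_trials = nrow(per_trial),
    n_excluded = sum(per_trial$excluded),
    exclusion_fraction = mean(per_trial$excluded),
    threshold = attr(x, "threshold")
  )
}

#' Per-condition exclusion fractions
#'
#' @param x An `ssvep_outlier_report` from [reject_outliers()].
#' @param ... Unused.
#' @return A tibble with one row per condition.
#' @method tidy ssvep_outlier_report
#' @export
tidy.ssvep_outlier_report <- function(x, ...) {
  x |>
    distinct(.data$participant, .data$trial, .data$condition, .data$excluded) |>
    group_by(.data$participant, .data$condition) |>
    summarise(n_trials = n(), n_excluded = sum(.data$excluded),
              exclusion_fraction = mean(.data$excluded), .groups = "drop")
}
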