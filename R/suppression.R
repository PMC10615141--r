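default_amplitude_floor <- 1e-3  # uV; keeps dB ratios finite on noise-free data

# align two amplitude courses on identical (participant, frequency, time)
# grids; errors loudly on any mismatch.
check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("Time courses have different lengths.")
  if (!isTRUE(all.equal(a$time_s, b$time_s)) ||
      !identical(a$participant, b$participant)) {
    abort("Time courses must share the same participant and time grid.")
  }
  invisible(NULL)
}

#' Suppression-ratio time course in dB
#'
#' Divides the target-alone amplitude course by the masked course at each
#' window centre and converts to decibels:
#' `ratio_db = 20 * log10(max(alone, floor) / max(masked, floor))`.
#' Positive dB means the mask suppressed the response; the raw ratio is
#' also returned.
#'
#' @param tc_alone,tc_masked Amplitude time courses from
#'   [sliding_timecourse()] for the same participant, frequency and grid.
#' @param mask_type Label stored in the result (`"monocular"`,
#'   `"dichoptic"`, ...).
#' @param floor Amplitude floor in uV applied to both numerator and
#'   denominator.
#' @return A tibble with `participant`, `frequency_hz`, `mask_type`,
#'   `time_s`, `ratio`, `ratio_db`.
#' @export
suppression_ratio <- function(tc_alone, tc_masked, mask_type = "monocular",
                              floor = default_amplitude_floor) {
  check_same_grid(tc_alone, tc_masked)
  if (!isTRUE(all.equal(tc_alone$frequency_hz, tc_masked$frequency_hz))) {
    abort("Time courses must be at the same frequency.")
  }
  ratio <- pmax(tc_alone$amplitude, floor) / pmax(tc_masked$amplitude, floor)
  tibble(
    participant = tc_alone$participant,
    frequency_hz = tc_alone$frequency_hz,
    mask_type = mask_type,
    time_s = tc_alone$time_s,
    ratio = ratio,
    ratio_db = 20 * log10(ratio)
  )
}

#' Build all suppression time courses from an amplitude-course table
#'
#' Applies the condition semantics of the four-condition design: at each
#' analysed frequency belonging to the `f1` stream (fundamental `f1` or
#' harmonic `2 f1`), the alone course comes from `alone_f1` and the masked
#' course from each plaid condition (`plaid_mon` -> monocular, `plaid_dich`
#' -> dichoptic); likewise for the `f2` stream.
#'
#' @param tc Amplitude-course tibble from [sliding_timecourse()] covering
#'   the needed conditions and frequencies.
#' @param f1,f2 The two tagged fundamentals (Hz).
#' @param floor Amplitude floor in uV.
#' @return A suppression tibble (rows for every frequency x mask type
#'   present), as from [suppression_ratio()].
#' @export
suppression_timecourses <- function(tc, f1 = 5, f2 = 7,
                                    floor = default_amplitude_floor) {
  masks <- c(plaid_mon = "monocular", plaid_dich = "dichoptic")
  freqs <- unique(tc$frequency_hz)
  purrr::map_dfr(freqs, function(f) {
    alone_cond <- if (f %in% c(f1, 2 * f1)) "alone_f1"
                  else if (f %in% c(f2, 2 * f2)) "alone_f2"
                  else return(tibble())
    purrr::map_dfr(names(masks), function(pc) {
      a <- filter(tc, .data$frequency_hz == f, .data$condition == alone_cond)
      m <- filter(tc, .data$frequency_hz == f, .data$condition == pc)
      if (!nrow(a) || !nrow(m)) return(tibble())
      suppression_ratio(a, m, mask_type = unname(masks[pc]), floor = floor)
    })
  })
}

#' Pool suppression time courses across frequencies and/or mask types
#'
#' Arithmetic mean of the dB ratios at each time point within participant,
#' collapsing the pooled dimensions (averaging is done in dB; the pooled
#' raw ratio is the corresponding geometric mean).
#'
#' @param sup A suppression tibble from [suppression_timecourses()].
#' @param over Dimensions to pool over: any of `"frequency_hz"`,
#'   `"mask_type"`.
#' @return A tibble with `participant`, the unpooled dimensions, `time_s`,
#'   `ratio_db`, `ratio`.
#' @export
pool_timecourses <- function(sup, over = c("frequency_hz", "mask_type")) {
  if (!nrow(sup)) abort("Cannot pool an empty set of time courses.")
  keep <- setdiff(c("participant", "frequency_hz", "mask_type", "time_s"),
                  over)
  out <- sup |>
    group_by(across(all_of(keep))) |>
    summarise(ratio_db = mean(.data$ratio_db), .groups = "drop") |>
    mutate(ratio = 10^(.data$ratio_db / 20))
  attr(out, "smoothed") <- attr(sup, "smoothed")
  out
}

#' Windowed effect size of increasing suppression
#'
#' Compares each participant's mean suppression (dB) in an early window
#' against a late window and expresses the increase as Cohen's d. The
#' default flavour is the paired (difference-score) d over participants,
#' `d = mean(late - early) / sd(late - early)`; `method = "pooled"` uses
#' the average of the two window SDs as denominator instead.
#'
#' @param sup A (typically pooled) suppression tibble with one course per
#'   participant.
#' @param early,late Two non-overlapping `c(start, end)` windows in
#'   seconds from onset (half-open; defaults 0-1 s vs 3-4 s).
#' @param method `"paired"` (default) or `"pooled"`.
#' @return An `ssvep_effect_size` object; see [glance.ssvep_effect_size()].
#' @export
window_effect_size <- function(sup, early = c(0, 1), late = c(3, 4),
                               method = c("paired", "pooled")) {
  method <- match.arg(method)
  assert_unsmoothed(sup, "window_effect_size()")
  if (max(early[1], late[1]) < min(early[2], late[2])) {
    abort("`early` and `late` windows must not overlap.")
  }
  win_mean <- function(lo, hi, nm) {
    sup |>
      filter(.data$time_s >= lo, .data$time_s < hi) |>
      group_by(.data$participant) |>
      summarise("{nm}" := mean(.data$ratio_db), .groups = "drop")
  }
  per <- win_mean(early[1], early[2], "early_db") |>
    dplyr::inner_join(win_mean(late[1], late[2], "late_db"), by = "participant") |>
    mutate(diff_db = .data$late_db - .data$early_db)
  if (nrow(per) < 2) abort("Effect sizes need at least 2 participants.")
  s <- switch(method,
    paired = sd(per$diff_db),
    pooled = sqrt((var(per$early_db) + var(per$late_db)) / 2)
  )
  if (!is.finite(s) || s == 0) {
    abort("Degenerate effect size: zero variability across participants.",
          class = "ssvep_degenerate_error")
  }
  structure(list(
    per_participant = per,
    cohen_d = mean(per$diff_db) / s,
    method = method, early = early, late = late
  ), class = "ssvep_effect_size")
}

#' @export
print.ssvep_effect_size <- function(x, ...) {
  cat(sprintf("<ssvep_effect_size> d = %.3f (%s), %d participants, windows %g-%g vs %g-%g s\n",
              x$cohen_d, x$method, nrow(x$per_participant),
              x$early[1], x$early[2], x$late[1], x$late[2]))
  invisible(x)
}

#' @describeIn window_effect_size One-row summary (Cohen's d, window means).
#' @param x An `ssvep_effect_size` object.
#' @param ... Unused.
#' @method glance ssvep_effect_size
#' @export
glance.ssvep_effect_size <- function(x, ...) {
  tibble(
    cohen_d = x$cohen_d,
    n_participants = nrow(x$per_participant),
    mean_early_db = mean(x$per_participant$early_db),
    mean_late_db = mean(x$per_participant$late_db),
    mean_diff_db = mean(x$per_participant$diff_db),
    sd_diff_db = sd(x$per_participant$diff_db),
    method = x$method
  )
}

#' @describeIn window_effect_size Per-participant window means.
#' @method tidy ssvep_effect_size
#' @export
tidy.ssvep_effect_size <- function(x, ...) {
  x$per_participant
}

#' Intermodulation response time course
#'
#' Expresses the amplitude at the sum intermodulation frequency
#' (`f1 + f2`) in the plaid conditions as a proportional increase over the
#' alone-condition baseline, in which no intermodulation response exists:
#' `index = (plaid - baseline) / max(baseline, floor)`, where the baseline
#' is the mean of the two alone-condition courses at the same frequency.
#'
#' @param tc Amplitude-course tibble containing the intermodulation
#'   frequency for the plaid and both alone conditions.
#' @param f_im Intermodulation frequency in Hz (default 12).
#' @param floor Baseline amplitude floor in uV.
#' @return A tibble with `participant`, `condition` (plaid conditions),
#'   `frequency_hz`, `time_s`, `im_index`.
#' @export
intermodulation_timecourse <- function(tc, f_im = 12,
                                       floor = default_amplitude_floor) {
  tc_im <- filter(tc, .data$frequency_hz == f_im)
  if (!nrow(tc_im)) abort(sprintf("No amplitude course at %g Hz.", f_im))
  base <- tc_im |>
    filter(.data$condition %in% c("alone_f1", "alone_f2")) |>
    group_by(.data$participant, .data$time_s) |>
    summarise(baseline = mean(.data$amplitude), .groups = "drop")
  if (!nrow(base)) abort("No alone-condition baseline at the intermodulation frequency.")
  plaid <- filter(tc_im, .data$condition %in% c("plaid_mon", "plaid_dich"))
  out <- plaid |>
    left_join(base, by = c("participant", "time_s"))
  if (anyNA(out$baseline)) abort("Plaid and baseline courses are on different grids.")
  out |>
    mutate(im_index = (.data$amplitude - .data$baseline) /
             pmax(.data$baseline, floor)) |>
    select("participant", "condition", "frequency_hz", "time_s", "im_index")
}

#' Fit an exponential rise to a group-mean suppression course
#'
#' Least-squares fit of `db(t) = d0 + (d_inf - d0) * (1 - exp(-t / tau))`
#' to the across-participant mean suppression course, restricted to window
#' centres whose analysis window lies fully inside the stimulation period.
#' Used to recover the reweighting time constant and asymptotic
#' suppression from data.
#'
#' @param sup A (pooled) suppression tibble.
#' @param t_range Time range (s) of window centres entering the fit.
#' @return An `ssvep_reweighting_fit`; `glance()` gives `tau_s`,
#'   `asymptote_db`, `d0_db`.
#' @export
fit_reweighting <- function(sup, t_range = c(0.5, 5.5)) {
  assert_unsmoothed(sup, "fit_reweighting()")
  dat <- sup |>
    filter(.data$time_s >= t_range[1], .data$time_s <= t_range[2]) |>
    group_by(.data$time_s) |>
    summarise(ratio_db = mean(.data$ratio_db), .groups = "drop")
  if (nrow(dat) < 4) abort("Too few time points for an exponential fit.")
  start <- list(
    d0 = mean(head(dat$ratio_db, max(2, nrow(dat) %/% 10))),
    dinf = mean(tail(dat$ratio_db, max(2, nrow(dat) %/% 5))),
    tau = 1
  )
  fit <- minpack.lm::nlsLM(
    ratio_db ~ d0 + (dinf - d0) * (1 - exp(-time_s / tau)),
    data = dat, start = start,
    lower = c(d0 = -Inf, dinf = -Inf, tau = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  structure(list(fit = fit, data = dat), class = "ssvep_reweighting_fit")
}

#' @export
print.ssvep_reweighting_fit <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf("<ssvep_reweighting_fit> tau = %.3f s, asymptote = %.3f dB (onset %.3f dB)\n",
              cf[["tau"]], cf[["dinf"]], cf[["d0"]]))
  invisible(x)
}

#' @describeIn fit_reweighting One-row parameter summary.
#' @param x An `ssvep_reweighting_fit` object.
#' @param ... Unused.
#' @method glance ssvep_reweighting_fit
#' @export
glance.ssvep_reweighting_fit <- function(x, ...) {
  cf <- coef(x$fit)
  tibble(
    tau_s = cf[["tau"]],
    asymptote_db = cf[["dinf"]],
    d0_db = cf[["d0"]],
    rss = sum(stats::resid(x$fit)^2),
    n_timepoints = nrow(x$data)
  )
}

#' @describeIn fit_reweighting Parameter estimates with standard errors.
#' @method tidy ssvep_reweighting_fit
#' @export
tidy.ssvep_reweighting_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}
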