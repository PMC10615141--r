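#' Analyse one epoched recording to amplitude and suppression courses
#'
#' The per-participant analysis chain: average the analysis channels,
#' reject outlier trials on complex Fourier coefficients, coherently
#' average the survivors per condition, compute sliding-window amplitude
#' time courses at the requested frequencies, and form suppression and
#' intermodulation courses.
#'
#' @param rec An [ssvep_epochs] recording.
#' @param channels Channel names to average (default: all).
#' @param f1,f2 Tagged fundamentals in Hz.
#' @param freqs Analysis frequencies; defaults to the fundamentals plus,
#'   when below Nyquist, the second harmonics and the sum intermodulation
#'   frequency.
#' @param window_s,step_s Sliding-window length and step in seconds.
#' @param mahal_threshold Outlier-rejection threshold (see
#'   [reject_outliers()]); `Inf` disables rejection.
#' @param floor Amplitude floor in uV for ratio-type quantities.
#' @return A list with tibbles `amplitude`, `suppression`,
#'   `intermodulation` (NULL if `f1 + f2` was not analysed), and `qc`
#'   (per-condition exclusion fractions).
#' @export
analyze_recording <- function(rec, channels = rec$channel_names,
                              f1 = 5, f2 = 7, freqs = NULL,
                              window_s = 1, step_s = 0.01,
                              mahal_threshold = 3,
                              floor = default_amplitude_floor) {
  nyq <- rec$sample_rate / 2
  freqs <- freqs %||% {
    ff <- c(f1, f2, 2 * f1, 2 * f2, f1 + f2)
    unique(ff[ff < nyq])
  }
  wf <- average_channels(rec, channels)
  if (is.finite(mahal_threshold)) {
    qc <- reject_outliers(wf, freqs = c(f1, f2), threshold = mahal_threshold)
    wf_clean <- qc$waveforms
    qc_tbl <- tidy(qc$report)
  } else {
    # QC disabled: keep everything (also usable with < 3 trials/condition)
    wf_clean <- wf
    qc_tbl <- as_tibble(table(condition = wf$condition)) |>
      mutate(participant = wf$participant_id, n_excluded = 0L,
             exclusion_fraction = 0) |>
      select("participant", "condition", n_trials = "n", "n_excluded",
             "exclusion_fraction")
  }
  avg <- coherent_average(wf_clean)
  amp <- sliding_timecourse(avg, freqs, window_s = window_s, step_s = step_s)
  sup <- suppression_timecourses(amp, f1 = f1, f2 = f2, floor = floor)
  im <- if ((f1 + f2) %in% freqs) {
    intermodulation_timecourse(amp, f_im = f1 + f2, floor = floor)
  }
  list(amplitude = amp, suppression = sup, intermodulation = im, qc = qc_tbl)
}

#' Analyse every recording of a dataset
#'
#' Maps [analyze_recording()] over a list of recordings (or an
#' `ssvep_dataset`) and row-binds the results.
#'
#' @param x An `ssvep_dataset` from [generate_dataset()], or a list of
#'   [ssvep_epochs] recordings.
#' @param ... Passed to [analyze_recording()].
#' @return A list of tibbles `amplitude`, `suppression`,
#'   `intermodulation`, `qc`, plus `groups` (participant -> group label).
#' @export
analyze_dataset <- function(x, ...) {
  recs <- if (inherits(x, "ssvep_dataset")) x$recordings else x
  res <- purrr::map(recs, analyze_recording, ...)
  list(
    amplitude = purrr::map_dfr(res, "amplitude"),
    suppression = purrr::map_dfr(res, "suppression"),
    intermodulation = purrr::map_dfr(res, "intermodulation"),
    qc = purrr::map_dfr(res, "qc"),
    groups = tibble(
      participant = purrr::map_chr(recs, "participant_id"),
      group_label = purrr::map_chr(recs, "group_label")
    )
  )
}

#' Simulate and analyse a dataset one participant at a time
#'
#' Equivalent to `analyze_dataset(generate_dataset(cfg), ...)` but streams:
#' each participant's raw epochs are generated, analysed and discarded
#' before the next is simulated, so only the (small) time-course tibbles
#' are ever held in memory. Useful for simulation studies at realistic
#' sample sizes.
#'
#' @param cfg A [sim_config()].
#' @param group_labels Optional group labels, one per participant.
#' @param ... Passed to [analyze_recording()].
#' @return As [analyze_dataset()].
#' @export
simulate_and_analyze <- function(cfg, group_labels = NULL, ...) {
  validate_sim_config(cfg)
  if (is.null(group_labels)) {
    group_labels <- rep(NA_character_, cfg$n_participants)
  }
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  res <- purrr::map(seq_len(cfg$n_participants), function(i) {
    p <- generate_participant(cfg, ids[i], seeds[i], group_labels[i])
    out <- analyze_recording(p$recording, ...)
    rm(p)
    out
  })
  list(
    amplitude = purrr::map_dfr(res, "amplitude"),
    suppression = purrr::map_dfr(res, "suppression"),
    intermodulation = purrr::map_dfr(res, "intermodulation"),
    qc = purrr::map_dfr(res, "qc"),
    groups = tibble(participant = ids, group_label = group_labels)
  )
}

#' Split participants into two groups
#'
#' `by = "median_score"` assigns participants with scores at or below the
#' median to `"low"` and the rest to `"high"` (ties go low). `by =
#' "diagnosis"` splits by the labels of `var` verbatim. Participants with
#' missing values are dropped with a warning.
#'
#' @param metadata Tibble with a `participant` column and the split
#'   variable.
#' @param var Name of the split variable column.
#' @param by `"median_score"` or `"diagnosis"`.
#' @return Named list of participant-id character vectors (two entries).
#' @export
split_groups <- function(metadata, var, by = c("median_score", "diagnosis")) {
  by <- match.arg(by)
  if (!var %in% names(metadata)) abort(sprintf("No column '%s' in metadata.", var))
  v <- metadata[[var]]
  keep <- !is.na(v)
  if (any(!keep)) {
    warn(sprintf("Dropping %d participant(s) with missing '%s'.",
                 sum(!keep), var))
  }
  md <- metadata[keep, ]
  v <- v[keep]
  groups <- if (by == "median_score") {
    med <- median(v)
    list(low = md$participant[v <= med], high = md$participant[v > med])
  } else {
    labs <- unique(v)
    if (length(labs) != 2) {
      abort(sprintf("Diagnosis split needs exactly 2 labels; found %d.",
                    length(labs)))
    }
    setNames(lapply(labs, function(l) md$participant[v == l]), labs)
  }
  if (any(lengths(groups) == 0)) {
    abort("Group split produced an empty group.")
  }
  groups
}

#' Simulation-based check that windowing does not distort suppression
#'
#' Reproduces the ratio-cancellation diagnostic: two matched noise-free
#' recordings are simulated in which the masked waveform is the
#' target-alone waveform scaled by a constant `gain` from stimulus onset.
#' The sliding window blurs each amplitude course across onset, but the
#' blur is common to numerator and denominator, so the estimated ratio
#' should sit at `-20 log10(gain)` dB at every window centre where signal
#' is present — including windows straddling the onset.
#'
#' @param gain Constant amplitude gain (< 1 means suppression).
#' @param f Tagging frequency in Hz.
#' @param amplitude Signal amplitude in uV.
#' @param sample_rate,trial_duration,epoch_pre,epoch_post Timing (s, Hz).
#' @param window_s,step_s Analysis window and step (s).
#' @param floor Amplitude floor in uV; centres where either course falls
#'   to the floor (no signal in the window) are excluded from the
#'   deviation summary.
#' @return An `ssvep_blur_report`: programmed and estimated dB, the
#'   maximum absolute deviation over evaluable centres, and the underlying
#'   courses.
#' @export
blur_cancellation_diagnostic <- function(gain = 0.8, f = 5, amplitude = 2,
                                         sample_rate = 1000,
                                         trial_duration = 6,
                                         epoch_pre = 1.5, epoch_post = 1.5,
                                         window_s = 1, step_s = 0.01,
                                         floor = default_amplitude_floor) {
  n_pre <- round(epoch_pre * sample_rate)
  n_stim <- round(trial_duration * sample_rate)
  n_post <- round(epoch_post * sample_rate)
  n <- n_pre + n_stim + n_post
  onset <- n_pre + 1L
  t <- (seq_len(n) - onset) / sample_rate
  stim <- t >= 0 & t < trial_duration
  alone <- ifelse(stim, amplitude * sin(2 * pi * f * t), 0)
  masked <- alone * gain
  wf <- structure(list(
    waveforms = rbind(alone, masked), sample_rate = sample_rate,
    onset_index = onset, offset_index = onset + n_stim,
    condition = c("alone_f1", "plaid_mon"), participant_id = "SIM",
    group_label = NA_character_, channels = "Oz"
  ), class = "ssvep_waveforms")
  amp <- sliding_timecourse(wf, f, window_s = window_s, step_s = step_s)
  sup <- suppression_ratio(
    filter(amp, .data$condition == "alone_f1"),
    filter(amp, .data$condition == "plaid_mon"),
    mask_type = "monocular", floor = floor
  )
  alone_amp <- filter(amp, .data$condition == "alone_f1")$amplitude
  masked_amp <- filter(amp, .data$condition == "plaid_mon")$amplitude
  evaluable <- alone_amp > floor & masked_amp > floor
  programmed <- -20 * log10(gain)
  structure(list(
    gain = gain, programmed_db = programmed,
    suppression = sup, amplitude = amp, evaluable = evaluable,
    max_deviation_db = max(abs(sup$ratio_db[evaluable] - programmed))
  ), class = "ssvep_blur_report")
}

#' @export
print.ssvep_blur_report <- function(x, ...) {
  cat(sprintf("<ssvep_blur_report> gain %g -> programmed %.4f dB; max |deviation| = %.2e dB over %d centres\n",
              x$gain, x$programmed_db, x$max_deviation_db, sum(x$evaluable)))
  invisible(x)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline end to end
#'
#' Simulates (or loads) epoched recordings, runs QC, time courses,
#' suppression metrics, the windowed effect size and the
#' increasing-suppression cluster test, optionally a two-group comparison,
#' and writes tidy CSV/JSON outputs plus a run manifest with file
#' checksums.
#'
#' @param sim A [sim_config()] to simulate from, or `NULL` when
#'   `input_paths` is given.
#' @param input_paths Character vector of epochs-container JSON sidecars
#'   to load instead of simulating.
#' @param out_dir Output directory.
#' @param channels Channels to average (default: all in each recording).
#' @param f1,f2,window_s,step_s,mahal_threshold,floor See
#'   [analyze_recording()].
#' @param lag,alpha_pointwise,n_permutations Cluster-test settings.
#' @param effect_early,effect_late Effect-size windows in seconds.
#' @param metadata,split_var,split_by Optional group comparison: a
#'   metadata tibble and arguments for [split_groups()].
#' @param seed Seed for the permutation RNG (simulation uses `sim$seed`).
#' @return The run manifest (list), invisibly; all outputs are files in
#'   `out_dir`.
#' @export
run_pipeline <- function(sim = NULL, input_paths = NULL, out_dir,
                         channels = NULL, f1 = 5, f2 = 7,
                         window_s = 1, step_s = 0.01, mahal_threshold = 3,
                         floor = default_amplitude_floor,
                         lag = 1, alpha_pointwise = 0.05,
                         n_permutations = 1000,
                         effect_early = c(0, 1), effect_late = c(3, 4),
                         metadata = NULL, split_var = NULL,
                         split_by = "median_score", seed = 1) {
  if (is.null(sim) == is.null(input_paths)) {
    abort("Provide exactly one of `sim` or `input_paths`.")
  }
  if (!is.null(sim) && window_s > sim$trial_duration) {
    abort("`window_s` exceeds the trial duration; no stimulation window fits.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, s = proc.time()[["elapsed"]] - t0)
  }

  st <- clock(if (is.null(sim)) {
    list(recordings = purrr::map(input_paths, read_epochs))
  } else {
    generate_dataset(sim)
  })
  dataset <- st$val
  timings$load <- st$s
  recs <- dataset$recordings

  st <- clock(analyze_dataset(
    recs, channels = channels %||% recs[[1]]$channel_names,
    f1 = f1, f2 = f2, window_s = window_s, step_s = step_s,
    mahal_threshold = mahal_threshold, floor = floor
  ))
  res <- st$val
  timings$analysis <- st$s

  pooled <- pool_timecourses(res$suppression)
  es <- window_effect_size(pooled, early = effect_early, late = effect_late)
  st <- clock(cluster_test_increase(
    pooled, lag = lag, alpha_pointwise = alpha_pointwise,
    n_permutations = n_permutations, seed = seed
  ))
  increase <- st$val
  timings$cluster_increase <- st$s

  group_test <- NULL
  if (!is.null(metadata) && !is.null(split_var)) {
    groups <- split_groups(metadata, split_var, by = split_by)
    group_test <- cluster_test_groups(
      filter(pooled, .data$participant %in% groups[[1]]),
      filter(pooled, .data$participant %in% groups[[2]]),
      alpha_pointwise = alpha_pointwise,
      n_permutations = n_permutations, seed = seed
    )
  }

  files <- c(
    amplitude = write_stage_csv(res$amplitude, file.path(out_dir, "amplitude_timecourses.csv")),
    suppression = write_stage_csv(res$suppression, file.path(out_dir, "suppression_timecourses.csv")),
    pooled = write_stage_csv(pooled, file.path(out_dir, "pooled_suppression.csv")),
    qc = write_stage_csv(res$qc, file.path(out_dir, "qc_report.csv"))
  )
  if (!is.null(res$intermodulation) && nrow(res$intermodulation)) {
    files["intermodulation"] <- write_stage_csv(
      res$intermodulation, file.path(out_dir, "intermodulation_timecourses.csv"))
  }
  jsonlite::write_json(glance(es), file.path(out_dir, "effect_size.json"),
                       auto_unbox = TRUE, digits = NA)
  files["effect_size"] <- file.path(out_dir, "effect_size.json")
  cluster_out <- list(
    increase = list(clusters = tidy(increase),
                    critical_value = increase$critical_value,
                    significant_until_s = significant_until(increase))
  )
  if (!is.null(group_test)) {
    cluster_out$groups <- list(clusters = tidy(group_test),
                               critical_value = group_test$critical_value)
  }
  jsonlite::write_json(cluster_out, file.path(out_dir, "cluster_tests.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files["cluster_tests"] <- file.path(out_dir, "cluster_tests.json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssvepdyn")),
    config_hash = rlang::hash(list(sim = sim, f1 = f1, f2 = f2,
                                   window_s = window_s, step_s = step_s,
                                   mahal_threshold = mahal_threshold,
                                   lag = lag, n_permutations = n_permutations,
                                   seed = seed)),
    seed = seed,
    n_participants = length(recs),
    n_trials_in = sum(res$qc$n_trials),
    n_trials_excluded = sum(res$qc$n_excluded),
    exclusion_fraction = sum(res$qc$n_excluded) / sum(res$qc$n_trials),
    effect_size_d = es$cohen_d,
    significant_until_s = significant_until(increase),
    stage_seconds = timings,
    files = as.list(setNames(unname(tools::md5sum(files)), names(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
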