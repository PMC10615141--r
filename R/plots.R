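#' Plot amplitude time courses
#'
#' Group-mean amplitude against window-centre time, one line per
#' condition, faceted by frequency. Shaded ribbons show +/- 1 SEM across
#' participants when more than one is present.
#'
#' @param tc Amplitude tibble from [sliding_timecourse()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  summ <- tc |>
    group_by(.data$condition, .data$frequency_hz, .data$time_s) |>
    summarise(mean = mean(.data$amplitude),
              sem = sd(.data$amplitude) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$time_s, .data$mean,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~frequency_hz, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time from onset (s)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot suppression-ratio time courses
#'
#' Group-mean dB suppression against time per mask type, faceted by
#' frequency (pooled input plots a single panel).
#'
#' @param sup Suppression tibble from [suppression_timecourses()] or
#'   [pool_timecourses()].
#' @return A ggplot object.
#' @export
plot_suppression <- function(sup) {
  dims <- intersect(c("mask_type", "frequency_hz"), names(sup))
  summ <- sup |>
    group_by(across(all_of(c(dims, "time_s")))) |>
    summarise(mean = mean(.data$ratio_db),
              sem = sd(.data$ratio_db) / sqrt(n()), .groups = "drop")
  aes_col <- if ("mask_type" %in% dims) {
    ggplot2::aes(.data$time_s, .data$mean, colour = .data$mask_type,
                 fill = .data$mask_type)
  } else {
    ggplot2::aes(.data$time_s, .data$mean)
  }
  p <- ggplot2::ggplot(summ, aes_col) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from onset (s)", y = "Suppression (dB)") +
    ggplot2::theme_minimal()
  if ("frequency_hz" %in% dims) {
    p <- p + ggplot2::facet_wrap(~frequency_hz, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a cluster permutation test
#'
#' The pointwise t series with the cluster-forming threshold and shaded
#' significant clusters.
#'
#' @param object An `ssvep_cluster_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssvep_cluster_test
#' @export
autoplot.ssvep_cluster_test <- function(object, ...) {
  thr <- attr(object$clusters, "threshold")
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  p <- ggplot2::ggplot(object$t_series, ggplot2::aes(.data$time_s, .data$t)) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from onset (s)", y = "t statistic",
                  title = sprintf("Cluster test (%s)", object$type)) +
    ggplot2::theme_minimal()
  if (object$config$sidedness == "two_sided") {
    p <- p + ggplot2::geom_hline(yintercept = -thr, linetype = 2,
                                 colour = "grey50")
  }
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick")
  }
  p
}

#' Plot a stimulation-period amplitude spectrum
#'
#' @param spec Tibble from [full_trial_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spec) {
  summ <- spec |>
    group_by(.data$condition, .data$frequency_hz) |>
    summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$frequency_hz, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}
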