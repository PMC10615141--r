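# participants x timepoints matrix from a pooled suppression tibble;
# errors unless every participant sits on the same time grid.
course_matrix <- function(sup, value_col = "ratio_db") {
  wide <- sup |>
    select("participant", "time_s", all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "time_s", values_from = all_of(value_col)) |>
    arrange(.data$participant)
  m <- as.matrix(select(wide, -"participant"))
  if (anyNA(m)) abort("Participants are not on a shared time grid.")
  rownames(m) <- wide$participant
  attr(m, "times") <- as.numeric(colnames(wide)[-1])
  m
}

# lagged within-participant differences y(t + lag/2) - y(t - lag/2),
# snapping lag/2 to the nearest grid offset (with a warning if inexact).
lagged_differences <- function(sup, lag) {
  if (lag <= 0) abort("`lag` must be > 0.")
  Y <- course_matrix(sup)
  times <- attr(Y, "times")
  step <- median(diff(times))
  off <- round((lag / 2) / step)
  if (off < 1) abort("`lag` is below the time-grid resolution.")
  if (abs(off * step - lag / 2) > 1e-8) {
    warn(sprintf("lag/2 = %g s is not on the %g-s grid; snapped to %g s.",
                 lag / 2, step, off * step))
  }
  ct <- seq(1 + off, length(times) - off)
  if (!length(ct)) abort("No window centre has both lagged neighbours in range.")
  D <- Y[, ct + off, drop = FALSE] - Y[, ct - off, drop = FALSE]
  list(D = D, times = times[ct])
}

# one-sample t per column with the degenerate zero-variance convention:
# t = 0 when all differences are 0, +/-Inf when they are equal but nonzero.
one_sample_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(pmax(colSums(D^2) - n * m^2, 0) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
  t
}

#' Trend t series for increasing suppression
#'
#' At each window centre with both lagged neighbours in range, a paired
#' one-sample t statistic (df = N - 1) over participants of the
#' within-participant difference `ratio_db(t + lag/2) - ratio_db(t -
#' lag/2)`. Positive t means suppression is higher half a lag after the
#' centre than half a lag before it.
#'
#' @param sup A pooled suppression tibble (one course per participant on a
#'   shared grid).
#' @param lag Separation in seconds between the compared time points
#'   (default 1).
#' @return A tibble with `time_s`, `t`, `df`.
#' @export
trend_t_series <- function(sup, lag = 1) {
  assert_unsmoothed(sup, "trend_t_series()")
  ld <- lagged_differences(sup, lag)
  if (nrow(ld$D) < 3) abort("Trend test needs at least 3 participants.")
  tibble(time_s = ld$times, t = one_sample_t(ld$D), df = nrow(ld$D) - 1L)
}

# maximal runs of TRUE in a logical vector -> start/end indices
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  list(starts = starts[keep], ends = ends[keep])
}

#' Identify supra-threshold clusters in a t series
#'
#' Thresholds the pointwise t statistics at the `1 - alpha` (one-sided) or
#' `1 - alpha/2` (two-sided, both signs) quantile of the t distribution
#' and returns maximal runs of temporally adjacent supra-threshold points
#' with their summed t values.
#'
#' @param t_series Tibble with `time_s`, `t`, `df` (from
#'   [trend_t_series()] or the group test).
#' @param alpha_pointwise Cluster-forming pointwise alpha (default 0.05).
#' @param sidedness `"one_sided_increase"` or `"two_sided"`.
#' @return A tibble with one row per cluster: `start_s`, `end_s`,
#'   `n_points`, `summed_t` (signed); attribute `threshold` holds the
#'   t threshold used.
#' @export
find_clusters <- function(t_series, alpha_pointwise = 0.05,
                          sidedness = c("one_sided_increase", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (!nrow(t_series)) abort("Empty t series.")
  df <- t_series$df[1]
  thr <- if (sidedness == "one_sided_increase") {
    qt(1 - alpha_pointwise, df)
  } else {
    qt(1 - alpha_pointwise / 2, df)
  }
  supra <- if (sidedness == "one_sided_increase") {
    t_series$t > thr
  } else {
    abs(t_series$t) > thr
  }
  # split two-sided runs at sign changes so clusters are sign-consistent
  sign_key <- sign(t_series$t)
  out <- tibble(start_s = numeric(), end_s = numeric(),
                n_points = integer(), summed_t = numeric())
  runs <- logical_runs(supra)
  for (i in seq_along(runs$starts)) {
    idx <- runs$starts[i]:runs$ends[i]
    pieces <- split(idx, cumsum(c(1, diff(sign_key[idx]) != 0)))
    for (p in pieces) {
      out <- bind_rows(out, tibble(
        start_s = t_series$time_s[p[1]],
        end_s = t_series$time_s[p[length(p)]],
        n_points = length(p),
        summed_t = sum(t_series$t[p])
      ))
    }
  }
  attr(out, "threshold") <- thr
  attr(out, "sidedness") <- sidedness
  out
}

# largest cluster statistic of one t vector (summed t for one-sided
# positive clusters; |summed t| within sign-consistent runs for two-sided).
max_cluster_stat <- function(t, thr, two_sided = FALSE) {
  supra <- if (two_sided) abs(t) > thr else t > thr
  if (!any(supra)) return(0)
  best <- 0
  runs <- logical_runs(supra)
  for (i in seq_along(runs$starts)) {
    idx <- runs$starts[i]:runs$ends[i]
    if (two_sided) {
      pieces <- split(idx, cumsum(c(1, diff(sign(t[idx])) != 0)))
      for (p in pieces) best <- max(best, abs(sum(t[p])))
    } else {
      best <- max(best, sum(t[idx]))
    }
  }
  best
}

new_cluster_test <- function(type, t_series, clusters, null_max, alpha,
                             config) {
  crit <- unname(quantile(null_max, 0.95))
  stat <- if (type == "groups") abs(clusters$summed_t) else clusters$summed_t
  clusters$significant <- stat > crit
  clusters$p_perm <- vapply(stat, function(s) {
    (1 + sum(null_max >= s)) / (1 + length(null_max))
  }, numeric(1))
  structure(list(
    type = type, t_series = t_series, clusters = clusters,
    null_max_summed_t = null_max, critical_value = crit,
    config = config
  ), class = "ssvep_cluster_test")
}

#' Cluster-corrected test for increasing suppression
#'
#' Nonparametric one-sided test that suppression ratios rise over time.
#' Pointwise paired t statistics between time points separated by `lag`
#' ([trend_t_series()]) are thresholded and clustered; the family-wise
#' null is built by flipping the sign of each participant's whole lagged
#' difference series at random (the exchangeable null for a one-sample
#' design with symmetric noise) and recording the maximum cluster's summed
#' t, `n_permutations` times. A cluster is significant when its summed t
#' exceeds the 95th percentile of that null maximum distribution.
#'
#' @param sup Pooled suppression tibble, one course per participant.
#' @param lag Trend lag in seconds (default 1).
#' @param alpha_pointwise Cluster-forming pointwise alpha (default 0.05).
#' @param n_permutations Number of sign-flip permutations (default 1000,
#'   minimum 100).
#' @param seed Integer seed for the permutation RNG.
#' @return An `ssvep_cluster_test`; see [tidy.ssvep_cluster_test()].
#' @export
cluster_test_increase <- function(sup, lag = 1, alpha_pointwise = 0.05,
                                  n_permutations = 1000, seed = 1) {
  assert_unsmoothed(sup, "cluster_test_increase()")
  if (n_permutations < 100) abort("Use at least 100 permutations.")
  ld <- lagged_differences(sup, lag)
  D <- ld$D
  n <- nrow(D)
  if (n < 3) abort("Cluster test needs at least 3 participants.")
  t_obs <- one_sample_t(D)
  t_series <- tibble(time_s = ld$times, t = t_obs, df = n - 1L)
  clusters <- find_clusters(t_series, alpha_pointwise, "one_sided_increase")
  thr <- attr(clusters, "threshold")

  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
              n_permutations, n)
  M <- S %*% D / n
  ss2 <- colSums(D^2)
  varm <- sweep(-n * M^2, 2, ss2, "+") / (n - 1)
  varm[varm < 0] <- 0
  Tm <- M / sqrt(varm / n)
  Tm[varm == 0] <- ifelse(M[varm == 0] == 0, 0, sign(M[varm == 0]) * Inf)
  null_max <- vapply(seq_len(n_permutations), function(i) {
    max_cluster_stat(Tm[i, ], thr)
  }, numeric(1))

  new_cluster_test("increase", t_series, clusters, null_max, alpha_pointwise,
                   list(lag = lag, alpha_pointwise = alpha_pointwise,
                        n_permutations = n_permutations, seed = seed,
                        null_type = "sign_flip",
                        sidedness = "one_sided_increase"))
}

# pooled-variance two-sample t per column for all label permutations at
# once; P is an n_perm x N 0/1 matrix selecting group A.
two_sample_t_matrix <- function(P, Y, Y2, nA, nB) {
  mA <- P %*% Y / nA
  mB <- (1 - P) %*% Y / nB
  ssA <- P %*% Y2 - nA * mA^2
  ssB <- (1 - P) %*% Y2 - nB * mB^2
  sp2 <- pmax(ssA + ssB, 0) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tt <- (mA - mB) / se
  tt[se == 0] <- ifelse((mA - mB)[se == 0] == 0, 0,
                        sign((mA - mB)[se == 0]) * Inf)
  tt
}

#' Cluster-corrected comparison of two participant groups
#'
#' Two-sided pointwise two-sample t tests (pooled variance,
#' df = nA + nB - 2) at each window centre, clustered as in
#' [find_clusters()]. The null distribution reassigns participants to
#' groups at random (group sizes preserved) and records the largest
#' cluster's |summed t| per permutation; clusters are significant when
#' their |summed t| exceeds the 95th percentile of this null.
#'
#' @param sup_a,sup_b Pooled suppression tibbles for the two groups (each
#'   with at least 2 participants, on the same time grid).
#' @inheritParams cluster_test_increase
#' @return An `ssvep_cluster_test`.
#' @export
cluster_test_groups <- function(sup_a, sup_b, alpha_pointwise = 0.05,
                                n_permutations = 1000, seed = 1) {
  assert_unsmoothed(sup_a, "cluster_test_groups()")
  assert_unsmoothed(sup_b, "cluster_test_groups()")
  if (n_permutations < 100) abort("Use at least 100 permutations.")
  YA <- course_matrix(sup_a)
  YB <- course_matrix(sup_b)
  if (!isTRUE(all.equal(attr(YA, "times"), attr(YB, "times")))) {
    abort("The two groups are on different time grids.")
  }
  nA <- nrow(YA); nB <- nrow(YB)
  if (nA < 2 || nB < 2) abort("Each group needs at least 2 participants.")
  Y <- rbind(YA, YB)
  Y2 <- Y^2
  obsP <- matrix(c(rep(1, nA), rep(0, nB)), 1)
  t_obs <- as.vector(two_sample_t_matrix(obsP, Y, Y2, nA, nB))
  t_series <- tibble(time_s = attr(YA, "times"), t = t_obs,
                     df = nA + nB - 2L)
  clusters <- find_clusters(t_series, alpha_pointwise, "two_sided")
  thr <- attr(clusters, "threshold")

  set.seed(seed)
  P <- t(vapply(seq_len(n_permutations), function(i) {
    p <- numeric(nA + nB)
    p[sample.int(nA + nB, nA)] <- 1
    p
  }, numeric(nA + nB)))
  Tm <- two_sample_t_matrix(P, Y, Y2, nA, nB)
  null_max <- vapply(seq_len(n_permutations), function(i) {
    max_cluster_stat(Tm[i, ], thr, two_sided = TRUE)
  }, numeric(1))

  new_cluster_test("groups", t_series, clusters, null_max, alpha_pointwise,
                   list(alpha_pointwise = alpha_pointwise,
                        n_permutations = n_permutations, seed = seed,
                        null_type = "label_shuffle", sidedness = "two_sided"))
}

#' @export
print.ssvep_cluster_test <- function(x, ...) {
  cat(sprintf("<ssvep_cluster_test: %s> %d cluster(s), critical summed t = %.2f (%d permutations)\n",
              x$type, nrow(x$clusters), x$critical_value,
              x$config$n_permutations))
  if (nrow(x$clusters)) {
    sig <- x$clusters[x$clusters$significant, ]
    if (nrow(sig)) {
      cat(sprintf("  significant: %s\n",
                  paste(sprintf("%.2f-%.2f s (sum t = %.1f)",
                                sig$start_s, sig$end_s, sig$summed_t),
                        collapse = "; ")))
    } else cat("  no significant clusters\n")
  }
  invisible(x)
}

#' Cluster table of a permutation test
#'
#' @param x An `ssvep_cluster_test`.
#' @param ... Unused.
#' @return Tibble of clusters (`start_s`, `end_s`, `n_points`, `summed_t`,
#'   `significant`, `p_perm`).
#' @method tidy ssvep_cluster_test
#' @export
tidy.ssvep_cluster_test <- function(x, ...) {
  as_tibble(x$clusters)
}

#' @rdname tidy.ssvep_cluster_test
#' @return For `glance()`: a one-row summary with the critical value and
#'   the extent of significant time.
#' @method glance ssvep_cluster_test
#' @export
glance.ssvep_cluster_test <- function(x, ...) {
  sig <- x$clusters[x$clusters$significant, , drop = FALSE]
  tibble(
    type = x$type,
    n_clusters = nrow(x$clusters),
    n_significant = nrow(sig),
    critical_value = x$critical_value,
    max_summed_t = if (nrow(x$clusters)) max(abs(x$clusters$summed_t)) else NA_real_,
    significant_until_s = significant_until(x),
    n_permutations = x$config$n_permutations
  )
}

#' Window centres inside significant clusters
#'
#' @param x An `ssvep_cluster_test`.
#' @return Numeric vector of significant window-centre times (s).
#' @export
significant_timepoints <- function(x) {
  sig <- x$clusters[x$clusters$significant, , drop = FALSE]
  if (!nrow(sig)) return(numeric(0))
  unlist(purrr::map2(sig$start_s, sig$end_s, function(a, b) {
    x$t_series$time_s[x$t_series$time_s >= a & x$t_series$time_s <= b]
  }))
}

#' Last significant centre of the earliest significant cluster
#'
#' The "suppression increases until T seconds" summary: the end time of
#' the earliest-starting significant cluster, or `NA` if none.
#'
#' @param x An `ssvep_cluster_test`.
#' @return A time in seconds, or `NA_real_`.
#' @export
significant_until <- function(x) {
  sig <- x$clusters[x$clusters$significant, , drop = FALSE]
  if (!nrow(sig)) return(NA_real_)
  sig$end_s[which.min(sig$start_s)]
}
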