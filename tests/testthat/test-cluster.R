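test_that("trend t series matches the textbook paired t statistic", {
  # ten participants whose courses are straight lines with known slopes:
  # the lagged difference is exactly the slope (lag 1)
  slopes <- c(0.31, 0.72, 0.44, 0.58, 0.36, 0.55, 0.49, 0.66, 0.41, 0.62)
  tt <- seq(0, 5, 0.25)
  sup <- make_courses(outer(slopes, tt), tt)
  ts <- trend_t_series(sup, lag = 1)
  oracle <- stats::t.test(slopes)$statistic  # independent reference
  expect_equal(unique(round(ts$t, 10)), round(unname(oracle), 10))
  expect_equal(unique(ts$df), 9L)
  # centres exclude the half-lag margins
  expect_equal(min(ts$time_s), 0.5)
  expect_equal(max(ts$time_s), 4.5)

  # constant courses give t = 0 everywhere
  flat <- make_courses(matrix(1.3, 5, length(tt)), tt)
  expect_true(all(trend_t_series(flat, lag = 1)$t == 0))

  # identical nonzero slopes: zero-variance sentinel +Inf
  same <- make_courses(outer(rep(1, 5), tt), tt)
  expect_true(all(trend_t_series(same, lag = 1)$t == Inf))

  expect_error(trend_t_series(sup[sup$participant %in% c("P001", "P002"), ]),
               "3 participants")
  expect_error(trend_t_series(sup, lag = 0), "lag")
})

test_that("cluster finding returns maximal adjacent supra-threshold runs", {
  mk <- function(t) tibble::tibble(time_s = seq_along(t) - 1, t = t, df = 10L)
  thr_to_alpha <- function(thr, df) 1 - stats::pt(thr, df)  # threshold 2 exactly

  cl <- find_clusters(mk(c(0, 3, 3, 3, 0)), thr_to_alpha(2, 10))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$summed_t, 9)
  expect_equal(c(cl$start_s, cl$end_s), c(1, 3))

  expect_equal(nrow(find_clusters(mk(c(1, 0.5, -2, 1.9, 0)),
                                  thr_to_alpha(2, 10))), 0)

  cl2 <- find_clusters(mk(c(3, 0, 3)), thr_to_alpha(2, 10))
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$summed_t, c(3, 3))

  # two-sided: sign-consistent clusters on both tails
  cl3 <- find_clusters(mk(c(3, 3, -3, -3, 0)), thr_to_alpha(2, 10),
                       sidedness = "two_sided")
  expect_equal(sort(cl3$summed_t), c(-6, 6))
  expect_error(find_clusters(mk(numeric(0)), 0.05), "Empty")
})

test_that("the increase test is deterministic, seed-sensitive and offset-invariant", {
  set.seed(14)
  tt <- seq(0, 5, 0.1)
  m <- outer(rep(1, 8), 1.2 * (1 - exp(-tt / 1.5))) +
    matrix(rnorm(8 * length(tt), sd = 0.3), 8)
  sup <- make_courses(m, tt)

  r1 <- cluster_test_increase(sup, n_permutations = 200, seed = 5)
  r2 <- cluster_test_increase(sup, n_permutations = 200, seed = 5)
  expect_identical(r1$null_max_summed_t, r2$null_max_summed_t)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- cluster_test_increase(sup, n_permutations = 200, seed = 6)
  expect_false(identical(r1$null_max_summed_t, r3$null_max_summed_t))

  # adding a common constant changes nothing
  r4 <- cluster_test_increase(make_courses(m + 7, tt),
                              n_permutations = 200, seed = 5)
  keep <- c("start_s", "end_s", "n_points", "significant")
  expect_equal(tidy(r4)[keep], tidy(r1)[keep])
  expect_equal(tidy(r4)$summed_t, tidy(r1)$summed_t, tolerance = 1e-10)
  expect_equal(r4$critical_value, r1$critical_value)

  # a strong programmed rise is detected and covers early stimulation
  expect_gte(sum(r1$clusters$significant), 1)
  expect_lt(min(r1$clusters$start_s[r1$clusters$significant]), 1.5)
  expect_error(cluster_test_increase(sup, n_permutations = 50), "100")
})

test_that("the group test separates offset groups and accepts identical ones", {
  tt <- seq(0, 5, 0.1)
  set.seed(22)
  base <- outer(rep(1, 6), rep(1, length(tt)))
  noise <- function() matrix(rnorm(6 * length(tt), sd = 0.01), 6)
  gA <- make_courses(base + 3 + noise(), tt)
  gB <- make_courses(base + noise(), tt)
  res <- cluster_test_groups(gA, gB, n_permutations = 300, seed = 2)
  sig <- res$clusters[res$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$start_s, 0)
  expect_equal(sig$end_s, 5)
  expect_equal(range(significant_timepoints(res)), c(0, 5))
  expect_equal(significant_until(res), 5)

  # identical data in both groups: t = 0 everywhere, no clusters
  res0 <- cluster_test_groups(gA, gA, n_permutations = 300, seed = 2)
  expect_equal(nrow(res0$clusters), 0)
  expect_true(is.na(significant_until(res0)))

  # common offset to both groups changes nothing
  res_off <- cluster_test_groups(
    dplyr::mutate(gA, ratio_db = ratio_db + 11),
    dplyr::mutate(gB, ratio_db = ratio_db + 11),
    n_permutations = 300, seed = 2)
  expect_equal(tidy(res_off), tidy(res))

  expect_error(cluster_test_groups(gA[gA$participant == "P001", ], gB),
               "at least 2")
  expect_error(cluster_test_groups(gA, dplyr::mutate(gB, time_s = time_s + 0.05)),
               "different time grids")
})

test_that("sign-flip null max statistics are exchangeable with the observed one", {
  # under the null, the observed max cluster stat should be uniformly
  # ranked within its own permutation distribution
  set.seed(77)
  tt <- seq(0, 4, 0.25)
  ranks <- vapply(1:40, function(i) {
    m <- matrix(rnorm(6 * length(tt)), 6)
    r <- cluster_test_increase(make_courses(m, tt), n_permutations = 120,
                               seed = 1000 + i)
    obs <- if (nrow(r$clusters)) max(r$clusters$summed_t) else 0
    mean(r$null_max_summed_t <= obs)
  }, numeric(1))
  # ranks spread over [0, 1] rather than piling at either end
  expect_gt(mean(ranks > 0.5), 0.15)
  expect_lt(mean(ranks > 0.5), 0.85)
})
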