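test_that("the exclusion rule removes fast, slow, and incorrect trials", {
  pool <- tibble::tibble(
    observer_id = "o1", condition = "DC",
    rt_button_s = c(0.15, 0.25, 0.30, 0.35), correct = TRUE)
  ex <- exclude_trials(pool)
  expect_equal(ex$exclude_reason,
               c("rt_too_short", NA, NA, NA))
  expect_equal(sum(ex$kept), 3)

  # zero-variance boundary: rt > m + 3s is strict, so nothing is excluded
  flat <- tibble::tibble(observer_id = "o1", condition = "DC",
                         rt_button_s = rep(0.3, 4), correct = TRUE)
  expect_true(all(exclude_trials(flat)$kept))

  # incorrect trials are removed first and do not enter m and s
  mix <- tibble::tibble(observer_id = "o1", condition = "DC",
                        rt_button_s = c(0.3, 0.31, 0.32, 9),
                        correct = c(TRUE, TRUE, TRUE, FALSE))
  exm <- exclude_trials(mix)
  expect_equal(exm$exclude_reason[4], "incorrect")
  expect_true(all(exm$kept[1:3]))
})

test_that("exclusion matches a brute-force oracle on random pools", {
  set.seed(71)
  for (i in 1:1000) {
    pool <- random_pool(i)
    got <- exclude_trials(pool)$exclude_reason
    expect_identical(got, brute_force_exclude(pool))
  }
})

test_that("condition summaries report means, SEMs, and error rates", {
  pool <- tibble::tibble(
    observer_id = "o1", condition = "DC",
    rt_button_s = c(0.4, 0.6), correct = TRUE,
    gaze_reached_target = TRUE, gaze_rt_s = c(0.3, 0.4),
    first_saccade_x_deg = c(3, -3), target_side = "right")
  su <- summarize_conditions(exclude_trials(pool))
  expect_equal(su$mean_rt_button, 0.5)
  expect_equal(su$sem_rt_button, stats::sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(su$error_rate_button, 0)
  expect_equal(su$error_rate_first_saccade, 0.5)
  expect_equal(su$mean_rt_gaze, 0.35)

  # a pool whose gaze never reached the target has no gaze RT
  pool$gaze_reached_target <- FALSE
  su2 <- summarize_conditions(exclude_trials(pool))
  expect_true(is.na(su2$mean_rt_gaze))

  # an emptied pool is flagged instead of summarised
  pool$correct <- FALSE
  su3 <- summarize_conditions(exclude_trials(pool))
  expect_equal(su3$n_kept, 0)
  expect_true(is.na(su3$mean_rt_button))
  expect_equal(su3$error_rate_button, 1)
})

test_that("baseline normalisation divides within observer and family", {
  su <- summarize_conditions(exclude_trials(tibble::tibble(
    observer_id = rep(c("o1", "o2"), each = 4),
    condition = rep(c("baseline", "DC"), 4),
    O_mag = rep(c(0.2, 0.2, 0.6, 0.6), 2),
    rt_button_s = c(0.4, 0.8, 0.5, 0.25, 0.8, 1.6, 1.0, 0.5),
    correct = TRUE, gaze_reached_target = TRUE, gaze_rt_s = 0.3,
    first_saccade_x_deg = 3, target_side = "right")))
  norm <- normalize_by_baseline(su)
  expect_true(all(norm$normalized_rt[norm$condition == "baseline"] == 1))
  expect_equal(norm$normalized_rt[norm$condition == "DC" & norm$O_mag == 0.2],
               c(2, 2))  # equal ratios across observers with different RTs
  expect_equal(norm$normalized_rt[norm$condition == "DC" & norm$O_mag == 0.6],
               c(0.5, 0.5))

  expect_error(normalize_by_baseline(su[su$condition != "baseline", ]),
               "baseline")
})

test_that("first-saccade scoring uses side agreement with a dead zone", {
  trials <- tibble::tibble(
    first_saccade_x_deg = c(3, -3, 0.05, NA),
    target_side = c("right", "right", "right", "left"))
  expect_equal(first_saccade_error(trials), c(FALSE, TRUE, NA, NA))
})

test_that("gaze reach time is the first fixation within the radius", {
  gaze <- tibble::tibble(t_s = c(0, 0.3, 0.5),
                         x_deg = c(0, 5, 9), y_deg = c(0, 0, 1))
  expect_equal(gaze_reach_rt(gaze, 5, 0), 0.3)
  expect_true(is.na(gaze_reach_rt(gaze, -8, 0)))
  # reach time is weakly decreasing in the radius (set inclusion)
  radii <- seq(0.5, 3, by = 0.5)
  rts <- vapply(radii, function(r) gaze_reach_rt(gaze, 9.6, 1.2, r), 0)
  rts[is.na(rts)] <- Inf
  expect_true(all(diff(rts) <= 0))
})

test_that("median splits follow the documented tie rules and an oracle", {
  log <- tibble::tibble(target_disparity = c(0.2, -0.2, 0, NA),
                        median_disparity = c(0, 0, 0, 0),
                        target_csum = c(1.5, 0.5, 1, 1),
                        median_csum = c(1, 1, 1, NA))
  expect_equal(depth_split(log), c("far", "near", "near", NA))
  expect_equal(contrast_split(log), c("strong", "weak", "weak", NA))

  set.seed(91)
  rnd <- tibble::tibble(target_disparity = round(stats::runif(1000, -1, 1), 2),
                        median_disparity = round(stats::runif(1000, -1, 1), 2),
                        target_csum = round(stats::runif(1000, 0, 2), 2),
                        median_csum = round(stats::runif(1000, 0, 2), 2))
  oracle_depth <- ifelse(rnd$target_disparity > rnd$median_disparity,
                         "far", "near")
  oracle_con <- ifelse(rnd$target_csum > rnd$median_csum, "strong", "weak")
  expect_identical(depth_split(rnd), oracle_depth)
  expect_identical(contrast_split(rnd), oracle_con)

  # trial-level route: all-zero-disparity arrays are unlabelled
  cfg <- experiment_config("E1")  # no random depth in the default session
  tr <- generate_trial(cfg, "baseline", seed = 3)
  expect_true(is.na(depth_split(tr)))
})

test_that("the matched-sample t-test matches the closed form", {
  t0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
  expect_false(t0$significant)

  tsym <- paired_t(c(2, 0), c(1, 1))  # differences 1, -1 cancel
  expect_equal(tsym$statistic, 0)

  tdeg <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(tdeg$degenerate)
  expect_equal(tdeg$p.value, 0)
  expect_true(tdeg$significant)

  set.seed(13)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    got <- paired_t(a, b)
    want <- closed_form_paired_t(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
    expect_equal(got$df, n - 1)
  }

  td <- tidy(paired_t(c(1, 2, 4), c(0, 1, 2)))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "statistic", "df", "p.value",
                     "significant", "degenerate"))
  gl <- glance(paired_t(c(1, 2, 4), c(0, 1, 2)))
  expect_equal(gl$n, 3)
})

test_that("exclusion accounting is exact for a simulated cohort", {
  cfg <- experiment_config("E2")
  log <- simulate_cohort(cfg, 2, observer_preset("paper_like_E2"),
                         master_seed = 41)
  ex <- exclude_trials(log)
  counts <- dplyr::count(ex, .data$observer_id, .data$condition, .data$O_mag)
  expect_true(all(counts$n == 50))
  expect_equal(sum(ex$kept) + sum(!is.na(ex$exclude_reason)), nrow(log))
  # the pipeline is deterministic given a trial log
  expect_identical(summarize_conditions(ex),
                   summarize_conditions(exclude_trials(log)))
})
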