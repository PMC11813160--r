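# Synthetic cohort generator: determinism, degenerate configs, conservation
# invariants, truth consistency, and distributional sanity.

noiseless_config <- function(n = 3, seed = 1, ...) {
  cohort_config(
    n_participants = n, seed = seed,
    wear = list(gap_rate = 0, p_miss_day = 0),
    activity = list(budget_sd = c(very = 0, moderate = 0, light = 0)),
    sleep = list(onset_mean_min = 735, onset_sd_min = 0,
                 weekend_shift_min = 0, span_mean_h = 7.9, span_sd_h = 0,
                 restless_per_night = 0, wake_bouts_per_night = 0,
                 p_split = 0, p_nap = 0, p_late = 0),
    ...)
}

test_that("the same seed reproduces the cohort exactly; different seeds differ", {
  s1 <- generate_cohort(cohort_config(n_participants = 4, seed = 99))
  s2 <- generate_cohort(cohort_config(n_participants = 4, seed = 99))
  expect_identical(s1$grids, s2$grids)
  expect_identical(as.data.frame(s1$truth$nights),
                   as.data.frame(s2$truth$nights))
  s3 <- generate_cohort(cohort_config(n_participants = 4, seed = 100))
  expect_false(identical(s1$grids, s3$grids))
  # participant substreams: the first participants of a larger cohort are
  # the same as a smaller cohort's
  s4 <- generate_cohort(cohort_config(n_participants = 2, seed = 99))
  expect_identical(s1$grids[[1]], s4$grids[[1]])
})

test_that("a noiseless config yields 1440 wear minutes per day and identical nights", {
  sim <- generate_cohort(noiseless_config(n = 2))
  for (id in names(sim$grids)) {
    wd <- compute_wear_days(sim$grids[[id]])
    full_days <- wd[1:8, ]  # the 8 protocol days (a spill-over morning follows)
    expect_true(all(full_days$wear_minutes == 1440))
  }
  n <- sim$truth$nights
  expect_equal(nrow(n), 16)
  expect_true(all(n$span_minutes == round(7.9 * 60)))
  expect_true(all(n$waso_minutes == 0))
  onsets_ax <- n$onset_idx - (as.numeric(n$night_key) * 1440 + 720)
  expect_true(all(onsets_ax == 735))
})

test_that("a p_late = 1 cohort has every onset between 06:00 and 18:00", {
  sim <- generate_cohort(cohort_config(n_participants = 3, seed = 5,
                                       sleep = list(p_late = 1)))
  n <- sim$truth$nights
  expect_true(all(n$is_late_onset))
  onset_ax <- n$onset_idx - (as.numeric(n$night_key) * 1440 + 720)
  # axis 1080..1800 is 06:00..18:00 of the following day
  expect_true(all(onset_ax >= 1080 & onset_ax < 1800))
})

test_that("wear + nonwear minutes conserve to 1440 on every generated day", {
  sim <- generate_cohort(cohort_config(n_participants = 5, seed = 12))
  for (id in names(sim$grids)) {
    g <- sim$grids[[id]]
    idx <- minute_index(g$timestamp)
    days <- unique(wearminute:::index_date(idx))
    for (dn in as.numeric(days[-length(days)])) {  # full days; last is partial
      d0 <- as.integer(dn * 1440)
      sel <- idx >= d0 & idx < d0 + 1440
      worn <- sum(!is.na(g$heart_rate[sel]))
      nonwear <- sum(is.na(g$heart_rate[sel]))
      expect_equal(worn + nonwear, 1440)
    }
  }
})

test_that("every stage-labeled minute lies inside a truth sleep or nap interval", {
  sim <- generate_cohort(cohort_config(n_participants = 6, seed = 31))
  for (id in names(sim$grids)) {
    g <- sim$grids[[id]]
    idx <- minute_index(g$timestamp)
    labeled <- idx[!is.na(g$sleep_stage)]
    tn <- dplyr::filter(sim$truth$nights, participant_id == id)
    tp <- dplyr::filter(sim$truth$naps, participant_id == id)
    covered <- rep(FALSE, length(labeled))
    for (k in seq_len(nrow(tn))) {
      covered <- covered |
        (labeled >= tn$onset_idx[k] & labeled < tn$wake_idx[k])
    }
    for (k in seq_len(nrow(tp))) {
      covered <- covered |
        (labeled >= tp$start_idx[k] & labeled < tp$end_idx[k])
    }
    expect_true(all(covered))
    # and no labels on nonwear minutes
    expect_true(all(!is.na(g$heart_rate[!is.na(g$sleep_stage)])))
  }
})

test_that("generated night spans match the configured mean within 3 standard errors", {
  sim <- generate_cohort(cohort_config(n_participants = 60, seed = 77))
  spans <- sim$truth$nights$span_minutes / 60
  se <- stats::sd(spans) / sqrt(length(spans))
  expect_lt(abs(mean(spans) - 7.9), 3 * se)
})

test_that("infeasible or invalid configs error before generation", {
  expect_error(cohort_config(sleep = list(span_mean_h = 20, span_sd_h = 2)),
               "infeasible")
  expect_error(cohort_config(sleep = list(p_nap = 1.4)), "probabilities")
  expect_error(cohort_config(sleep = list(onset_sd_min = -3)),
               "standard deviations")
  expect_error(cohort_config(activity = list(
    budget_mean = c(very = 800, moderate = 500, light = 400))),
    "1440")
})

test_that("truth_summary matches a hand computation on a hand-written truth", {
  # 3 nights for one participant: Mon, Fri, Sat starting 2021-03-01;
  # onsets 23:00 / 00:30(+1) / 01:00(+1); spans 8h / 9h / 7h.
  key <- as.Date(c("2021-03-01", "2021-03-05", "2021-03-06"))
  onset_ax <- c(660, 750, 780)
  span <- c(480L, 540L, 420L)
  onset_idx <- as.numeric(key) * 1440 + 720 + onset_ax
  nights <- tibble::tibble(
    participant_id = "X", night_key = key,
    onset_idx = onset_idx, wake_idx = onset_idx + span,
    span_minutes = span, stage3_minutes = c(30L, 0L, 12L),
    restless_minutes = 0L, gap_minutes = c(0L, 6L, 0L),
    waso_minutes = c(30L, 6L, 12L),
    is_late_onset = FALSE, is_weekend_night = c(FALSE, TRUE, TRUE))
  days <- tibble::tibble(
    participant_id = "X",
    date = as.Date("2021-03-01") + 0:6,
    wear_minutes = c(1300L, 1200L, 100L, 1440L, 1350L, 1250L, 900L),
    total_steps = c(8000L, 9000L, 50L, 10000L, 7000L, 8500L, 9500L),
    minutes_very = 20L, minutes_moderate = 25L, minutes_light = 200L,
    minutes_awake_sedentary = 500L)
  truth <- list(nights = nights, days = days, naps = tibble::tibble())
  ts <- truth_summary(truth, cutoff = 600, min_days = 1)
  # day 3 (100 min) is invalid; 6 valid days remain
  expect_equal(ts$n_valid_days, 6)
  expect_equal(ts$true_mean_steps, mean(c(8000, 9000, 10000, 7000, 8500, 9500)))
  # nights anchored on valid days: all three (Mar 1, 5, 6 are valid)
  expect_equal(ts$n_nights, 3)
  expect_equal(ts$true_mean_span_hours, mean(span) / 60)
  expect_equal(ts$true_mean_waso_hours, mean(c(30, 6, 12)) / 60)
  # midpoints: wd 660+240=900; we (750+270, 780+210) = (1020, 990)
  expect_equal(ts$true_social_jet_lag_hours, abs(mean(c(1020, 990)) - 900) / 60)
  # one night, onset 23:00 wake 07:00 -> true span 8 h
  one <- truth_summary(list(nights = nights[1, ], days = days,
                            naps = tibble::tibble()), cutoff = 600,
                       min_days = 1)
  expect_equal(one$true_mean_span_hours, 8)
  expect_true(is.na(one$true_social_jet_lag_hours))  # no weekend night
})
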