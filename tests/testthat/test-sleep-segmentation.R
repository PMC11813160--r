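# Sleep-cycle extraction and main-sleep-period identification.

test_that("cycles are maximal runs of labeled minutes", {
  g <- make_grid(TS0, 40)
  g$sleep_stage[11:20] <- 1L  # minutes 10-19
  g$sleep_stage[26:31] <- 2L  # minutes 25-30
  cyc <- extract_sleep_cycles(g)
  expect_equal(nrow(cyc), 2)
  expect_equal(as.numeric(cyc$start - TS0, units = "mins"), c(10, 25))
  expect_equal(as.numeric(cyc$end - TS0, units = "mins"), c(20, 31))
  expect_equal(cyc$n_minutes, c(10L, 6L))
  expect_identical(cyc$stages[[1]], rep(1L, 10))

  expect_equal(nrow(extract_sleep_cycles(make_grid(TS0, 30))), 0)
})

test_that("random label masks match a brute-force run scan", {
  set.seed(21)
  for (rep_i in 1:30) {
    n <- sample(50:300, 1)
    st <- sample(c(NA, 1L, 2L, 3L), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.1, 0.1))
    g <- make_grid(TS0, n, sleep_stage = st)
    cyc <- extract_sleep_cycles(g)
    oracle <- brute_runs(minute_index(g$timestamp), st)
    expect_equal(nrow(cyc), nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_equal(minute_index(cyc$start), oracle$start)
      expect_equal(minute_index(cyc$end), oracle$end)
    }
  }
})

night_grid <- function(...) {
  # grid spanning 2021-03-01 12:00 .. 2021-03-02 18:00 with staged intervals
  g <- make_grid(ts_at("2021-03-01 12:00"), 30 * 60)
  for (iv in list(...)) {
    g <- set_stages(g, ts_at(iv[[1]]), ts_at(iv[[2]]),
                    if (length(iv) > 2) iv[[3]] else 1L)
  }
  g
}

test_that("cycles inside the 18:00-06:00 window merge into one main period", {
  g <- night_grid(list("2021-03-01 23:00", "2021-03-02 02:00"),
                  list("2021-03-02 02:30", "2021-03-02 07:10"))
  p <- identify_main_sleep(extract_sleep_cycles(g), as.Date("2021-03-01"))
  expect_equal(p$onset, ts_at("2021-03-01 23:00"))
  expect_equal(p$wake, ts_at("2021-03-02 07:10"))
  expect_equal(p$n_cycles, 2)
  expect_false(p$is_late_onset)

  # single cycle is its own period
  g1 <- night_grid(list("2021-03-01 22:00", "2021-03-02 06:30"))
  p1 <- identify_main_sleep(extract_sleep_cycles(g1), as.Date("2021-03-01"))
  expect_equal(p1$onset, ts_at("2021-03-01 22:00"))
  expect_equal(p1$wake, ts_at("2021-03-02 06:30"))
  expect_equal(p1$n_cycles, 1)
})

test_that("an onset exactly at 06:00 is outside the night window", {
  g <- night_grid(list("2021-03-02 06:00", "2021-03-02 09:00"))
  p <- identify_main_sleep(extract_sleep_cycles(g), as.Date("2021-03-01"))
  # no window sleep -> the 06:00 cycle is found by the late-onset fallback
  expect_true(p$is_late_onset)
  g2 <- night_grid(list("2021-03-02 05:59", "2021-03-02 09:00"))
  p2 <- identify_main_sleep(extract_sleep_cycles(g2), as.Date("2021-03-01"))
  expect_false(p2$is_late_onset)
})

test_that("the post-06:00 fallback seeds on the longest cycle and chains within 60 minutes", {
  g <- night_grid(list("2021-03-02 09:00", "2021-03-02 13:00"),
                  list("2021-03-02 13:30", "2021-03-02 14:00"))
  p <- identify_main_sleep(extract_sleep_cycles(g), as.Date("2021-03-01"))
  expect_true(p$is_late_onset)
  expect_equal(p$onset, ts_at("2021-03-02 09:00"))
  expect_equal(p$wake, ts_at("2021-03-02 14:00"))

  # a cycle further than the chaining threshold is not absorbed
  g2 <- night_grid(list("2021-03-02 09:00", "2021-03-02 13:00"),
                   list("2021-03-02 14:30", "2021-03-02 15:00"))
  p2 <- identify_main_sleep(extract_sleep_cycles(g2), as.Date("2021-03-01"))
  expect_equal(p2$wake, ts_at("2021-03-02 13:00"))

  # nothing anywhere -> no period
  expect_null(identify_main_sleep(
    extract_sleep_cycles(make_grid(TS0, 100)), as.Date("2021-03-01")))
})

test_that("naps after the main period's wake are excluded and surface as naps", {
  g <- make_grid(ts_at("2021-03-01 12:00"), 30 * 60)
  g <- set_stages(g, ts_at("2021-03-01 23:00"), ts_at("2021-03-02 07:00"))
  g <- set_stages(g, ts_at("2021-03-02 14:00"), ts_at("2021-03-02 15:00"))
  cyc <- extract_sleep_cycles(g)
  p <- identify_main_sleep(cyc, as.Date("2021-03-01"))
  expect_equal(p$wake, ts_at("2021-03-02 07:00"))
  expect_equal(p$n_cycles, 1)

  periods <- main_sleep_periods(cyc)
  expect_equal(nrow(periods), 1)
  naps <- attr(periods, "naps")
  expect_equal(nrow(naps), 1)
  expect_equal(naps$start, ts_at("2021-03-02 14:00"))
})

test_that("multi-night decomposition assigns each cycle to exactly one night", {
  g <- make_grid(ts_at("2021-03-01 12:00"), 3 * 1440)
  g <- set_stages(g, ts_at("2021-03-01 23:30"), ts_at("2021-03-02 07:00"))
  g <- set_stages(g, ts_at("2021-03-02 13:00"), ts_at("2021-03-02 14:00"))
  g <- set_stages(g, ts_at("2021-03-03 00:15"), ts_at("2021-03-03 08:05"))
  periods <- main_sleep_periods(extract_sleep_cycles(g))
  expect_equal(nrow(periods), 2)
  expect_equal(periods$night_key, as.Date(c("2021-03-01", "2021-03-02")))
  expect_equal(periods$onset,
               c(ts_at("2021-03-01 23:30"), ts_at("2021-03-03 00:15")))
  expect_equal(nrow(attr(periods, "naps")), 1)
  # determinism
  periods2 <- main_sleep_periods(extract_sleep_cycles(g))
  expect_identical(as.data.frame(periods[1:6]), as.data.frame(periods2[1:6]))
})

test_that("window membership matches the brute-force merge on random nights", {
  set.seed(33)
  key <- as.Date("2021-03-01")
  for (rep_i in 1:40) {
    g <- make_grid(ts_at("2021-03-01 12:00"), 30 * 60)
    n_iv <- sample(0:4, 1)
    if (n_iv > 0) {
      starts <- sort(sample(0:(30 * 60 - 61), n_iv))
      for (s in starts) {
        len <- sample(10:300, 1)
        g$sleep_stage[(s + 1):min(s + len, 30 * 60)] <-
          sample(c(1L, 2L, 3L), 1)
      }
    }
    cyc <- extract_sleep_cycles(g)
    p <- identify_main_sleep(cyc, key)
    oracle <- brute_rule_a(minute_index(g$timestamp), g$sleep_stage, key)
    if (is.null(oracle)) {
      expect_true(is.null(p) || p$is_late_onset)
    } else {
      expect_false(p$is_late_onset)
      expect_equal(minute_index(p$onset), oracle$onset)
      expect_equal(minute_index(p$wake), oracle$wake)
      expect_equal(p$n_cycles, oracle$n_cycles)
    }
  }
})
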