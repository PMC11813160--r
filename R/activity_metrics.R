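# Daily and participant-level physical-activity metrics on retained valid
# days. Total steps per day is unconditioned; steps/hour is restricted to
# wear minutes; awake sedentary time is sedentary-labeled minutes falling
# outside every detected sleep period and nap interval (a sleep period
# crossing midnight is excluded from both days it touches).

# union of [start_idx, end_idx) intervals hit by each minute index
in_any_interval <- function(idx, starts, ends) {
  if (length(starts) == 0) {
    return(rep(FALSE, length(idx)))
  }
  hit <- rep(FALSE, length(idx))
  for (k in seq_along(starts)) {
    hit <- hit | (idx >= starts[k] & idx < ends[k])
  }
  hit
}

#' Compute daily physical-activity metrics
#'
#' @param grid A `minute_grid` tibble for one participant.
#' @param dates `Date` vector of (retained, valid) days to compute.
#' @param sleep_periods Period tibble from [main_sleep_periods()] for this
#'   participant (may have zero rows); their `[onset, wake)` intervals are
#'   excluded from awake sedentary time.
#' @param naps Optional nap cycle tibble (columns `start`, `end`), likewise
#'   excluded from awake sedentary time.
#' @return Tibble with one row per date: `participant_id`, `date`,
#'   `wear_minutes`, `total_steps`, `steps_per_hour_wear`, `minutes_very`,
#'   `minutes_moderate`, `minutes_light`, `minutes_awake_sedentary`.
#' @export
compute_activity_day <- function(grid, dates, sleep_periods = NULL,
                                 naps = NULL) {
  idx <- minute_index(grid$timestamp)
  worn <- !is.na(grid$heart_rate) &
    grid$heart_rate >= HR_MIN & grid$heart_rate <= HR_MAX
  sl_starts <- integer(0)
  sl_ends <- integer(0)
  if (!is.null(sleep_periods) && nrow(sleep_periods) > 0) {
    sl_starts <- minute_index(sleep_periods$onset)
    sl_ends <- minute_index(sleep_periods$wake)
  }
  if (!is.null(naps) && nrow(naps) > 0) {
    sl_starts <- c(sl_starts, minute_index(naps$start))
    sl_ends <- c(sl_ends, minute_index(naps$end))
  }
  in_sleep <- in_any_interval(idx, sl_starts, sl_ends)

  rows <- purrr::map(as.list(as.Date(dates)), function(d) {
    d0 <- date_index(d)
    day <- idx >= d0 & idx < d0 + 1440L
    wear <- sum(worn & day)
    if (wear == 0) {
      abort(paste0("day ", format(d), " has zero wear minutes; ",
                   "activity metrics are only defined on valid days"))
    }
    steps <- grid$steps[day]
    steps_wear <- grid$steps[day & worn]
    intens <- grid$intensity[day]
    tibble(
      participant_id = grid$participant_id[1],
      date = d,
      wear_minutes = wear,
      total_steps = sum(steps, na.rm = TRUE),
      steps_per_hour_wear = sum(steps_wear, na.rm = TRUE) / (wear / 60),
      minutes_very = sum(intens == "very_active", na.rm = TRUE),
      minutes_moderate = sum(intens == "moderately_active", na.rm = TRUE),
      minutes_light = sum(intens == "lightly_active", na.rm = TRUE),
      minutes_awake_sedentary =
        sum(grid$intensity[day & !in_sleep] == "sedentary", na.rm = TRUE)
    )
  })
  bind_rows(rows)
}

#' Summarize a participant's activity across retained days
#'
#' Unweighted mean and sample SD of each daily metric.
#'
#' @param days Daily activity tibble from [compute_activity_day()] for one
#'   participant (5–9 rows).
#' @param min_days Minimum number of days required (default 5); fewer is an
#'   error, since callers should only pass retained valid days.
#' @return One-row tibble of participant-level means/SDs plus `n_days` and
#'   mean daily wear minutes.
#' @export
summarize_participant_activity <- function(days, min_days = 5L) {
  if (nrow(days) < min_days) {
    abort(paste0("participant has ", nrow(days), " activity days; at least ",
                 min_days, " retained valid days are required"))
  }
  tibble(
    participant_id = days$participant_id[1],
    n_days = nrow(days),
    mean_wear_minutes = mean(days$wear_minutes),
    sd_wear_minutes = sd(days$wear_minutes),
    mean_total_steps = mean(days$total_steps),
    sd_total_steps = sd(days$total_steps),
    mean_steps_per_hour = mean(days$steps_per_hour_wear),
    sd_steps_per_hour = sd(days$steps_per_hour_wear),
    mean_minutes_very = mean(days$minutes_very),
    sd_minutes_very = sd(days$minutes_very),
    mean_minutes_moderate = mean(days$minutes_moderate),
    sd_minutes_moderate = sd(days$minutes_moderate),
    mean_minutes_light = mean(days$minutes_light),
    sd_minutes_light = sd(days$minutes_light),
    mean_minutes_awake_sedentary = mean(days$minutes_awake_sedentary),
    sd_minutes_awake_sedentary = sd(days$minutes_awake_sedentary)
  )
}
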