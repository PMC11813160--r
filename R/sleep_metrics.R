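# Per-night and per-participant sleep metrics.
#
# Within a main sleep period [onset, wake):
#   asleep minutes  = stage-1 plus (by default) stage-2 "restless" minutes;
#   awake minutes   = stage-3 minutes plus unlabeled gap minutes between the
#                     merged cycles;
#   WASO            = awake minutes, in hours;
#   efficiency      = asleep minutes / (wake - onset)   (span denominator);
#   midpoint        = (onset + wake)/2 on the noon-anchored clock axis.
# "Sleep duration" is the onset-to-wake span: efficiency divides asleep time
# by this span, so a night with any wakefulness has efficiency < 1.

# per-minute stage vector over [onset, wake); NA marks inter-cycle gaps
period_stage_vector <- function(period_row) {
  onset <- minute_index(period_row$onset)
  wake <- minute_index(period_row$wake)
  stages <- rep(NA_integer_, wake - onset)
  cyc <- period_row$cycles[[1]]
  for (i in seq_len(nrow(cyc))) {
    s <- minute_index(cyc$start[i]) - onset
    stages[(s + 1L):(s + cyc$n_minutes[i])] <- cyc$stages[[i]]
  }
  stages
}

#' Compute per-night sleep metrics from main sleep periods
#'
#' @param periods Period tibble from [identify_main_sleep()] or
#'   [main_sleep_periods()] (one or more rows).
#' @param restless_as_awake If `TRUE`, stage-2 (restless) minutes count as
#'   wakefulness (added to WASO, removed from asleep time). Default `FALSE`:
#'   restless is treated as sleep, distinct from the explicit awake stage.
#' @return Tibble with one row per night: `participant_id`, `night_key`,
#'   `onset`, `wake`, `span_hours`, `asleep_minutes`, `awake_minutes`,
#'   `waso_hours`, `efficiency` (in \[0, 1\]), `midpoint_min` (noon-anchored
#'   axis, see [noon_axis_minutes()]), `onset_min`, `wake_min` (same axis),
#'   `is_weekend_night`, `is_late_onset`.
#' @export
compute_night_metrics <- function(periods, restless_as_awake = FALSE) {
  stopifnot(nrow(periods) >= 0)
  rows <- purrr::map(seq_len(nrow(periods)), function(i) {
    p <- periods[i, , drop = FALSE]
    stopifnot(p$onset < p$wake)
    stages <- period_stage_vector(p)
    span_min <- length(stages)
    asleep_codes <- if (restless_as_awake) STAGE_ASLEEP else
      c(STAGE_ASLEEP, STAGE_RESTLESS)
    asleep <- sum(stages %in% asleep_codes)
    awake <- span_min - asleep
    onset_ax <- noon_axis_minutes(p$onset, p$night_key)
    wake_ax <- noon_axis_minutes(p$wake, p$night_key)
    tibble(
      participant_id = p$participant_id,
      night_key = p$night_key,
      onset = p$onset,
      wake = p$wake,
      span_hours = span_min / 60,
      asleep_minutes = asleep,
      awake_minutes = awake,
      waso_hours = awake / 60,
      efficiency = asleep / span_min,
      onset_min = onset_ax,
      wake_min = wake_ax,
      midpoint_min = (onset_ax + wake_ax) / 2,
      is_weekend_night = is_weekend_key(p$night_key),
      is_late_onset = p$is_late_onset
    )
  })
  if (length(rows) == 0) {
    return(tibble(participant_id = character(),
                  night_key = as.Date(character()),
                  onset = index_time(integer()), wake = index_time(integer()),
                  span_hours = numeric(), asleep_minutes = integer(),
                  awake_minutes = integer(), waso_hours = numeric(),
                  efficiency = numeric(), onset_min = numeric(),
                  wake_min = numeric(), midpoint_min = numeric(),
                  is_weekend_night = logical(), is_late_onset = logical()))
  }
  bind_rows(rows)
}

#' Social jet lag from nightly midpoints
#'
#' Absolute difference, in hours, between the mean weekend-night midpoint
#' (Friday and Saturday nights) and the mean weekday-night midpoint
#' (Sunday–Thursday nights), both on the noon-anchored axis.
#'
#' @param nights Night-metric tibble from [compute_night_metrics()] for one
#'   participant.
#' @return Social jet lag in hours (non-negative), or `NA_real_` when the
#'   participant has no weekend night or no weekday night — the metric is
#'   absent, not zero.
#' @export
social_jet_lag <- function(nights) {
  wk <- nights$midpoint_min[!nights$is_weekend_night]
  we <- nights$midpoint_min[nights$is_weekend_night]
  if (length(wk) == 0 || length(we) == 0) {
    return(NA_real_)
  }
  abs(mean(we) - mean(wk)) / 60
}

#' Summarize a participant's sleep across retained nights
#'
#' Means and sample SDs of the night metrics on the noon-anchored clock
#' axis; classifies the participant by whether their mean sleep onset falls
#' before or after midnight (mean onset at exactly 00:00 counts as
#' after-midnight).
#'
#' @param nights Night metrics for one participant.
#' @param min_nights,max_nights Number of nights required/retained
#'   (defaults 5 and 9; nights beyond `max_nights` are dropped from the end
#'   of the chronological sequence).
#' @return A one-row tibble of participant-level sleep summaries, or `NULL`
#'   when fewer than `min_nights` nights are available (the participant is
#'   excluded from sleep summaries, not an error).
#' @export
summarize_participant_sleep <- function(nights, min_nights = 5L,
                                        max_nights = 9L) {
  if (is.null(nights) || nrow(nights) < min_nights) {
    return(NULL)
  }
  nights <- nights %>% arrange(.data$night_key) %>% head(max_nights)
  mean_onset <- mean(nights$onset_min)
  tibble(
    participant_id = nights$participant_id[1],
    n_nights = nrow(nights),
    mean_span_hours = mean(nights$span_hours),
    sd_span_hours = sd(nights$span_hours),
    mean_efficiency = mean(nights$efficiency),
    mean_waso_hours = mean(nights$waso_hours),
    mean_onset_min = mean_onset,
    sd_onset_hours = sd(nights$onset_min) / 60,
    mean_wake_min = mean(nights$wake_min),
    sd_wake_hours = sd(nights$wake_min) / 60,
    mean_midpoint_min = mean(nights$midpoint_min),
    onset_clock = clock_label(mean_onset),
    wake_clock = clock_label(mean(nights$wake_min)),
    social_jet_lag_hours = social_jet_lag(nights),
    onset_group = if (mean_onset >= 720) "after_midnight" else
      "before_midnight"
  )
}

#' Sleep summaries for a cohort
#'
#' Runs segmentation and per-night metrics for each grid, keeps nights whose
#' `night_key` is among that participant's retained valid wear days, and
#' summarizes participants with enough nights.
#'
#' @param grids Named list of `minute_grid` tibbles.
#' @param retained_dates Optional named list (by participant id) of `Date`
#'   vectors of retained valid days; nights anchored outside them are
#'   dropped. `NULL` keeps all nights.
#' @param late_merge_gap_min,restless_as_awake See
#'   [identify_main_sleep()] and [compute_night_metrics()].
#' @param min_nights,max_nights See [summarize_participant_sleep()].
#' @return List with `periods`, `nights`, `participants` tibbles, `naps`
#'   (named list of unabsorbed nap cycles per participant) and `skipped`:
#'   ids of participants with sleep data but fewer than `min_nights`
#'   retained nights.
#' @export
summarize_cohort_sleep <- function(grids, retained_dates = NULL,
                                   late_merge_gap_min = 60,
                                   restless_as_awake = FALSE,
                                   min_nights = 5L, max_nights = 9L) {
  periods_l <- list()
  nights_l <- list()
  parts_l <- list()
  naps_l <- list()
  skipped <- character()
  for (id in names(grids)) {
    cycles <- extract_sleep_cycles(grids[[id]])
    periods <- main_sleep_periods(cycles,
                                  late_merge_gap_min = late_merge_gap_min)
    naps_l[[id]] <- attr(periods, "naps")
    if (nrow(periods) == 0) next
    nights <- compute_night_metrics(periods,
                                    restless_as_awake = restless_as_awake)
    if (!is.null(retained_dates)) {
      keep <- nights$night_key %in% as.Date(retained_dates[[id]])
      nights <- nights[keep, , drop = FALSE]
    }
    periods_l[[id]] <- periods
    if (nrow(nights) == 0) next
    nights_l[[id]] <- nights
    summ <- summarize_participant_sleep(nights, min_nights, max_nights)
    if (is.null(summ)) {
      skipped <- c(skipped, id)
    } else {
      parts_l[[id]] <- summ
    }
  }
  list(
    periods = bind_rows(periods_l),
    nights = bind_rows(nights_l),
    participants = bind_rows(parts_l),
    naps = naps_l,
    skipped = skipped
  )
}
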