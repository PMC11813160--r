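# Wear-time validation. Heart-rate presence is the wear proxy: a minute
# counts as worn iff it carries a physiologically plausible heart-rate value
# (20-250 bpm); days are calendar midnight-to-midnight.

HR_MIN <- 20L
HR_MAX <- 250L

#' Compute per-day wear time from heart-rate presence
#'
#' A minute is wear time iff its heart rate is present and within
#' \[20, 250\] bpm; anything else (absent or implausible) is nonwear. One row
#' is produced for every calendar day intersecting the grid, including
#' partial first/last days, each judged by the same thresholds.
#'
#' @param grid A `minute_grid` tibble (one participant).
#' @param cutoffs Integer vector of valid-day wear-minute thresholds; the
#'   defaults yield the `valid_600` (>= 10 h worn) and `valid_1200`
#'   (>= 20 h worn) flags.
#' @return Tibble with one row per day: `participant_id`, `date`,
#'   `wear_minutes`, and a logical `valid_<cutoff>` column per cutoff.
#' @export
compute_wear_days <- function(grid, cutoffs = c(600L, 1200L)) {
  stopifnot(nrow(grid) > 0)
  worn <- !is.na(grid$heart_rate) &
    grid$heart_rate >= HR_MIN & grid$heart_rate <= HR_MAX
  date <- index_date(minute_index(grid$timestamp))
  days <- tibble(date = date, worn = worn) %>%
    group_by(.data$date) %>%
    summarise(wear_minutes = sum(.data$worn), .groups = "drop") %>%
    mutate(participant_id = grid$participant_id[1], .before = 1)
  for (co in cutoffs) {
    days[[paste0("valid_", co)]] <- days$wear_minutes >= co
  }
  days
}

#' Classify a participant's validity under a wear cutoff
#'
#' A participant is valid under a cutoff when at least `min_days` of their
#' calendar days meet it. Analyses retain the earliest `max_days` valid days
#' (participants wearing the device longer than the requested ~1 week are
#' truncated to the protocol window rather than excluded).
#'
#' @param wear_days Output of [compute_wear_days()] for one participant.
#' @param cutoff Wear-minute threshold, typically 600 or 1200.
#' @param min_days,max_days Valid-day range defining an includable
#'   participant (defaults 5 and 9).
#' @return A one-row tibble: `participant_id`, `cutoff`, `n_valid_days`,
#'   `is_valid`, and `retained_dates` (list column of the retained `Date`s;
#'   empty when invalid).
#' @export
classify_participant <- function(wear_days, cutoff = 600L,
                                 min_days = 5L, max_days = 9L) {
  stopifnot(length(unique(wear_days$participant_id)) == 1)
  col <- paste0("valid_", cutoff)
  if (!col %in% names(wear_days)) {
    wear_days[[col]] <- wear_days$wear_minutes >= cutoff
  }
  valid_dates <- sort(wear_days$date[wear_days[[col]]])
  n_valid <- length(valid_dates)
  is_valid <- n_valid >= min_days
  retained <- if (is_valid) head(valid_dates, max_days) else as.Date(character())
  tibble(
    participant_id = wear_days$participant_id[1],
    cutoff = as.integer(cutoff),
    n_valid_days = n_valid,
    n_retained_days = length(retained),
    is_valid = is_valid,
    retained_dates = list(retained)
  )
}

#' Validity table for a whole cohort
#'
#' Applies [compute_wear_days()] and [classify_participant()] across a list
#' of minute grids, for each requested cutoff.
#'
#' @param grids Named list of `minute_grid` tibbles.
#' @param cutoffs Integer vector of wear cutoffs.
#' @inheritParams classify_participant
#' @return List with `wear_days` (row-bound day table) and `participants`
#'   (one row per participant x cutoff).
#' @export
validate_cohort <- function(grids, cutoffs = c(600L, 1200L),
                            min_days = 5L, max_days = 9L) {
  wd_list <- purrr::map(grids, compute_wear_days, cutoffs = cutoffs)
  participants <- purrr::map(wd_list, function(wd) {
    purrr::map(cutoffs, ~ classify_participant(wd, .x, min_days, max_days)) %>%
      bind_rows()
  }) %>% bind_rows()
  list(wear_days = bind_rows(wd_list), participants = participants)
}
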