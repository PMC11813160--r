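# Cohort-level aggregation: participant summaries -> descriptive tables
# (activity and sleep, by stratum), attrition flow counts, a figure-ready
# clock matrix of how many participants are asleep per 15-minute interval,
# and the end-to-end pipeline driver.

summarise_stratum <- function(df, cols, stratum) {
  purrr::map(cols, function(cl) {
    x <- df[[cl]]
    x <- x[!is.na(x)]
    tibble(stratum = stratum, metric = cl, n = length(x),
           mean = if (length(x)) mean(x) else NA_real_,
           sd = if (length(x) > 1) sd(x) else NA_real_)
  }) %>% bind_rows()
}

#' Build cohort descriptive tables
#'
#' Unweighted cross-participant means and sample (n-1) SDs per stratum.
#' Activity strata: overall plus, when `metadata` supplies a `sex` column,
#' one stratum per sex. Sleep strata: overall plus the before-/after-
#' midnight onset groups. Empty strata yield rows with `n = 0` and absent
#' statistics.
#'
#' @param activity Participant activity summaries
#'   ([summarize_participant_activity()] rows).
#' @param sleep Participant sleep summaries
#'   ([summarize_participant_sleep()] rows).
#' @param metadata Optional tibble with `participant_id` plus attribute
#'   columns (e.g. `sex`) joined for stratification; never required.
#' @param nights Optional night-metric tibble (from
#'   [compute_night_metrics()]) used to build the 15-minute clock matrix;
#'   omitted when `NULL`.
#' @return List of tibbles: `table_activity`, `table_sleep`, and (when
#'   `nights` is given) `clock_matrix` with the mean number of participants
#'   asleep per onset group and 15-minute clock interval.
#' @export
build_cohort_tables <- function(activity, sleep, metadata = NULL,
                                nights = NULL) {
  act_cols <- c("n_days", "mean_wear_minutes", "mean_total_steps",
                "mean_steps_per_hour", "mean_minutes_very",
                "mean_minutes_moderate", "mean_minutes_light",
                "mean_minutes_awake_sedentary")
  slp_cols <- c("n_nights", "mean_span_hours", "mean_efficiency",
                "mean_waso_hours", "mean_onset_min", "mean_wake_min",
                "mean_midpoint_min", "social_jet_lag_hours")

  if (!is.null(metadata)) {
    activity <- activity %>% left_join(metadata, by = "participant_id")
  }
  table_activity <- summarise_stratum(activity, act_cols, "overall")
  if (!is.null(metadata) && "sex" %in% names(metadata)) {
    for (s in sort(unique(metadata$sex))) {
      table_activity <- bind_rows(
        table_activity,
        summarise_stratum(activity %>% filter(.data$sex == s), act_cols,
                          paste0("sex=", s)))
    }
  }

  table_sleep <- summarise_stratum(sleep, slp_cols, "overall")
  for (g in c("before_midnight", "after_midnight")) {
    table_sleep <- bind_rows(
      table_sleep,
      summarise_stratum(sleep %>% filter(.data$onset_group == g),
                        slp_cols, g))
  }

  out <- list(table_activity = table_activity, table_sleep = table_sleep)
  if (!is.null(nights) && nrow(sleep) > 0) {
    out$clock_matrix <- clock_matrix(nights, sleep)
  }
  out
}

#' Mean number of participants asleep per 15-minute clock interval
#'
#' For each onset group and each of the 96 quarter-hour intervals of the
#' 24-hour clock, sums over participants the fraction of their retained
#' nights during which the interval's midpoint lies inside the main sleep
#' period — a figure-ready polar-clock export.
#'
#' @param nights Night metrics (must carry `onset_min`, `wake_min`).
#' @param sleep Participant sleep summaries (for `onset_group`).
#' @return Tibble: `onset_group`, `clock_min` (interval start, minutes after
#'   midnight), `interval` ("HH:MM"), `n_asleep`.
#' @export
clock_matrix <- function(nights, sleep) {
  nights <- nights %>%
    left_join(sleep %>% select("participant_id", "onset_group"),
              by = "participant_id") %>%
    filter(!is.na(.data$onset_group))
  starts <- seq(0, 1425, by = 15)
  mids <- starts + 7.5
  rows <- list()
  for (g in c("before_midnight", "after_midnight")) {
    gn <- nights %>% filter(.data$onset_group == g)
    per_part <- gn %>% group_by(.data$participant_id) %>%
      summarise(frac = list({
        o <- .data$onset_min
        w <- .data$wake_min
        vapply(mids, function(t) {
          ax <- (t - 720) %% 1440
          mean((o <= ax & ax < w) | (o <= ax + 1440 & ax + 1440 < w))
        }, numeric(1))
      }), .groups = "drop")
    total <- if (nrow(per_part)) Reduce(`+`, per_part$frac) else
      rep(0, length(starts))
    rows[[g]] <- tibble(
      onset_group = g, clock_min = starts,
      interval = sprintf("%02d:%02d", starts %/% 60, starts %% 60),
      n_asleep = total)
  }
  bind_rows(rows)
}

#' Run the full minute-level pipeline
#'
#' Executes wear validation, sleep segmentation and metrics, activity
#' metrics, and cohort tables over a cohort of minute grids, under one
#' declared wear cutoff.
#'
#' @param input Either a named list of `minute_grid` tibbles or a directory
#'   containing canonical `minutes_<id>.csv` files.
#' @param cutoff Declared wear cutoff for retained days (600 or 1200).
#' @param cutoffs All cutoffs to report validity for (flow counts).
#' @param late_merge_gap_min,restless_as_awake Sleep options; see
#'   [identify_main_sleep()] and [compute_night_metrics()].
#' @param min_days,max_days Valid-day / valid-night retention rule.
#' @param metadata Optional per-participant attribute tibble.
#' @return List: `wear_days`, `participants` (validity), `activity_days`,
#'   `activity_participants`, `sleep_periods`, `sleep_nights`,
#'   `sleep_participants`, `tables` (from [build_cohort_tables()]),
#'   `flow_counts`, and the options used.
#' @export
run_pipeline <- function(input, cutoff = 600L, cutoffs = c(600L, 1200L),
                         late_merge_gap_min = 60, restless_as_awake = FALSE,
                         min_days = 5L, max_days = 9L, metadata = NULL) {
  grids <- if (is.character(input)) {
    paths <- sort(list.files(input, pattern = "^minutes_.*\\.csv$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      abort(paste0("no minutes_<id>.csv files found in ", input))
    }
    gl <- purrr::map(paths, read_minute_csv)
    setNames(gl, purrr::map_chr(gl, ~ .x$participant_id[1]))
  } else {
    input
  }
  grids <- grids[sort(names(grids))]
  cutoffs <- sort(unique(c(as.integer(cutoff), as.integer(cutoffs))))

  val <- validate_cohort(grids, cutoffs = cutoffs, min_days = min_days,
                         max_days = max_days)
  at_cutoff <- val$participants %>% filter(.data$cutoff == !!as.integer(cutoff))
  valid_ids <- at_cutoff$participant_id[at_cutoff$is_valid]
  retained <- setNames(at_cutoff$retained_dates, at_cutoff$participant_id)

  slp <- summarize_cohort_sleep(
    grids[valid_ids], retained_dates = retained[valid_ids],
    late_merge_gap_min = late_merge_gap_min,
    restless_as_awake = restless_as_awake,
    min_nights = min_days, max_nights = max_days)

  act_days <- list()
  act_parts <- list()
  for (id in valid_ids) {
    periods <- slp$periods %>% filter(.data$participant_id == id)
    days <- compute_activity_day(grids[[id]], retained[[id]],
                                 sleep_periods = periods,
                                 naps = slp$naps[[id]])
    act_days[[id]] <- days
    act_parts[[id]] <- summarize_participant_activity(days,
                                                      min_days = min_days)
  }
  activity_days <- bind_rows(act_days)
  activity_participants <- bind_rows(act_parts)

  tables <- build_cohort_tables(activity_participants, slp$participants,
                                metadata = metadata, nights = slp$nights)
  flow_counts <- tibble(
    stage = c("received",
              paste0("valid_", cutoffs),
              "sleep_5plus_nights"),
    n = c(length(grids),
          vapply(cutoffs, function(co) {
            sum(val$participants$is_valid[val$participants$cutoff == co])
          }, numeric(1)),
          nrow(slp$participants))
  )

  sleep_periods <- if (nrow(slp$periods) > 0) {
    slp$periods %>% select(-"cycles")
  } else {
    slp$periods
  }

  list(
    wear_days = val$wear_days,
    participants = val$participants,
    activity_days = activity_days,
    activity_participants = activity_participants,
    sleep_periods = sleep_periods,
    sleep_nights = slp$nights,
    sleep_participants = slp$participants,
    sleep_skipped = slp$skipped,
    tables = tables,
    flow_counts = flow_counts,
    options = list(cutoff = as.integer(cutoff), cutoffs = cutoffs,
                   late_merge_gap_min = late_merge_gap_min,
                   restless_as_awake = restless_as_awake,
                   min_days = min_days, max_days = max_days)
  )
}

#' Write pipeline outputs (and optionally the minute grids) to a directory
#'
#' Writes `wear_days.csv`, `participants.csv`, `activity_days.csv`,
#' `activity_participants.csv`, `sleep_periods.csv`, `sleep_nights.csv`,
#' `sleep_participants.csv`, `table_activity.csv`, `table_sleep.csv`,
#' `clock_matrix.csv` and `flow_counts.csv`. Sleep efficiency is
#' additionally written as a percentage with one decimal
#' (`efficiency_pct`); all other numeric columns keep full precision so the
#' files round-trip. When `grids` is supplied the canonical
#' `minutes_<id>.csv` files are written too, making the directory a complete
#' re-runnable input for [run_pipeline()].
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param grids Optional named list of minute grids to write alongside.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir, grids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    readr::write_csv(df, file.path(dir, name), na = "")
  }
  wcsv(result$wear_days, "wear_days.csv")
  parts <- result$participants %>%
    mutate(retained_dates = purrr::map_chr(
      .data$retained_dates, ~ paste(format(.x), collapse = ";")))
  wcsv(parts, "participants.csv")
  wcsv(result$activity_days, "activity_days.csv")
  wcsv(result$activity_participants, "activity_participants.csv")
  wcsv(result$sleep_periods, "sleep_periods.csv")
  nights <- result$sleep_nights
  if (nrow(nights) > 0) {
    nights <- nights %>%
      mutate(efficiency_pct = round(.data$efficiency * 100, 1))
  }
  wcsv(nights, "sleep_nights.csv")
  sp <- result$sleep_participants
  if (nrow(sp) > 0) {
    sp <- sp %>% mutate(efficiency_pct = round(.data$mean_efficiency * 100, 1))
  }
  wcsv(sp, "sleep_participants.csv")
  wcsv(result$tables$table_activity, "table_activity.csv")
  wcsv(result$tables$table_sleep, "table_sleep.csv")
  if (!is.null(result$tables$clock_matrix)) {
    wcsv(result$tables$clock_matrix, "clock_matrix.csv")
  }
  wcsv(result$flow_counts, "flow_counts.csv")
  if (!is.null(grids)) {
    purrr::walk(grids, write_minute_csv, dir = dir)
  }
  invisible(dir)
}
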