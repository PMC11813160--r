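# Sleep segmentation. Minute stage labels (1 asleep, 2 restless, 3 awake;
# absent = fully awake) are first grouped into sleep cycles — maximal runs of
# consecutive labeled minutes — and cycles are then merged into one main
# sleep period per night:
#
#   Rule A  merge every cycle whose onset falls in the night window
#           [18:00, 06:00) anchored on the night_key date; the period spans
#           the first merged onset to the last merged wake, and inter-cycle
#           gap minutes become in-period wakefulness.
#   Rule B  (fallback, flagged is_late_onset) if no cycle starts in the
#           window, take the longest cycle starting in [06:00, 18:00) of the
#           following day and chain subsequent cycles whose onset is within
#           `late_merge_gap_min` minutes of the running period's end. This is
#           a declared automation of what is otherwise a manual review step.
#
# Cycles beginning after the main period's wake are naps and are excluded.

#' Extract sleep cycles from a minute grid
#'
#' A sleep cycle is a maximal run of consecutive minutes carrying any sleep
#' stage label; unlabeled (fully awake) minutes separate cycles.
#'
#' @param grid A `minute_grid` tibble for one participant.
#' @return Tibble of cycles in time order: `participant_id`, `start`, `end`
#'   (POSIXct, half-open `[start, end)`), `n_minutes`, and `stages`, a list
#'   column holding the per-minute integer stage sequence of each cycle.
#' @export
extract_sleep_cycles <- function(grid) {
  labeled <- !is.na(grid$sleep_stage)
  if (!any(labeled)) {
    return(tibble::new_tibble(list(
      participant_id = character(), start = index_time(integer()),
      end = index_time(integer()), n_minutes = integer(),
      stages = list()), nrow = 0L))
  }
  idx <- minute_index(grid$timestamp)
  # a run breaks on an unlabeled minute (grids are dense by construction)
  r <- rle(labeled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  k <- length(keep)
  stages <- vector("list", k)
  for (j in seq_len(k)) {
    stages[[j]] <- grid$sleep_stage[starts[keep[j]]:ends[keep[j]]]
  }
  tibble::new_tibble(list(
    participant_id = rep(grid$participant_id[1], k),
    start = index_time(idx[starts[keep]]),
    end = index_time(idx[ends[keep]] + 1L),
    n_minutes = r$lengths[keep],
    stages = stages), nrow = k)
}

# internal: period assembled from a set of cycle rows (assumed time-ordered)
assemble_period <- function(cycles, night_key, is_late_onset) {
  tibble::new_tibble(list(
    participant_id = cycles$participant_id[1],
    night_key = as.Date(night_key),
    onset = cycles$start[1],
    wake = cycles$end[nrow(cycles)],
    n_cycles = nrow(cycles),
    is_late_onset = is_late_onset,
    cycles = list(cycles)
  ), nrow = 1L)
}

# internal: fast row subset of a cycle table
slice_cycles <- function(cycles, i) {
  tibble::new_tibble(lapply(cycles, `[`, i), nrow = length(i))
}

#' Identify the main sleep period of one night
#'
#' Applies the night-window merge rule (Rule A) and, when no cycle starts
#' inside the 18:00–06:00 window, the post-06:00 fallback (Rule B); see the
#' package vignette for the full procedure. Cycles starting after the main
#' period's wake are naps and are not merged.
#'
#' @param cycles Cycle table from [extract_sleep_cycles()], time-ordered.
#' @param night_key `Date` anchoring the night: the window is
#'   `[18:00 night_key, 06:00 night_key+1)`.
#' @param late_merge_gap_min Chaining threshold (minutes) for the Rule B
#'   fallback: a following cycle is absorbed while its onset is within this
#'   many minutes of the running period's end. Default 60.
#' @return A one-row period tibble (`participant_id`, `night_key`, `onset`,
#'   `wake`, `n_cycles`, `is_late_onset`, list column `cycles`), or `NULL`
#'   when no cycle qualifies under either rule.
#' @export
identify_main_sleep <- function(cycles, night_key, late_merge_gap_min = 60) {
  if (is.null(cycles) || nrow(cycles) == 0) {
    return(NULL)
  }
  if (is.unsorted(cycles$start)) {
    cycles <- slice_cycles(cycles, order(cycles$start))
  }
  onset_idx <- minute_index(cycles$start)

  win <- night_window(night_key)
  in_win <- onset_idx >= win[["start"]] & onset_idx < win[["end"]]
  if (any(in_win)) {
    return(assemble_period(slice_cycles(cycles, which(in_win)),
                           night_key, FALSE))
  }

  lw <- late_window(night_key)
  cand <- which(onset_idx >= lw[["start"]] & onset_idx < lw[["end"]])
  if (length(cand) == 0) {
    return(NULL)
  }
  seed <- cand[which.max(cycles$n_minutes[cand])]
  take <- seed
  end_idx <- minute_index(cycles$end)
  run_end <- end_idx[seed]
  i <- seed + 1L
  while (i <= nrow(cycles)) {
    if (onset_idx[i] - run_end <= late_merge_gap_min) {
      take <- c(take, i)
      run_end <- max(run_end, end_idx[i])
      i <- i + 1L
    } else {
      break
    }
  }
  assemble_period(slice_cycles(cycles, take), night_key, TRUE)
}

#' Main sleep periods for every night of a participant
#'
#' Walks the night keys covering a cycle table in chronological order and
#' applies [identify_main_sleep()] to each, consuming cycles as they are
#' absorbed so no cycle can belong to two nights. Nights with no qualifying
#' cycles are simply absent from the result. Cycles absorbed by no night are
#' reported as naps.
#'
#' @param cycles Cycle table from [extract_sleep_cycles()].
#' @param night_keys Optional `Date` vector of nights to examine; defaults to
#'   every date from the day before the first cycle to the day of the last.
#' @inheritParams identify_main_sleep
#' @return Tibble of main sleep periods (possibly zero rows) with attribute
#'   `"naps"`: the cycle rows not absorbed into any period.
#' @export
main_sleep_periods <- function(cycles, night_keys = NULL,
                               late_merge_gap_min = 60) {
  empty <- tibble(participant_id = character(), night_key = as.Date(character()),
                  onset = index_time(integer()), wake = index_time(integer()),
                  n_cycles = integer(), is_late_onset = logical(),
                  cycles = list())
  if (is.null(cycles) || nrow(cycles) == 0) {
    attr(empty, "naps") <- cycles
    return(empty)
  }
  if (is.unsorted(cycles$start)) {
    cycles <- slice_cycles(cycles, order(cycles$start))
  }
  if (is.null(night_keys)) {
    first_day <- index_date(minute_index(cycles$start[1]))
    last_day <- index_date(minute_index(cycles$end[nrow(cycles)]))
    night_keys <- seq(first_day - 1L, last_day, by = "day")
  }
  remaining <- cycles
  periods <- list()
  for (key in sort(unique(as.Date(night_keys)))) {
    p <- identify_main_sleep(remaining, as.Date(key, origin = "1970-01-01"),
                             late_merge_gap_min = late_merge_gap_min)
    if (!is.null(p)) {
      used <- p$cycles[[1]]
      remaining <- slice_cycles(remaining,
                                which(!(remaining$start %in% used$start)))
      periods[[length(periods) + 1]] <- p
    }
  }
  out <- if (length(periods)) bind_rows(periods) else empty
  attr(out, "naps") <- remaining
  out
}
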