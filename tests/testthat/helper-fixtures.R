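# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately use plain minute-by-minute for-loops over raw
# vectors, independent of the package's rle/tibble implementations.

TS0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# internal minute-index plumbing, convenient in oracles
minute_index <- wearminute:::minute_index

ts_at <- function(spec) {
  # "2021-03-01 23:45" convenience constructor
  as.POSIXct(spec, tz = "UTC")
}

# build a dense minute grid from parallel vectors starting at `start`
make_grid <- function(start, n, id = "P1", heart_rate = NA_integer_,
                      steps = NA_integer_, intensity = NA_character_,
                      sleep_stage = NA_integer_) {
  g <- tibble::tibble(
    participant_id = id,
    timestamp = start + 60 * (0:(n - 1)),
    heart_rate = as.integer(rep_len(heart_rate, n)),
    steps = as.integer(rep_len(steps, n)),
    intensity = as.character(rep_len(intensity, n)),
    sleep_stage = as.integer(rep_len(sleep_stage, n))
  )
  class(g) <- c("minute_grid", class(g))
  g
}

# set sleep stages on a grid over clock-time intervals
set_stages <- function(grid, start, end, stage = 1L) {
  sel <- grid$timestamp >= start & grid$timestamp < end
  grid$sleep_stage[sel] <- as.integer(stage)
  grid
}

# ---- brute-force oracles ---------------------------------------------------

# maximal labeled runs by linear scan; returns data.frame of [start, end)
# minute indices (minutes since epoch)
brute_runs <- function(idx, stage) {
  runs <- list()
  cur_start <- NA
  prev_idx <- NA
  for (i in seq_along(idx)) {
    labeled <- !is.na(stage[i])
    contiguous <- !is.na(prev_idx) && idx[i] == prev_idx + 1
    if (labeled && (is.na(cur_start) || !contiguous)) {
      if (!is.na(cur_start)) {
        runs[[length(runs) + 1]] <- c(cur_start, prev_idx + 1)
      }
      cur_start <- idx[i]
    }
    if (!labeled && !is.na(cur_start)) {
      runs[[length(runs) + 1]] <- c(cur_start, prev_idx + 1)
      cur_start <- NA
    }
    prev_idx <- idx[i]
  }
  if (!is.na(cur_start)) {
    runs[[length(runs) + 1]] <- c(cur_start, prev_idx + 1)
  }
  if (length(runs) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

# night-window merge (Rule A) by direct definition: take every run whose
# first minute lies in [18:00 key, 06:00 key+1); the period spans the first
# such start to the last such end. NULL when no run qualifies.
brute_rule_a <- function(idx, stage, night_key) {
  runs <- brute_runs(idx, stage)
  w0 <- as.numeric(as.Date(night_key)) * 1440 + 18 * 60
  w1 <- w0 + 12 * 60
  sel <- runs$start >= w0 & runs$start < w1
  if (!any(sel)) {
    return(NULL)
  }
  list(onset = min(runs$start[sel]), wake = max(runs$end[sel]),
       n_cycles = sum(sel))
}

# per-night metrics by direct minute count over a stage vector spanning
# [onset, wake); NA = gap
brute_night_counts <- function(stages, restless_as_awake = FALSE) {
  asleep <- 0
  awake <- 0
  for (s in stages) {
    if (!is.na(s) && (s == 1 || (s == 2 && !restless_as_awake))) {
      asleep <- asleep + 1
    } else {
      awake <- awake + 1
    }
  }
  list(asleep = asleep, awake = awake)
}
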