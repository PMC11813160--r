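# Ingestion of minute-level per-stream CSV exports into a canonical dense
# per-participant minute grid, plus the canonical round-trippable CSV format.

#' Default export dialect
#'
#' Describes how per-stream CSV exports map onto the canonical minute record.
#' Each stream entry gives a filename `pattern` (regex, case-insensitive)
#' identifying the stream, plus the id, timestamp and value column names.
#' The defaults cover the common research-export layout
#' (`Id`, `ActivityMinute`, `Value`).
#'
#' @param streams Optional named list overriding individual stream entries;
#'   names among `"heart_rate"`, `"steps"`, `"intensity"`, `"sleep"`.
#' @return A dialect list usable as the `dialect` argument of
#'   [parse_minute_csvs()].
#' @export
minute_csv_dialect <- function(streams = list()) {
  base <- list(
    heart_rate = list(pattern = "heart", id_col = "Id",
                      time_col = "ActivityMinute", value_col = "Value"),
    steps      = list(pattern = "step", id_col = "Id",
                      time_col = "ActivityMinute", value_col = "Value"),
    intensity  = list(pattern = "intensit", id_col = "Id",
                      time_col = "ActivityMinute", value_col = "Value"),
    sleep      = list(pattern = "sleep", id_col = "Id",
                      time_col = "ActivityMinute", value_col = "Value")
  )
  for (nm in names(streams)) {
    if (!nm %in% names(base)) {
      abort(paste0("unknown stream '", nm, "' in dialect"))
    }
    base[[nm]] <- utils::modifyList(base[[nm]], streams[[nm]])
  }
  base
}

#' Load an ingestion dialect from a YAML config
#'
#' The YAML file holds a `streams:` mapping with per-stream `pattern`,
#' `id_col`, `time_col`, `value_col` entries; omitted fields fall back to
#' [minute_csv_dialect()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A dialect list.
#' @export
read_dialect_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  minute_csv_dialect(streams = cfg$streams %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map raw intensity values (numeric codes 0-3 or names) to canonical labels
canonical_intensity <- function(x) {
  x <- trimws(tolower(as.character(x)))
  code <- match(x, c("0", "1", "2", "3")) - 1L
  named <- match(gsub("[ _-]+", "_", x), INTENSITY_LEVELS)
  out <- INTENSITY_LEVELS[ifelse(is.na(code), named, code + 1L)]
  out
}

#' Parse per-stream minute-level CSV exports
#'
#' Reads one or more per-stream CSV files (heart rate, steps, intensity,
#' sleep stage), identifies each file's stream from its filename via the
#' dialect patterns, normalizes timestamps to whole minutes, resolves
#' duplicate rows within a stream for the same participant-minute (numeric
#' values averaged and rounded half up; categorical values take the last
#' occurrence), and merges streams into one record per participant-minute.
#'
#' Rows whose timestamp cannot be parsed are dropped with a warning and
#' collected in the `"issues"` attribute of the result (file, line, raw
#' value); a file matching no stream pattern is a hard error.
#'
#' @param paths Character vector of CSV file paths.
#' @param dialect Dialect list from [minute_csv_dialect()] or
#'   [read_dialect_config()].
#' @return A tibble of merged minute records with columns `participant_id`,
#'   `timestamp`, `heart_rate`, `steps`, `intensity`, `sleep_stage`, sorted
#'   by participant then time; attribute `"issues"` holds row-level parse
#'   failures.
#' @export
parse_minute_csvs <- function(paths, dialect = minute_csv_dialect()) {
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }

  issues <- list()
  streams <- list()
  for (path in paths) {
    hits <- vapply(dialect, function(s) {
      grepl(s$pattern, basename(path), ignore.case = TRUE)
    }, logical(1))
    if (!any(hits)) {
      abort(paste0("file '", path,
                   "' matches no stream pattern in the dialect"))
    }
    stream <- names(dialect)[which(hits)[1]]
    spec <- dialect[[stream]]
    raw <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    need <- c(spec$id_col, spec$time_col, spec$value_col)
    if (!all(need %in% names(raw))) {
      abort(paste0("file '", path, "' lacks required column(s): ",
                   paste(setdiff(need, names(raw)), collapse = ", ")))
    }
    ts <- parse_timestamp(raw[[spec$time_col]])
    bad <- is.na(ts)
    if (any(bad)) {
      issues[[length(issues) + 1]] <- tibble(
        file = path, line = which(bad) + 1L,
        raw = raw[[spec$time_col]][bad])
    }
    dat <- tibble(
      participant_id = as.character(raw[[spec$id_col]]),
      timestamp = ts,
      value = raw[[spec$value_col]]
    )[!bad, , drop = FALSE]
    streams[[stream]] <- bind_rows(streams[[stream]], dat)
  }
  issues <- if (length(issues)) bind_rows(issues) else
    tibble(file = character(), line = integer(), raw = character())
  if (nrow(issues) > 0) {
    warn(paste0(nrow(issues), " row(s) with unparseable timestamps dropped ",
                "(see attr(., 'issues'))"))
  }

  resolve_numeric <- function(df, out_name) {
    df %>%
      mutate(value = suppressWarnings(as.numeric(.data$value))) %>%
      group_by(.data$participant_id, .data$timestamp) %>%
      summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
      mutate(value = ifelse(is.nan(.data$value), NA_real_,
                            round_half_up(.data$value))) %>%
      rename(!!out_name := "value")
  }
  resolve_last <- function(df, out_name) {
    df %>%
      group_by(.data$participant_id, .data$timestamp) %>%
      summarise(value = last(.data$value), .groups = "drop") %>%
      rename(!!out_name := "value")
  }

  parts <- list()
  if (!is.null(streams$heart_rate)) {
    parts$heart_rate <- resolve_numeric(streams$heart_rate, "heart_rate")
  }
  if (!is.null(streams$steps)) {
    parts$steps <- resolve_numeric(streams$steps, "steps")
  }
  if (!is.null(streams$intensity)) {
    parts$intensity <- streams$intensity %>%
      mutate(value = canonical_intensity(.data$value)) %>%
      resolve_last("intensity")
  }
  if (!is.null(streams$sleep)) {
    parts$sleep_stage <- streams$sleep %>%
      mutate(value = suppressWarnings(as.integer(.data$value))) %>%
      filter(.data$value %in% c(STAGE_ASLEEP, STAGE_RESTLESS, STAGE_AWAKE)) %>%
      resolve_last("sleep_stage")
  }
  merged <- purrr::reduce(parts, function(a, b) {
    dplyr::full_join(a, b, by = c("participant_id", "timestamp"))
  })
  for (col in c("heart_rate", "steps", "intensity", "sleep_stage")) {
    if (!col %in% names(merged)) {
      merged[[col]] <- if (col == "intensity") NA_character_ else NA_integer_
    }
  }
  out <- merged %>%
    mutate(heart_rate = as.integer(.data$heart_rate),
           steps = as.integer(.data$steps),
           sleep_stage = as.integer(.data$sleep_stage)) %>%
    select("participant_id", "timestamp", "heart_rate", "steps",
           "intensity", "sleep_stage") %>%
    arrange(.data$participant_id, .data$timestamp)
  attr(out, "issues") <- issues
  out
}

#' Build a dense per-participant minute grid
#'
#' Densifies minute records of a single participant onto every minute from
#' the first to the last observed timestamp; unobserved minutes carry all
#' fields absent (`NA`). Construction is a pure function of the record set:
#' input order does not matter.
#'
#' @param records Tibble of minute records for one participant, as returned
#'   by [parse_minute_csvs()] (columns `participant_id`, `timestamp`, and any
#'   of `heart_rate`, `steps`, `intensity`, `sleep_stage`).
#' @return A `minute_grid` tibble: one row per minute of
#'   `[first, last]` observed minutes, strictly increasing timestamps.
#' @export
build_minute_grid <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("no data for participant")
  }
  ids <- unique(records$participant_id)
  if (length(ids) != 1) {
    abort(paste0("build_minute_grid() expects one participant, got: ",
                 paste(ids, collapse = ", ")))
  }
  recs <- records %>% arrange(.data$timestamp)
  if (anyDuplicated(recs$timestamp)) {
    abort("duplicate (participant, minute) records; resolve duplicates first")
  }
  idx <- minute_index(recs$timestamp)
  full <- seq(idx[1], idx[length(idx)])
  pos <- match(full, idx)
  grid <- tibble(
    participant_id = ids,
    timestamp = index_time(full),
    heart_rate = (recs$heart_rate %||% rep(NA_integer_, nrow(recs)))[pos],
    steps = (recs$steps %||% rep(NA_integer_, nrow(recs)))[pos],
    intensity = (recs$intensity %||% rep(NA_character_, nrow(recs)))[pos],
    sleep_stage = (recs$sleep_stage %||% rep(NA_integer_, nrow(recs)))[pos]
  )
  class(grid) <- c("minute_grid", class(grid))
  grid
}

#' Build minute grids for every participant in a record table
#'
#' @param records Merged minute records for one or more participants.
#' @return Named list of `minute_grid` tibbles, one per participant id.
#' @export
build_minute_grids <- function(records) {
  split(records, records$participant_id) %>%
    purrr::map(build_minute_grid)
}

#' Write a minute grid to the canonical CSV
#'
#' Canonical format: `minutes_<id>.csv` with columns `participant_id`,
#' `timestamp` (ISO-8601 to the minute), `heart_rate`, `steps`, `intensity`,
#' `sleep_stage`; empty string encodes an absent value. Re-reading with
#' [read_minute_csv()] reproduces the grid field-for-field.
#'
#' @param grid A `minute_grid` tibble.
#' @param dir Output directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_minute_csv <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- grid$participant_id[1]
  path <- file.path(dir, paste0("minutes_", id, ".csv"))
  out <- grid %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a canonical minute CSV back into a minute grid
#'
#' @param path Path to a file written by [write_minute_csv()].
#' @return A `minute_grid` tibble.
#' @export
read_minute_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    heart_rate = readr::col_integer(),
    steps = readr::col_integer(),
    intensity = readr::col_character(),
    sleep_stage = readr::col_integer()
  ), na = "", progress = FALSE)
  raw$timestamp <- parse_timestamp(raw$timestamp)
  build_minute_grid(raw)
}
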