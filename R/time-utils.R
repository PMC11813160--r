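# Time handling.
#
# All timestamps are naive local civil time carried as POSIXct in UTC so that
# no DST or timezone arithmetic ever applies. Internally most computations use
# integer "minute indices" (minutes since the epoch), which make day and
# night-window arithmetic exact.

# POSIXct (UTC) -> integer minutes since epoch
minute_index <- function(time) {
  as.integer(floor(as.numeric(time) / 60))
}

# integer minutes since epoch -> POSIXct (UTC)
index_time <- function(idx) {
  as.POSIXct(as.numeric(idx) * 60, origin = "1970-01-01", tz = "UTC")
}

# truncate a timestamp to the whole minute
minute_floor <- function(time) {
  index_time(minute_index(time))
}

# calendar date of a minute index (naive civil day)
index_date <- function(idx) {
  as.Date(floor(as.numeric(idx) / 1440), origin = "1970-01-01")
}

# first minute index of a calendar date
date_index <- function(date) {
  as.integer(as.numeric(as.Date(date)) * 1440)
}

#' Round half away from zero
#'
#' Deterministic "round half up" used when averaging duplicate integer
#' readings (e.g. two heart-rate rows of 60 and 70 bpm for one minute give
#' 65; 62.5 gives 63), avoiding banker's rounding surprises.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to the nearest integer, ties away from zero.
#' @examples
#' round_half_up(c(62.5, 62.4, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Noon-anchored clock axis
#'
#' Sleep clock times (onsets, wakes, midpoints) are averaged on a linear axis
#' of minutes since the noon preceding the night, so that times straddling
#' midnight (23:50 vs 00:10) average correctly without circular statistics.
#' 18:00 of the night's anchor date maps to 360; midnight to 720; noon of the
#' next day to 1440.
#'
#' @param time POSIXct timestamp(s).
#' @param night_key `Date` anchor of the night (the evening date on which the
#'   18:00 night window opens).
#' @return Numeric minutes since 12:00 of `night_key`.
#' @seealso [clock_label()] to render axis minutes back as clock time.
#' @export
noon_axis_minutes <- function(time, night_key) {
  as.numeric(minute_index(time)) - (date_index(night_key) + 720)
}

#' Render noon-axis minutes as a clock-time label
#'
#' Inverse presentation of [noon_axis_minutes()]: folds the noon-anchored
#' minute back onto a 24-hour clock and formats it "HH:MM". Lossless for any
#' axis value, since the axis spans less than one full day per night.
#'
#' @param axis_min Numeric minutes since the preceding noon.
#' @return Character "HH:MM" labels.
#' @examples
#' clock_label(c(360, 720, 735))  # "18:00" "00:00" "00:15"
#' @export
clock_label <- function(axis_min) {
  m <- (round(axis_min) + 720) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# night window [18:00 key, 06:00 key+1) as minute indices
night_window <- function(night_key) {
  start <- date_index(night_key) + 18L * 60L
  c(start = start, end = start + 12L * 60L)
}

# late-onset search window [06:00, 18:00) of key+1 as minute indices
late_window <- function(night_key) {
  start <- date_index(night_key) + 30L * 60L
  c(start = start, end = start + 12L * 60L)
}

# Friday/Saturday anchor dates are weekend nights (Fri->Sat, Sat->Sun sleep)
is_weekend_key <- function(night_key) {
  format(as.Date(night_key), "%u") %in% c("5", "6")
}

# Parse timestamps in either ISO-8601 ("2021-03-01 23:45[:00]", "T" separator
# allowed, date-only allowed) or the device-export dialect
# "3/1/2021 11:45:00 PM". Returns POSIXct (UTC) floored to the minute, NA
# where unparseable.
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  iso <- gsub("T", " ", x, fixed = TRUE)
  out <- index_time(rep(NA_integer_, length(x)))
  fill <- function(out, str, fmt) {
    todo <- is.na(out) & !is.na(str)
    if (any(todo)) {
      out[todo] <- as.POSIXct(strptime(str[todo], fmt, tz = "UTC"))
    }
    out
  }
  # element-wise so one bad row never poisons the vector; 12-hour formats
  # first, or a %H parse would silently swallow an AM/PM suffix
  out <- fill(out, iso, "%Y-%m-%d %H:%M:%S")
  out <- fill(out, iso, "%Y-%m-%d %H:%M")
  out <- fill(out, x, "%m/%d/%Y %I:%M:%S %p")
  out <- fill(out, x, "%m/%d/%Y %I:%M %p")
  out <- fill(out, x, "%m/%d/%Y %H:%M:%S")
  minute_floor(out)
}
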