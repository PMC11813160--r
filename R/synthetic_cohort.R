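# Synthetic minute-level cohort generator with recorded ground truth.
#
# Emulates the behavioral structure the pipeline measures: per-participant
# wear schedules with nonwear gaps and fully missing days, circadian
# step/intensity profiles, nightly sleep periods with post-midnight (and
# rarely post-06:00) onsets, restless/awake interruptions, occasional split
# sleep cycles and morning/afternoon naps, weekend onset shifts, and AR(1)
# heart rate during wear. Every planted quantity is recorded as ground truth
# so downstream stages can be tested by parameter recovery.

#' Build a synthetic-cohort configuration
#'
#' All rates and distributions of the generator. Defaults describe a cohort
#' of adolescents wearing the device around the clock for about a week, with
#' behavior centered near typical published adolescent wearable summaries
#' (about 9000 steps/day, ~22 h/day wear, ~7.9 h sleep starting shortly
#' after midnight, ~0.6 h WASO, a ~48-minute weekend onset delay).
#'
#' Clock parameters are minutes on the noon-anchored axis (see
#' [noon_axis_minutes()]): 735 is 00:15, 1230 is 08:30 the next day.
#'
#' @param n_participants Number of participants.
#' @param days_per_participant Number of full monitoring days (and nights).
#' @param start_date First monitoring day (a `Date`); default a Monday so an
#'   8-day protocol includes one Friday and one Saturday night.
#' @param seed Integer master seed; each participant derives an independent
#'   substream from `(seed, participant index)`.
#' @param wear List: `gap_rate` (nonwear gaps/day, Poisson),
#'   `gap_meanlog`/`gap_sdlog` (log-normal gap length, minutes),
#'   `p_miss_day` (probability a day is fully unworn).
#' @param activity List: `budget_mean`/`budget_sd` (named `very`, `moderate`,
#'   `light`; daily awake minute budgets), `steps_rate` (named per-intensity
#'   Poisson steps/minute, incl. `sedentary`).
#' @param sleep List: `onset_mean_min`, `onset_sd_min`, `weekend_shift_min`,
#'   `span_mean_h`, `span_sd_h`, `restless_per_night` (Poisson minutes),
#'   `wake_bouts_per_night` (Poisson), `wake_bout_p` (geometric bout-length
#'   parameter), `p_split`/`split_gap_mean` (probability and mean length of
#'   an unlabeled mid-night gap splitting the night into two cycles),
#'   `p_nap`/`nap_mean_min`/`nap_sd_min`, and `p_late`/`late_onset_mean_min`/
#'   `late_onset_sd_min` for the rare post-06:00-onset participants.
#' @param heart_rate List: `wake_mean`, `wake_sd`, `sleep_mean`, `sleep_sd`
#'   (bpm), `ar1` (lag-1 autocorrelation).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 50L,
                          days_per_participant = 8L,
                          start_date = as.Date("2021-03-01"),
                          seed = 1L,
                          wear = list(),
                          activity = list(),
                          sleep = list(),
                          heart_rate = list()) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_per_participant = as.integer(days_per_participant),
    start_date = as.Date(start_date),
    seed = as.integer(seed),
    wear = utils::modifyList(list(
      gap_rate = 1.5, gap_meanlog = log(60), gap_sdlog = 0.7,
      p_miss_day = 0.05), wear),
    activity = utils::modifyList(list(
      budget_mean = c(very = 20, moderate = 23, light = 235),
      budget_sd = c(very = 10, moderate = 10, light = 60),
      steps_rate = c(sedentary = 0, lightly_active = 20,
                     moderately_active = 80, very_active = 130)), activity),
    sleep = utils::modifyList(list(
      onset_mean_min = 735, onset_sd_min = 75, weekend_shift_min = 48,
      span_mean_h = 7.9, span_sd_h = 0.9,
      restless_per_night = 25, wake_bouts_per_night = 8, wake_bout_p = 0.25,
      p_split = 0.3, split_gap_mean = 20,
      p_nap = 0.15, nap_mean_min = 60, nap_sd_min = 20,
      p_late = 0.05, late_onset_mean_min = 1230, late_onset_sd_min = 60),
      sleep),
    heart_rate = utils::modifyList(list(
      wake_mean = 75, wake_sd = 8, sleep_mean = 58, sleep_sd = 5,
      ar1 = 0.9), heart_rate)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$wear$p_miss_day, cfg$sleep$p_split, cfg$sleep$p_nap,
             cfg$sleep$p_late, cfg$sleep$wake_bout_p)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  sds <- c(cfg$wear$gap_sdlog, cfg$activity$budget_sd, cfg$sleep$onset_sd_min,
           cfg$sleep$span_sd_h, cfg$sleep$nap_sd_min,
           cfg$sleep$late_onset_sd_min, cfg$heart_rate$wake_sd,
           cfg$heart_rate$sleep_sd)
  if (any(sds < 0)) {
    abort("all standard deviations must be non-negative")
  }
  if (cfg$sleep$span_mean_h + 4 * cfg$sleep$span_sd_h >= 24) {
    abort("infeasible sleep model: span distribution reaches 24 h")
  }
  if (sum(cfg$activity$budget_mean) > 1440) {
    abort("per-day intensity budgets exceed 1440 minutes")
  }
  if (cfg$n_participants < 1 || cfg$days_per_participant < 2) {
    abort("need at least 1 participant and 2 days")
  }
  invisible(cfg)
}

# independent per-participant substream seed (kept below 2^31)
participant_seed <- function(seed, i) {
  (abs(as.numeric(seed)) * 1000003 + i * 7919) %% 2147483647
}

# one participant; pseed selects their pseudo-random substream
simulate_participant <- function(id, cfg, pseed) {
  set.seed(pseed)
  D <- cfg$days_per_participant
  sp <- cfg$sleep
  wr <- cfg$wear
  ac <- cfg$activity
  hr <- cfg$heart_rate
  origin <- date_index(cfg$start_date)
  day_lo <- function(d) origin + (d - 1L) * 1440L

  is_late <- runif(1) < sp$p_late
  miss <- runif(D) < wr$p_miss_day

  # --- nights ------------------------------------------------------------
  nights <- list()
  night_stages <- list()
  prev_wake <- -Inf
  for (d in seq_len(D)) {
    key <- cfg$start_date + (d - 1L)
    weekend <- is_weekend_key(key)
    if (is_late) {
      # onset clamped inside [06:10, 17:00) of the next day so the night is
      # always identifiable through the post-06:00 fallback
      ax <- rnorm(1, sp$late_onset_mean_min, sp$late_onset_sd_min)
      ax <- min(max(ax, 1090), 1740)
    } else {
      # onset clamped inside (18:10, 05:50) so the night always opens in the
      # 18:00-06:00 window
      shift <- if (weekend) sp$weekend_shift_min else 0
      ax <- rnorm(1, sp$onset_mean_min + shift, sp$onset_sd_min)
      ax <- min(max(ax, 370), 1070)
    }
    onset <- day_lo(d) + 720L + as.integer(floor(ax))
    span <- as.integer(round_half_up(rnorm(1, sp$span_mean_h * 60,
                                           sp$span_sd_h * 60)))
    span <- min(max(span, 60L), 1380L)
    if (onset < prev_wake + 30L) onset <- as.integer(prev_wake + 30L)
    wake <- onset + span

    touched <- (floor(onset / 1440) : floor((wake - 1) / 1440)) -
      floor(origin / 1440) + 1L
    if (any(touched >= 1L & touched <= D & miss[pmin(pmax(touched, 1L), D)])) {
      next  # the device was off that day; the night leaves no record
    }

    stages <- rep(STAGE_ASLEEP, span)
    interior <- if (span > 2L) 2L:(span - 1L) else integer(0)
    nb <- rpois(1, sp$wake_bouts_per_night)
    if (nb > 0 && length(interior) > 0) {
      for (b in seq_len(nb)) {
        len <- 1L + rgeom(1, sp$wake_bout_p)
        s <- interior[sample.int(length(interior), 1L)]
        e <- min(s + len - 1L, span - 1L)
        stages[s:e] <- STAGE_AWAKE
      }
    }
    nr <- rpois(1, sp$restless_per_night)
    asleep_int <- interior[stages[interior] == STAGE_ASLEEP]
    if (nr > 0 && length(asleep_int) > 0) {
      pick <- asleep_int[sample.int(length(asleep_int),
                                    min(nr, length(asleep_int)))]
      stages[pick] <- STAGE_RESTLESS
    }
    gap_len <- 0L
    if (!is_late && runif(1) < sp$p_split) {
      glen <- rpois(1, sp$split_gap_mean)
      # the post-gap cycle must still begin before 06:00 so the night-window
      # rule reunites the two cycles
      g_hi <- min(span - glen, (1080L - as.integer(floor(ax))) - glen)
      if (glen >= 1L && g_hi >= 2L) {
        g <- sample.int(g_hi - 1L, 1L) + 1L
        stages[g:(g + glen - 1L)] <- NA_integer_
        gap_len <- glen
      }
    }
    n3 <- sum(stages == STAGE_AWAKE, na.rm = TRUE)
    n2 <- sum(stages == STAGE_RESTLESS, na.rm = TRUE)
    nights[[length(nights) + 1]] <- tibble(
      participant_id = id, night_key = key,
      onset_idx = onset, wake_idx = wake,
      span_minutes = span, stage3_minutes = n3, restless_minutes = n2,
      gap_minutes = gap_len, waso_minutes = n3 + gap_len,
      is_late_onset = is_late, is_weekend_night = weekend
    )
    night_stages[[length(nights)]] <- stages
    prev_wake <- wake
  }
  nights_tbl <- bind_rows(nights)

  # --- naps (morning/afternoon, after the previous main night) -----------
  naps <- list()
  if (!is_late && nrow(nights_tbl) > 0) {
    for (d in 2:D) {
      if (miss[d]) next
      prev <- nights_tbl[nights_tbl$night_key == cfg$start_date + (d - 2L), ]
      if (nrow(prev) == 0) next
      if (runif(1) >= sp$p_nap) next
      len <- as.integer(round_half_up(rnorm(1, sp$nap_mean_min,
                                            sp$nap_sd_min)))
      len <- min(max(len, 10L), 240L)
      lo <- max(prev$wake_idx + 120L, day_lo(d) + 6L * 60L)
      hi <- day_lo(d) + 18L * 60L - len - 30L
      if (lo >= hi) next
      s <- lo + sample.int(hi - lo, 1L) - 1L
      naps[[length(naps) + 1]] <- tibble(
        participant_id = id, date = cfg$start_date + (d - 1L),
        start_idx = s, end_idx = s + len)
    }
  }
  naps_tbl <- bind_rows(naps)

  # --- grid arrays --------------------------------------------------------
  gend <- max(origin + D * 1440L,
              if (nrow(nights_tbl)) max(nights_tbl$wake_idx) else -Inf,
              if (nrow(naps_tbl)) max(naps_tbl$end_idx) else -Inf)
  gend <- as.integer(gend)
  n <- gend - origin
  stage_arr <- rep(NA_integer_, n)
  sleepish <- rep(FALSE, n)  # inside any night span or nap (incl. gaps)
  for (k in seq_len(nrow(nights_tbl))) {
    rngk <- (nights_tbl$onset_idx[k] - origin + 1L):
      (nights_tbl$wake_idx[k] - origin)
    stage_arr[rngk] <- night_stages[[k]]
    sleepish[rngk] <- TRUE
  }
  for (k in seq_len(nrow(naps_tbl))) {
    rngk <- (naps_tbl$start_idx[k] - origin + 1L):
      (naps_tbl$end_idx[k] - origin)
    stage_arr[rngk] <- STAGE_ASLEEP
    sleepish[rngk] <- TRUE
  }

  worn <- rep(TRUE, n)
  for (d in which(miss)) {
    worn[(day_lo(d) - origin + 1L):(day_lo(d) - origin + 1440L)] <- FALSE
  }
  for (d in which(!miss)) {
    ng <- rpois(1, wr$gap_rate)
    if (ng == 0) next
    base <- day_lo(d) - origin
    for (g in seq_len(ng)) {
      len <- as.integer(round_half_up(rlnorm(1, wr$gap_meanlog,
                                             wr$gap_sdlog)))
      len <- min(max(len, 5L), 600L)
      s <- base + sample.int(1440L, 1L)
      e <- min(s + len - 1L, base + 1440L, n)
      if (s > n) next
      seg <- s:e
      worn[seg[!sleepish[seg]]] <- FALSE
    }
  }
  # nonwear minutes carry no stage labels (device off records nothing)
  stage_arr[!worn] <- NA_integer_

  # --- activity & steps ---------------------------------------------------
  steps_arr <- rep(NA_integer_, n)
  intens_arr <- rep(NA_character_, n)
  sleep_worn <- sleepish & worn
  intens_arr[sleep_worn] <- "sedentary"
  steps_arr[sleep_worn] <- 0L
  truth_days <- list()
  n_days_grid <- as.integer(ceiling(n / 1440))
  for (d in seq_len(n_days_grid)) {
    base <- day_lo(d) - origin
    dayrng <- (base + 1L):min(base + 1440L, n)
    if (d <= D && !miss[d]) {
      awake_pos <- dayrng[worn[dayrng] & !sleepish[dayrng]]
      nv <- max(0L, as.integer(round_half_up(
        rnorm(1, ac$budget_mean[["very"]], ac$budget_sd[["very"]]))))
      nm <- max(0L, as.integer(round_half_up(
        rnorm(1, ac$budget_mean[["moderate"]], ac$budget_sd[["moderate"]]))))
      nl <- max(0L, as.integer(round_half_up(
        rnorm(1, ac$budget_mean[["light"]], ac$budget_sd[["light"]]))))
      avail <- length(awake_pos)
      if (nv + nm + nl > avail) {
        scale <- avail / (nv + nm + nl)
        nv <- as.integer(floor(nv * scale))
        nm <- as.integer(floor(nm * scale))
        nl <- as.integer(floor(nl * scale))
      }
      shuffled <- awake_pos[sample.int(avail)]
      lab <- rep("sedentary", avail)
      if (nv > 0) lab[1:nv] <- "very_active"
      if (nm > 0) lab[(nv + 1):(nv + nm)] <- "moderately_active"
      if (nl > 0) lab[(nv + nm + 1):(nv + nm + nl)] <- "lightly_active"
      intens_arr[shuffled] <- lab
      steps_arr[shuffled] <- rpois(avail, ac$steps_rate[lab])
    }
    truth_days[[d]] <- tibble(
      participant_id = id, date = cfg$start_date + (d - 1L),
      wear_minutes = sum(worn[dayrng]),
      total_steps = sum(steps_arr[dayrng], na.rm = TRUE),
      minutes_very = sum(intens_arr[dayrng] == "very_active", na.rm = TRUE),
      minutes_moderate = sum(intens_arr[dayrng] == "moderately_active",
                             na.rm = TRUE),
      minutes_light = sum(intens_arr[dayrng] == "lightly_active",
                          na.rm = TRUE),
      minutes_awake_sedentary = sum(!sleepish[dayrng] & worn[dayrng] &
                                      intens_arr[dayrng] == "sedentary",
                                    na.rm = TRUE)
    )
  }

  # --- heart rate: AR(1) deviations around a wake/sleep level -------------
  level <- ifelse(sleepish, hr$sleep_mean, hr$wake_mean)
  sd_state <- ifelse(sleepish, hr$sleep_sd, hr$wake_sd)
  innov_scale <- sqrt(max(0, 1 - hr$ar1^2))
  dev <- stats::filter(rnorm(n, 0, sd_state * innov_scale), hr$ar1,
                       method = "recursive")
  hr_arr <- as.integer(round_half_up(pmin(pmax(level + as.numeric(dev),
                                               35), 190)))
  hr_arr[!worn] <- NA_integer_
  steps_arr[!worn] <- NA_integer_
  intens_arr[!worn] <- NA_character_

  grid <- tibble(
    participant_id = id,
    timestamp = index_time(origin + 0:(n - 1L)),
    heart_rate = hr_arr,
    steps = steps_arr,
    intensity = intens_arr,
    sleep_stage = stage_arr
  )
  class(grid) <- c("minute_grid", class(grid))

  list(grid = grid,
       nights = nights_tbl,
       days = bind_rows(truth_days),
       naps = naps_tbl)
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given `config$seed`: each participant draws from an
#' independent substream derived from `(seed, participant index)`, so
#' cohorts are reproducible and participant subsets are stable.
#'
#' @param config A [cohort_config()].
#' @return List with `grids` (named list of `minute_grid` tibbles) and
#'   `truth`, itself a list of tibbles `nights` (true onset/wake minute
#'   indices, WASO components, weekend/late flags), `days` (true wear
#'   minutes, steps, intensity minutes per calendar day) and `naps`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  sims <- purrr::map(seq_along(ids), function(i) {
    simulate_participant(ids[i], config,
                         participant_seed(config$seed, i))
  })
  truth <- list(
    nights = bind_rows(purrr::map(sims, "nights")),
    days = bind_rows(purrr::map(sims, "days")),
    naps = bind_rows(purrr::map(sims, "naps"))
  )
  class(truth) <- c("cohort_truth", class(truth))
  list(grids = setNames(purrr::map(sims, "grid"), ids), truth = truth)
}

#' Per-participant true metric table from ground truth
#'
#' Applies the same metric definitions the pipeline estimates — valid-day
#' selection (wear >= `cutoff` minutes, earliest `max_days`), activity means
#' over retained days, and night metrics (span, WASO, midpoint-based social
#' jet lag) over nights anchored on retained days, earliest `max_days`,
#' requiring `min_days` of each — but computed directly from the planted
#' truth intervals, for recovery comparisons.
#'
#' @param truth `truth` element of [generate_cohort()] output.
#' @param cutoff Wear-minute valid-day cutoff (default 600).
#' @param min_days,max_days Retention rule (defaults 5 and 9).
#' @return Tibble with one row per participant: true activity and sleep
#'   means (`NA` where the participant fails the corresponding retention
#'   rule).
#' @export
truth_summary <- function(truth, cutoff = 600L, min_days = 5L,
                          max_days = 9L) {
  ids <- unique(truth$days$participant_id)
  rows <- purrr::map(ids, function(id) {
    days <- truth$days %>% filter(.data$participant_id == id) %>%
      arrange(.data$date)
    valid <- days %>% filter(.data$wear_minutes >= cutoff) %>%
      head(max_days)
    act_ok <- nrow(valid) >= min_days
    nights <- truth$nights %>% filter(.data$participant_id == id,
                                      .data$night_key %in% valid$date) %>%
      arrange(.data$night_key) %>% head(max_days)
    slp_ok <- nrow(nights) >= min_days
    onset_ax <- nights$onset_idx - (date_index(nights$night_key) + 720)
    wake_ax <- nights$wake_idx - (date_index(nights$night_key) + 720)
    mid_ax <- (onset_ax + wake_ax) / 2
    wk <- mid_ax[!nights$is_weekend_night]
    we <- mid_ax[nights$is_weekend_night]
    sjl <- if (slp_ok && length(wk) > 0 && length(we) > 0) {
      abs(mean(we) - mean(wk)) / 60
    } else {
      NA_real_
    }
    tibble(
      participant_id = id,
      n_valid_days = nrow(valid),
      true_mean_steps = if (act_ok) mean(valid$total_steps) else NA_real_,
      true_mean_wear = if (act_ok) mean(valid$wear_minutes) else NA_real_,
      true_mean_very = if (act_ok) mean(valid$minutes_very) else NA_real_,
      true_mean_moderate = if (act_ok) mean(valid$minutes_moderate)
        else NA_real_,
      true_mean_light = if (act_ok) mean(valid$minutes_light) else NA_real_,
      true_mean_awake_sed = if (act_ok) mean(valid$minutes_awake_sedentary)
        else NA_real_,
      n_nights = nrow(nights),
      true_mean_span_hours = if (slp_ok) mean(nights$span_minutes) / 60
        else NA_real_,
      true_mean_waso_hours = if (slp_ok) mean(nights$waso_minutes) / 60
        else NA_real_,
      true_mean_onset_min = if (slp_ok) mean(onset_ax) else NA_real_,
      true_mean_wake_min = if (slp_ok) mean(wake_ax) else NA_real_,
      true_social_jet_lag_hours = sjl
    )
  })
  bind_rows(rows)
}
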