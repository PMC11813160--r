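Package: wearminute
Title: Minute-Level Consumer Wearable Processing for Physical Activity and Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processes minute-level consumer wearable (Fitbit-style) exports of
    heart rate, steps, activity intensity, and sleep stage into wear-time
    validated daily and participant-level physical-activity and sleep metrics.
    Wear time is inferred from heart-rate presence; valid days and participants
    follow 600- and 1200-minute/day cutoffs over 5-9 days. Sleep cycles are
    segmented from minute stage labels, merged into a nightly main sleep period
    over an 18:00-06:00 window (with a declared fallback for post-06:00
    onsets), and summarized as duration, wakefulness after sleep onset, sleep
    efficiency, midpoint, and social jet lag. A synthetic-cohort generator with
    recorded ground truth supports end-to-end validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
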