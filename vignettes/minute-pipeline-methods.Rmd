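---
title: "Methods: minute-level wearable processing of physical activity and sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minute-level wearable processing of physical activity and sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearminute)
```

## Overview

Consumer wrist-worn devices export minute-level streams of heart rate
(bpm), step counts, an activity-intensity label (sedentary / lightly /
moderately / very active), and a sleep-stage label (1 = asleep,
2 = restless, 3 = awake; absent = fully awake, i.e. outside any
device-detected sleep period). `wearminute` turns these streams into
validated daily and participant-level physical-activity and sleep
summaries, the way free-living cohort studies analyze them. This vignette
documents the model behind each stage, the tunable parameters, the
synthetic-cohort generator used for validation, and the numerical and
design choices a maintainer should know about.

## Wear time and validity

A minute counts as **wear time** iff it carries a heart-rate value — the
optical heart-rate sensor only reports when the device is on the wrist, so
heart-rate presence is the wear proxy. Two refinements:

* Readings outside 20–250 bpm are treated as nonwear. The proxy assumes a
  physiologic reading; a value outside that range is sensor noise, not
  evidence of wear.
* Days are calendar midnight-to-midnight. Partial first/last days are kept
  and judged by the same thresholds, since a presence-count definition
  needs no trimming rule.

A **valid day** has at least 600 wear minutes (10 h, the conventional
actigraphy threshold) or, for the strict 24-hour-compliance analysis,
at least 1200 minutes (20 h). A **valid participant** has 5–9 valid days.
Participants with more than 9 valid days are truncated to the earliest 9
rather than excluded: the protocol requests about one week of wear, and
truncation preserves that analysis window under a declared, testable rule.
By construction the 1200-valid participant set is nested in the 600-valid
set, and adding heart-rate observations can only increase wear minutes —
both are enforced as property tests.

## Physical-activity metrics

On each retained valid day:

* `total_steps` — the unconditioned daily sum (steps recorded during
  nonwear minutes still count toward the day's total);
* `steps_per_hour_wear` — steps on wear minutes divided by wear hours.
  The denominator is wear time, not 24 h, because a steps-per-hour rate is
  only meaningful while the device can observe steps;
* minutes in each device intensity class; minutes with no intensity label
  contribute to no class (no imputation);
* `minutes_awake_sedentary` — sedentary-labeled minutes outside every
  detected main sleep period and nap interval. A sleep period crossing
  midnight is excluded from both calendar days it touches.

Participant-level values are unweighted means and sample (n−1) SDs across
retained days; cohort tables are unweighted across participants, so a
7-day participant and a 9-day participant carry equal weight.

## Sleep segmentation

A **sleep cycle** is a maximal run of consecutive minutes carrying any
stage label; unlabeled (fully awake) minutes separate cycles. Each night
is anchored by a **night key**: the calendar date on which its 18:00
window opens, so a 01:00 onset belongs to the previous evening's night.
This anchoring is what makes weekday/weekend attribution well defined.

The **main sleep period** of a night is found by:

* **Rule A** — merge every cycle whose onset lies in the half-open window
  \[18:00 night key, 06:00 next day). The period runs from the first merged
  onset to the last merged wake; minutes between cycles become in-period
  wakefulness. No gap threshold is applied — merges across long gaps are
  deliberately surfaced in WASO rather than suppressed. An onset exactly
  at 06:00 is outside the window.
* **Rule B** (fallback, flagged `is_late_onset`) — when no cycle opens in
  the window, take the longest cycle opening in \[06:00, 18:00) of the next
  day and chain subsequent cycles whose onset follows within
  `late_merge_gap_min` minutes (default 60) of the running period's end.
  In manual practice, late-onset sleepers are identified by inspecting
  their records; Rule B is this package's declared automation of that
  judgment, and the threshold is an explicit parameter rather than an
  implicit analyst choice.

Cycles starting after the main period's wake are naps: they are excluded
from sleep metrics (naps after the main sleep period are not sleep
duration) but still excluded from awake sedentary time. When a
participant's whole record is decomposed night by night
(`main_sleep_periods()`), cycles already absorbed into an earlier night
are not reconsidered for later nights, so no cycle can serve two nights —
the merge rules above address one night at a time, and this consumption
rule is the package's resolution of the multi-night case.
Nights with no qualifying cycles are simply absent from the tables;
missing sleep days are expected and tolerated downstream.

## Sleep metrics

Within a main sleep period \[onset, wake):

* asleep minutes = stage-1 plus stage-2 minutes (default);
* awake minutes = stage-3 plus unlabeled gap minutes;
* **WASO** = awake minutes (hours);
* **sleep duration** = the onset-to-wake span. Efficiency is defined as
  total asleep time divided by total sleep duration, which forces the
  span — not asleep time — to be the denominator, otherwise efficiency
  would always be 1;
* **efficiency** = asleep / span, in \[0, 1\];
* **midpoint** = (onset + wake) / 2.

The restless stage is ambiguous in device exports — it may reflect
restless sleep or brief wakefulness. The default counts restless as
asleep, keeping it distinct from the explicit awake stage; the
alternative reading is available via `restless_as_awake = TRUE` in
`compute_night_metrics()` so both conventions are first-class and tested.

**Clock-time averaging.** Onsets, wakes, and midpoints are averaged on a
noon-anchored linear axis (minutes since the preceding 12:00): 18:00 is
360, midnight is 720, noon next day is 1440. Midnight-straddling onsets
(23:50 vs 00:10) then average correctly without circular statistics. This
is valid because main-sleep clock times fall within one noon-to-noon
revolution by construction; Rule B late onsets extend the same axis to
18:00 of the next day. The axis is lossless: `clock_label()` recovers the
clock time for any axis minute.

A participant's **onset group** is `after_midnight` iff their mean onset
on this axis is ≥ 720 (a mean of exactly 00:00 counts as after midnight —
an explicit boundary rule). **Social jet lag** is the absolute difference
in hours between mean weekend-night and mean weekday-night midpoints,
where weekend nights are those with Friday or Saturday night keys
(Friday-into-Saturday and Saturday-into-Sunday sleep) and weekday nights
are Sunday–Thursday. It is reported as an absolute value since no sign
convention is standard, and it is *absent* — not zero — for participants
lacking either night type. Sleep summaries require 5–9 nights anchored on
retained valid days; participants with sleep data but fewer than 5 such
nights are recorded in a skip log rather than erroring.

## Synthetic cohort generator

No raw cohort of this kind is publicly deposited, so validation rests on
a generator that plants known behavior and records it as ground truth:

* **wear**: full-day wear with Poisson-count nonwear gaps (log-normal
  lengths) placed in awake time, plus occasional fully missing days;
* **activity**: daily minute budgets for very/moderately/lightly active
  time (normal, truncated at 0) scattered over awake wear minutes, with
  per-intensity Poisson steps/minute (~0 / 20 / 80 / 130 for sedentary
  through very active); sleep minutes are labeled sedentary with zero
  steps, as devices do;
* **sleep**: nightly onset on the noon axis (normal; default mean 00:15,
  SD 75 min), a weekend onset delay (default 48 min), normal span
  (default 7.9 h, SD 0.9 h), Poisson restless minutes and Poisson awake
  bouts with geometric lengths, an occasional unlabeled mid-night gap
  splitting the night into two cycles, morning/afternoon naps, and a
  small fraction of participants (default 5%) whose onsets fall after
  06:00 and exercise the Rule B fallback;
* **heart rate**: AR(1) deviations around wake/sleep levels, clamped to a
  physiologic range, present exactly on worn minutes.

Defaults were chosen once to emulate a compliant adolescent cohort
(~9000 steps/day, ~22 h/day wear, 7.9 h sleep, ~0.6 h WASO) and are
configuration, not constants. Determinism: every participant draws from a
substream derived from `(seed, participant index)`, so cohorts are
byte-reproducible and the first k participants of a larger cohort equal a
smaller cohort's.

Generator-side truncations worth knowing: normal onsets are clamped into
(18:10, 05:50) and late onsets into (06:10, 17:00), and split-night gaps
are only placed where the post-gap cycle still starts before 06:00. These
keep every planted night identifiable by the same rules the pipeline
applies, which is what makes exact recovery a meaningful test; they also
mean the generator does not produce nights that are *undetectable by
construction* (e.g. an onset at 17:30), a real-data possibility the
recovery tests therefore do not probe. The grid extends past the last
configured day up to the final wake so the last night completes; the
spill-over partial morning usually fails the 600-minute rule and drops
out of analyses, except for late-onset sleepers, where it can be retained
as a near-zero-activity day — a small, analyzed contribution well inside
the recovery tolerance.

What the generator does not emulate: intraday circadian structure within
intensity classes, heart-rate variability beyond AR(1), device-specific
staging errors, or naps before the evening window. Passing recovery tests
show the pipeline measures planted behavior losslessly; they do not show
the device's own measurements are accurate.

## Numerical choices and degenerate inputs

* Timestamps are naive local civil time (held as UTC internally); no
  timezone or DST arithmetic is ever applied, matching how device exports
  print clock time. Internally all computation is on integer minute
  indices, so day and window arithmetic is exact.
* Duplicate export rows for one participant-minute: numeric fields are
  averaged and rounded half up (so 60 and 70 bpm give 65); categorical
  fields take the last occurrence. Sub-minute heart-rate rows aggregate
  to minute means the same way. These rules are declared, deterministic,
  and order-robust; exports do not document upstream handling.
* Unparseable timestamps are collected as row-level issues (file and
  line) with a single warning, and the run continues; a file matching no
  known stream pattern is a hard error.
* An empty record set, a mixed-participant record set, or a supposedly
  valid day with zero wear minutes are contract errors and fail loudly.
* Sample sizes used by the validation suite: segmentation equivalence is
  exhaustively enumerated over 2^14 two-letter and 3^9 three-letter
  five-minute block sequences; conservation runs on ≥1000 generated
  nights; parameter recovery uses a 200-participant, 8-day cohort. These
  sizes give exhaustiveness where the state space allows it and
  sub-minute standard errors elsewhere, while keeping the suite fast.

## Known limitations

* Stage labels are consumed as exported; the package does not re-derive
  sleep from heart rate or movement, so device staging bias passes
  through untouched.
* Rule A has no gap ceiling: two short cycles at 18:30 and 05:30 merge
  into an 11-hour "night" with enormous WASO. This is the literal merge
  definition; such nights are visible in WASO rather than silently
  repaired.
* The heart-rate wear proxy cannot distinguish a worn device with a
  failed sensor from nonwear.
* Clock-time averaging on the noon axis assumes onsets after the
  preceding noon; a participant sleeping 13:00→20:00 would be
  summarized on the extended axis but their "night" semantics are
  genuinely ambiguous.
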