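---
title: "Scoring larval zebrafish behavior: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring larval zebrafish behavior: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaphenome)
```

## The measurement problem

Multi-well plate tracking systems record each larva's position in two
dimensions at 5 Hz. From this single time series, three behavioral domains
are scored per larva: photomotor locomotion under alternating 30-min
light/dark phases, behavioral sleep over a 10-h night, and thigmotaxis
(wall preference) during lights-on. Group contrasts — e.g. a neurotoxin
exposure such as MPP+ against untreated controls, with or without a
candidate rescue treatment — are then tested endpoint by endpoint.

This vignette describes the scoring models this package implements, the
parameters that matter and their defaults, the generative model behind the
synthetic cohorts, and the numerical and design decisions taken where the
conventions of the field leave room.

## From positions to speed

Speed is the sampled displacement rate: `v[i] = |p[i] − p[i−1]| / dt` with
`dt = 0.2` s. A speed sample is *valid* only if both endpoints of the
displacement were tracked; steps bridging a tracking dropout are invalid
and contribute zero distance, so distance under dropout is a lower bound
(conservative and order-preserving between groups — dropout is not
group-dependent). No position smoothing is applied by default; a centered
moving average of window 3 is available (`speed(smooth = TRUE)`) for
sensitivity analysis only.

Larvae tracked less than 90% of the analyzed window are excluded
(`apply_exclusion_filter`, `max_missing_fraction = 0.10`). The fraction is
computed over samples, which at constant rate equals the fraction of
wall-clock time. The analyzed window is configurable because the assays are
recorded in separate blocks; the default is the whole recording.

## Movement bouts: the 2/1 mm/s hysteresis rule

Movement initiation is the first sample whose speed strictly exceeds
2 mm/s; cessation is the first subsequent sample strictly below 1 mm/s
(that sample is not part of the bout). Speeds between the thresholds keep
the current state, which is what makes the rule a hysteresis: brief dips
into the 1–2 mm/s band do not split a swim bout. Both comparisons are
strict because the defining phrases are "exceeded" and "dropped below";
flipping to inclusive comparisons is a one-argument change
(`segment_movement_bouts(high =, low =)`).

Numerical conventions:

* Phases are analyzed independently; the state at each phase start is
  NOT_MOVING ("five separate time bins").
* A bout still open at the window end is closed at the window end.
* Untracked samples hold the state. A run of untracked samples longer than
  1 s terminates an open bout at its last valid sample; without this rule
  a dropout spell inside a bout would manufacture phantom long bouts.
* Bout duration has a floor of one sample interval.

Per 30-min lights-on phase, four endpoints follow: swum distance, movement
frequency (bout count), cumulative movement time (summed bout durations),
and bout duration. Bout duration is computed as cumulative time divided by
frequency — the quotient direction is forced by its unit (seconds) even
though assay descriptions sometimes state it inverted. Per-larva endpoints
are unweighted means over the five lights-on phases; a phase with no bout
has undefined bout duration and is dropped from that mean only.

## Sleep: 1-s dichotomization and the ≥ 6 s criterion

Night behavior is reduced to 1-s bins. A bin is *movement* when any valid
sample in it reaches 1.0 mm/s; everything slower is non-movement. The
threshold is inclusive on the movement side because only the non-movement
side ("slower than") is defined by the criterion. A bin with no valid
sample inherits the previous bin's state (first bin: non-movement), so
dropout cannot fragment a sleep bout.

A maximal run of six or more consecutive non-movement bins is a sleep bout
spanning the whole run; all other bins merge into wake bouts, and the two
lists tile the night exactly. The alternative reading of the standard
criterion — quiescence counts as sleep only from its seventh second — is
implemented as `score_sleep(onset_offset = 6)` for sensitivity analysis;
the whole-run reading is the default because it is the operative phrasing
of the established inactivity criteria this field uses. A qualifying run
truncated by lights-on still counts.

Endpoints per night: sleep fragmentation (sleep-bout *onsets* per hour),
sleep ratio, sleep latency (lights-off to first onset; undefined if the
larva never sleeps), night speed (all valid samples), and mean wake/sleep
bout durations. Fragmentation counts onsets — one direction — rather than
all state changes: with the one-direction count, fragmentation,
sleep ratio and sleep bout duration satisfy
`fragmentation = 3600 × ratio / sleep_bout_duration` exactly, which is the
internally consistent reading of published group values; the
both-direction count would be twice that. A unit test asserts the
implementation counts onsets.

## Thigmotaxis

The outer zone is the annulus 3 mm in from the wall, boundary inclusive on
the outer side. The score is the fraction of swum distance performed in
the outer zone during lights-on, which controls for overall hypolocomotion;
each displacement step is assigned to the zone of its starting sample
(crossing steps are rare at 5 Hz, and the rule is consistent under
reflection of time direction only up to one sample). Per-phase fractions
are averaged across the five lights-on phases, mirroring the photomotor
endpoints; pooled-distance weighting is available (`pooled = TRUE`). The
well radius is a config value (default 8 mm, typical 24-well geometry).
Mean distance from the well center is reported alongside.

## Group statistics

The decision tree mirrors standard practice in this assay family:

* Every group is first tested with the D'Agostino–Pearson omnibus
  normality test (implemented in-package from the published skewness and
  kurtosis z-transformations; it requires n ≥ 8 per group). The gate alpha
  is 0.05 — the convention when none is stated.
* Two groups: both normal → two-tailed unpaired t-test (pooled variance);
  otherwise two-tailed Mann–Whitney U. When groups disagree on normality
  the nonparametric branch is taken (conservative).
* Three groups: all normal → one-way ANOVA with Bonferroni-adjusted
  pairwise t-tests (pooled SD); otherwise Kruskal–Wallis with Dunn's post
  hoc (pairwise mean-rank z with tie correction, Bonferroni-adjusted over
  the three pairs).
* 2×2 factorial (toxin × treatment): two-way ANOVA with interaction,
  type III sums of squares under sum-to-zero contrasts (the convention of
  the common commercial analysis software for unbalanced designs), and
  Tukey HSD over the four cells. The error df is N − 4; for group sizes
  {32, 31, 32, 32} that is 123.

Undefined endpoint values (e.g. bout duration of a larva that never moved)
are dropped per group with the effective n reported — the only treatment
that keeps the test assumptions intact. All summaries are mean ± SEM.

## The synthetic cohort generator

No raw tracking data are distributed with the study design this package
targets, so the generator is a first-class module: it is the test bed that
the acceptance suite runs the pipeline against, and its defaults *are* the
study conditions as far as they are printed.

Per larva:

* **Day phases.** Bout onsets are a Poisson process (lights-on default
  44.6/30 ≈ 1.49 bouts/min for controls, 28.0/30 ≈ 0.93 for the MPP+-like
  preset — the printed movement frequencies); bout durations are
  exponential (means 5.7 / 8.0 s, the printed cumulative-time-to-frequency
  ratios); per-bout speeds are lognormal with means chosen so per-phase
  distances land near the printed 1251 / 980 mm. Lights-off onset rate is
  not printed; 2.5 bouts/min for both groups reflects elevated,
  group-similar dark activity. Exponential durations are the
  maximum-entropy choice given that only means ± SEM are published.
* **Night.** An alternating renewal process: wake bouts (exponential,
  means 14.8 / 13.0 s) with supra-threshold movement, quiescence bouts
  (exponential, means 11.2 / 18.8 s — the printed wake and sleep bout
  durations) with sub-threshold jitter. Jitter speeds are uniform on
  [0, 0.5] mm/s so the dichotomization is unambiguous.
* **Space.** Each moving step mixes, with weight κ, a wall-tangential
  direction with an isotropic one; positions reflect radially at the wall.
  κ presets are found by a built-in bisection calibrator targeting the
  printed outer fractions (0.92 control, 0.83 MPP+), not hand-set. A
  quiescent jitter step that would cross the wall is not taken, so jitter
  can never alias into supra-threshold movement through reflection.
* **Dropout.** Each sample is untracked independently with probability
  0.05 by default (in the 0–0.3 range the exclusion filter is built for).

Every drawn bout covers at least one sample, so no bout is invisible at
5 Hz. All randomness is drawn from R's RNG; the C++ position integrator is
a pure function of the drawn numbers, and a cohort is byte-reproducible
from (config, seed).

**What the generator does not emulate:** startle responses at light
transitions, within-bout speed profiles (burst-and-glide), daytime siesta
states, circadian drift across the night, and wake bouts containing
sub-threshold pauses. The last point matters when reading absolute night
numbers: because synthetic wake is continuously supra-threshold, synthetic
night speed and wake-bout durations run higher than real recordings, and
fragmentation runs lower. Passing tests therefore certify the scoring
arithmetic and the direction and robustness of group contrasts, not that
real larvae look like the model.

## The renewal identity and the censoring correction

For the synthetic night the scoring pipeline can be checked against closed
forms. A quiescence bout of duration τ starting at uniform phase within a
1-s bin is observed as a quiet run of `floor(τ − 1 + u)` bins (`u`
uniform): partial bins at both ends contain wake samples. For exponential
τ with mean s this gives

* probability a quiescence bout is scored sleep:
  `p = exp(−7/s) · s · (exp(1/s) − 1)`,
* mean observed sleep bout: `6 + 1/(exp(1/s) − 1)` (truncated geometric),
* fragmentation: `3600 · p / (w + s)` onsets/h, and the sleep ratio and
  wake bout mean by renewal balance.

`renewal_expected()` computes these; `renewal_invert()` inverts them, which
is the ≥ 6 s censoring correction used to recover generator bout means from
pipeline output. The acceptance suite verifies recovery within 5% at 60
larvae × 10-h nights, and the fragmentation prediction within 3 SE over
100 simulated nights. The residual ~1% bias from 0.2-s sampling
quantization is visible but sits well inside those bands.

## Problem sizes used by the test suite

Exhaustive checks run at full size (all 3^12 speed sequences for the bout
state machine, all 2^12 binary records for sleep scoring, 1000 null
simulations per statistical branch). Simulation-based checks use the
smallest cohorts that leave the checked property far from its decision
boundary: single 600-s lights-on phases for the motor and thigmotaxis
sign-recovery replicates (n = 30 and 40 per group, 100 cohorts), 30-min
nights for the sleep sign-recovery replicates (n = 10 per group), 2-h
nights for the renewal-identity replicates, and the full 60 × 10-h design
for parameter recovery. The acceptance script simulates the full study
schedule (five 30-min ON/OFF phase pairs plus a 10-h night) at 30 larvae
per group, and the 2×2 factorial arm at the published group sizes
{32, 31, 32, 32} on a shortened schedule.

## Known limitations

* The exclusion filter sees only the tracked-fraction criterion; upstream
  tracker artifacts (identity swaps, reflections) are out of scope.
* Bout-duration distributions in real larvae are not exponential; the
  generator's presets are anchored only to published means, and the
  lognormal option (`bout_speed_sdlog`, heavier-tailed durations) is a
  sensitivity hook, not a fit.
* The statistics module implements the published decision tree; it does
  not correct across the endpoint family, mirroring the original analysis.
* Night speed is averaged over all valid samples; if wake-only averaging
  is wanted, compute it from the wake bout list and the speed series.
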