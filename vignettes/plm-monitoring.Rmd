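---
title: "Non-contact periodic limb movement monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact periodic limb movement monitoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmwatch)
```

## The monitoring problem

Periodic limb movement disorder (PLMD) produces repetitive, involuntary
movements of the lower limbs during sleep, organised in periodic series. The
reference clinical instrument, polysomnography with leg EMG, is contact-based
and poorly suited to monitoring over weeks. `plmwatch` models a non-contact
alternative: six ceiling-mounted ultrasonic ranging sensors (upper, middle and
lower bed rows, one sensor per side) sample the sensor-to-body distance of
each bed region at 4 Hz. Posture determines the standing distance under each
beam; limb movements on the two lower-limb channels (LLL, LLR) appear as
transient distance dips.

The package implements the full chain as testable software: geometry and
latency calculators, a synthetic session generator with ground truth, capture
and normalization, a from-scratch random forest posture classifier, and an
event-based PLMD detector with decision fusion. All distances are stored in
tenths of a millimetre ("tmm", 1 m = 10000 tmm); the ultrasonic range
2 cm–4 m is therefore [200, 40000], which fits the 20-bit capture word.

## Geometry and latency calculators

`beam_coverage_cm(h, a)` returns `tan(a) * h` in whole centimetres,
truncated toward zero. Truncation rather than rounding is the declared
convention because it reproduces all three installed-row coverages (88, 84,
76 cm at 2.2, 2.1, 1.9 m with a 22° beam); rounding would not. Whether 22°
is a half-angle (making the covered width twice this figure) is left open;
the formula is implemented exactly as stated, one-sided.

`per_iteration_latency_ns` is `S·Tclk` and `pipeline_latency_ns` is
`(N + S − 1)·Tclk` — the standard filled-pipeline latency, under which a
single iteration (`N = 1`) collapses to one traversal. These are pure
calculators of the pipeline model; no hardware timing is measured or
emulated.

## The synthetic-data generator

`simulate_session()` is the stand-in for recorded sessions and defines the
study conditions for every test in the package.

**Postures.** Twelve labels: six base poses (supine, prone, fetal-left,
fetal-right, log-left, log-right — names follow common sleep-posture
taxonomies; tests rely on label identity only), each static or time-variant.
A pose is a table of body-thickness offsets (m) per channel
(`pose_offsets()`); a channel over an occupied region reads its mounting
height minus the offset, an unoccupied channel reads the empty bed. Static
and time-variant forms share the baseline; the time-variant form adds a slow
deterministic sinusoid (default amplitude 15 mm, period 6 s, fixed
per-channel phases) on occupied channels, so the two forms differ in
within-window variance, not in mean. The default offsets were chosen once to
keep pose baselines separated by well over twice the oscillation amplitude
on several channels, i.e. the 12 classes are geometrically separable — which
is what lets a correct classifier reach zero error on clean data.

**Limb movements.** An episode is a periodic series: `movement_count`
movements of `movement_duration_s` whole seconds, onsets
`inter_movement_interval_s` apart, on the left, right or both limbs, each a
dip of `magnitude_mm` toward the sensor. Kinematics (an artifact choice; the
hardware description does not specify them): during a movement the limb
alternates once per second between the dipped and resting position, starting
dipped; afterwards it relaxes back in steps of `return_step_mm` per second
(default 40 mm). Because the detector's motion statistic is the change
between consecutive one-second window means, this makes exactly the
movement seconds register as motion: every within-movement second changes
the mean by the full magnitude, while the relaxation glide stays below any
sensible threshold. Ground-truth flags are therefore the movement seconds
themselves, plus a posture-transition second on any lower-limb channel whose
baseline steps between the two poses.

**Noise and drift.** Additive Gaussian noise per frame and channel (default
sd 3 mm — a realistic figure for low-cost ultrasonic rangers at these
distances) and an optional linear drift over the session model environmental
variation. Readings are quantized to whole tmm and clamped to the sensor
range. All randomness flows through the single config seed; equal seeds give
bit-identical sessions.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: acoustic multipath and inter-transducer crosstalk,
bedding and mattress compliance, partial beam occlusion, non-Gaussian sensor
dropouts, and the gradual, low-velocity movement onsets that the reference
system itself reports as its main error source. Exact-recovery results on
zero-noise sessions certify the algorithmic chain, not field accuracy.

**Scenario presets** (`scenario_library()`) reproduce the experiment
taxonomy with known truth: `exp1` both-limb plus individual left and right
series (6 + 5 + 4 one-second movements); `exp2` a left-only series of eight
movements 10 s apart; `exp3` right plus both; `exp4` one unbroken 120 s
constant-movement run (non-PLMD by rule); `pose_change` a single posture
switch (supine to fetal-left, whose lower-row baseline steps of 0.13 m
exceed the default movement threshold on both limbs) and nothing else.

## Capture and normalization

The capture FIFO models the bounded hardware buffer: 6 channels wide, 40
frames deep, 20-bit words, strict oldest-first eviction. The stated
"4 iterations/s × 10 min" sizing arithmetic is not self-consistent
(4 Hz × 600 s = 2400); the concrete depth of 40 frames is taken as binding
and one buffered block is one frame.

Two baselines parameterize normalization. *Early* normalization is the
per-channel mean of an empty-bed stream. *Encoded* normalization is the
per-posture, per-channel mean over a labelled subject session; a per-posture
mean is the implemented reading of "encoded", the simplest scheme consistent
with its description. The mean-distance finder exposes the
previous-vs-current feedback flag (`stable`/`changed`, default tolerance
5 mm) used to decide whether a baseline still holds; adaptive re-calibration
beyond the flag is out of scope.

A frame's *binary pattern* sets bit `c` when channel `c` reads at least the
occupancy margin nearer than its early baseline. The margin default, 100 mm,
must exceed noise excursions (3σ ≈ 9 mm) and undershoot body-thickness dips
(120–300 mm); it is a config key. Window features (`M = 24`) are, per
channel: normalized mean (early − window mean), raw mean, variance
(population convention, n in the denominator — windows are fixed-width), and
the occupancy bit. This fixed composition is this package's concrete
realization of the loosely specified "sensor feature"; the forest's `m`
defaults adapt automatically if it is changed.

## The random forest, from scratch

The classifier is deliberately implemented from first principles —
bootstrap resampling, per-tree random feature subsets (`mtry`, default
`⌈√M⌉ = 5`), fully grown unpruned CART trees, majority voting — because the
ensemble construction itself is the subject being modelled. Gini impurity is
the split criterion (none is named in the source description; Gini is
standard practice). Candidate thresholds are midpoints between consecutive
distinct sorted values.

Two decisions deserve note:

* **Zero-gain splits are permitted.** A node becomes a leaf only at purity
  or when no assigned feature separates its rows. If splitting stopped as
  soon as no single split reduced impurity, parity-structured labellings
  (XOR) would stall at an impure root; growing fully resolves them and
  guarantees minimal training error on small binary datasets, which the
  test suite checks against an exhaustive enumeration oracle.
* **Every tie-break is deterministic**: lowest feature index, then lowest
  threshold for equal gains; lowest class in the fixed label order for leaf
  majorities and vote ties. Together with the documented draw order (per
  tree: bootstrap indices, then the feature subset, from one seeded stream)
  a forest is bit-reproducible.

The ensemble size default `T = 10` is a config parameter: the source reports
tuning by accuracy without printing values, and the clean-data task here
saturates well below ten trees. `randomForest` appears only in one test as
an independent ensemble oracle for held-out accuracy; it is never on the
implementation path. The 97.5% field-accuracy figure of the reference system
depends on its subject and is not reproducible here; the package instead
asserts zero error on clean separable sessions and >90% held-out accuracy
under the default noise.

Posture matching at detection time first consults a balanced binary search
tree over the encoded postures' pattern keys and falls back to the forest on
a miss. With the default pose table, occupancy patterns collide across many
poses (six bits cannot express thickness), so most lookups fall through to
the forest; the BST earns its keep when reference patterns are distinct, and
colliding postures are dropped from it with a warning rather than guessed.

## The PLMD detector

One *unit* of movement is one one-second analysis window (4 frames). The
per-second left/right comparison makes this the natural unit; the source
leaves it open.

1. **Fusion measurement / limb flags.** For each limb, second `t ≥ 1` is
   flagged when `|mean(t) − mean(t−1)|` exceeds `movement_threshold_tmm`
   (default 1000 = 100 mm, comfortably between noise-induced differences of
   a few mm and episode magnitudes of 150 mm and up). Sub-threshold onsets
   are simply not flagged; no interpolation is attempted.
2. **Event extraction.** Flagged seconds are partitioned into `both`,
   `left`, `right`; maximal runs of each category become events, so partial
   left/right overlaps split into a both-event plus residuals. TLM counts
   each flagged second once.
3. **Decision fusion.** A single-unit both-limb event at a posture-label
   transition is excluded as a pose change. Events longer than
   `max_event_units` (default 40) are excluded as constant movement. Per
   limb side (left = left + both events; right = right + both), surviving
   events chain while gaps are ≤ `max_interval_s`; a chain of ≥ `min_series`
   events confirms the side. Status is the confirmed side(s); confirmed
   durations feed an 8-deep circular FIFO.
4. **Staging.** Early / middle / high from confirmed events per hour with
   breaks at 25 and 50. The series-confirmation defaults (4 events, 90 s
   gap, 1–40 unit durations) and the stage breaks follow widely used
   clinical PLM scoring conventions, since the source names the stage
   vocabulary but no numbers; all are `detector_config()` keys.

Exact recovery — detected events equal injected ground truth in limb, onset
and duration — holds on zero-noise sessions whose episode magnitudes exceed
the threshold and whose posture transitions (if any) step the lower-row
baselines by more than the threshold; the property suite drives 100+ seeded
scenarios through this check.

## Degenerate inputs and numerical notes

Empty windows, empty datasets, short streams and out-of-range words raise
typed errors rather than propagating NaN. Window variances are clamped at
zero against floating-point round-off. Split-gain ties use a 1e-12
tolerance. The events-per-hour rate divides by the actual session length, so
short test sessions stage as `high` by construction — staging is only
meaningful on multi-hour runs.

## Problem sizes

The test and acceptance workloads are sized for a laptop-class single core:
training sessions of 15–20 s per posture label (180–240 windows), detector
scenarios of 2–5 minutes, 100–1000 replicate property cases, and forests of
around ten trees. These sizes already saturate the clean-data guarantees the
package makes; nothing in the implementation caps longer sessions or larger
forests.

## Reproducing a run

```{r, eval = FALSE}
run <- run_pipeline(default_run_config(), seed = 7)
glance(run$result)
autoplot(run$result)
```

Every artifact a run writes (frames, truth, baselines, model JSON, result
JSON, report CSV, log) is a pure function of the configuration and the one
seed; the acceptance script (`scripts/acceptance.R`) recomputes the
package's headline quantities the same way.
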