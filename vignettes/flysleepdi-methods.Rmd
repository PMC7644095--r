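---
title: "Sleep scoring, starvation-aligned windows, and the cone-restricted Sholl defasciculation index"
author: "FlySleepDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring and the defasciculation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlySleepDI)
```

# What this package computes

FlySleepDI implements two measurement procedures used in studies of
starvation-induced sleep loss in *Drosophila* and its neuronal correlate,
the remodeling of the PDF-expressing small ventral lateral neuron (s-LNv)
dorsal projections:

1. **Starvation-aligned sleep analysis.** Per-minute beam-break counts
   from Drosophila Activity Monitor (DAM) tubes are scored into sleep
   bouts, summarized as total sleep, bout number and mean bout duration
   over windows anchored to the light-dark (LD) cycle and to the moment
   food deprivation begins, and compared across fed and starved arms.
2. **The defasciculation index (DI).** A traced 2-D arbor rooted at the
   point where the dorsal ramification opens is intersected with
   concentric circles; a narrow cone centred on the root is rotated to
   capture as many ring crossings as possible, and
   `DI = crossings outside the best cone / total crossings`. Tight,
   fasciculated projections give DI near 0; spread-out (defasciculated)
   projections give larger DI.

A synthetic-data module generates both kinds of input with known ground
truth, so every stage of the pipeline is testable without laboratory
data.

# Sleep model and windowing

## Sleep scoring

Sleep is the field-standard inactivity rule: a sleep bout is any maximal
run of consecutive minutes with zero counts lasting at least
`thresholdMin` minutes, default **5 min**. The rule depends only on the
zero/nonzero pattern, so beam-count magnitudes never matter; runs
truncated by the recording edges still count when long enough, because no
information exists beyond the record. Windows are half-open minute
intervals `[from, to)`; a bout straddling a boundary is clipped and
counted once in each window it overlaps, which makes totals additive over
adjacent windows. When a window contains no bouts the mean bout duration
is reported missing (`NA`), never 0 — zero would conflate "no sleep" with
"brief sleep".

## Zeitgeber and starvation time

ZT0 is lights-on (the design's `lightsOnClock`, e.g. local 06:30 with
lights off at 18:30 in a 12:12 LD cycle); ST is hours since food
deprivation began. All analysis windows assume **series minute 0 = ZT0 of
recording day 1**. The synthetic generator emits series aligned this way;
real monitor files carry their own timestamps, and `sliceChannel()`
windows are how a recording is brought to that convention.

The *first LD shift* is the earliest lights-on/off transition strictly
after the starvation start; a start exactly at a transition resolves to
the next one. This reproduces the standard worked example: starts at
ZT0/ZT6/ZT12/ZT18 shift at ZT12/ZT12/ZT0/ZT0 after 12/6/12/6 h, and for a
ZT12 start the ST12–ST24 analysis window is exactly the ZT0–ZT12 light
phase of the next cycle. Starvation-induced sleep loss over a window is

$$\mathrm{loss\,\%} = 100 \cdot
  \frac{\overline{S}_{\text{fed}} - \overline{S}_{\text{starved}}}
       {\overline{S}_{\text{fed}}}$$

computed on group means of per-fly total sleep, because the fed and
starved cohorts are independent groups of different flies. Negative
values are legal and meaningful. A per-fly-ratio variant was considered
and set aside: with independent arms there is no pairing to exploit, and
the group-mean form is scale-invariant and robust to individual fed flies
with little sleep inflating ratios.

## Group statistics

Per-genotype fed-vs-starved comparisons use the two-sided Student t test
(equal variances) by default, with Welch's variant available. Across
genotypes, one-way ANOVA with Dunnett contrasts (each genotype against a
named control) or Tukey contrasts (all pairs) is used. The per-observation
unit for the cross-genotype comparison is the starved-arm per-fly total
sleep: loss itself is a ratio of group means and has no per-fly value
without pairing, so testing the starved totals (the quantity starvation
actually moves) is the defensible choice. Degenerate inputs follow fixed
conventions: two constant equal samples give `t = 0, p = 1`; identical
groups give `F = 0` and adjusted p-values of 1. Tukey p-values come from
the studentized range distribution; Dunnett p-values from the multivariate
t, evaluated under a frozen internal RNG state so repeated calls are
identical and the caller's RNG is untouched.

# The defasciculation index

## Geometry

The Sholl field is `nRings = 15` circles spaced `ringSpacingUm = 10` µm
apart, centred on the root. (Spacing is configurable; 10 µm per ring puts
the outermost circle 150 µm out, matching s-LNv dorsal projections whose
extent is on the order of a 50-µm scale bar.) Every transversal crossing
of a polyline segment with a circle is one intersection, located exactly
by solving the segment–circle quadratic. Tangential touches count once,
and a crossing at a vertex shared by two consecutive segments is
deduplicated within a geometric tolerance of 1e-9 µm, so polyline
discretization cannot double-count. SWC input is projected to 2-D by
dropping z (maximum-intensity-projection tracing convention; a strict
mode rejects 3-D input instead).

## The cone and its orientation

The cone has full apex angle `coneFullAngleDeg = 15`°, i.e. ±7.5° about
its center line. The orientation is chosen to **maximize the number of
crossings inside the cone**, and the search is exact rather than a grid
scan: an optimal cone can always be rotated until one edge touches a
crossing angle, so the candidate set {each crossing angle ± 7.5°} is
exhaustive. When several orientations tie (common in symmetric or sparse
crossing sets), the winning cone is re-centred on the midpoint of the arc
of angles it captures — so a crossing set concentrated at one angle
reports that angle — and any remaining tie resolves to the smallest
center angle in `[0, 360)`. Tie handling affects only the reported
orientation; the in-cone count, and therefore the DI, is the global
maximum regardless.

`DI = (total − in_cone) / total`. A skeleton with no ring crossings has
no defined DI and raises an error; silently reporting 0 would
misclassify an empty hemisphere as perfectly fasciculated. DI is
rotation-invariant about the root, invariant under joint rescaling of the
skeleton and the ring spacing, and non-increasing in the cone width.

Two unit/width readings were possible from the source conventions for
this quantity and are resolved as configuration defaults: ring spacing is
micrometers (a millimetre-scale Sholl field is physically impossible for
a fly brain), and the "15" of the cone is a full apex angle in degrees.
Both are `ShollConfig` knobs, and DI is computed per hemisphere, with
per-brain averaging left to the caller (`diBatch` groups do this).

# The synthetic generator

## Sleep/wake chain

Each fly is a two-state per-minute semi-Markov chain. Awake flies start a
bout with probability `pInit` per minute; asleep flies wake with
probability `1/boutLenMean` (geometric bout lengths — memoryless exits
chosen for closed-form tractability; the recovery checks depend only on
stationary fractions, not dwell shapes). Both parameters are LD-phase
dependent. Defaults — `pInitLight = 0.04`, `pInitDark = 0.10`,
`boutLenMeanLight = 25` min, `boutLenMeanDark = 40` min — give stationary
asleep fractions of 0.50 in light and 0.80 in dark, i.e. a fly sleeping
roughly two-thirds of the day with a pronounced night preference, typical
of wild-type DAM records. Awake minutes emit Poisson counts with mean
`activeCountRate = 2`, truncated to ≥ 1 so an awake minute can never be
misread as sleep and count noise stays separated from sleep structure.

Starvation multiplies `pInit` by `starvationInitMultiplier` (default 0.5)
from the first post-starvation LD shift onward — and changes nothing
else. This encodes exactly the effect structure the pipeline must be able
to detect: sleep loss driven by fewer bout initiations, with bout
duration untouched (a duration multiplier exists as a knob but defaults
off). The default experiment is 3 recording days with starvation at ZT12
of day 2, 32 flies per arm — cohort sizes in the range used for DAM
experiments.

The stationary asleep fraction per phase is `p/(p + 1/m)`, and the
closed-form expected loss over an ST window is the phase-weighted
stationary fraction with and without the multiplier. The ≥ 5-min
threshold removes bouts by length only, a distribution starvation does
not alter, so its correction factor cancels from the loss ratio. One
caveat is stated in `expectedSleepLoss()`: a window starting exactly at
the LD shift carries an entry transient (the chain arrives at the dark
stationary fraction, ~0.8, and relaxes with rate `p + q`, a 15–25 min
time scale), which depresses measured losses slightly below the
stationary value; the effect is below the Monte-Carlo noise at n = 32 and
vanishes for windows starting an hour or more past the shift.

Per-fly seeds follow a stated counter scheme (`seed + i` for fed fly *i*,
`seed + nPerArm + i` for starved fly *i*) on R's Mersenne-Twister, so
cohorts are fully reproducible from one master seed.

## Arbors

Branches leave the root at angles `Normal(trunkDeg, spreadSigmaDeg)` and
walk in 2-µm steps with `Normal(0, 3°)` heading noise for 160 µm —
beyond the 150-µm outer ring, so straight rays cross all 15 circles. The
spread parameter is the arbor's ground truth: with spread and wiggle
zero, all branches are collinear and DI = 0; mean DI rises monotonically
with the programmed spread (checked over fixed-seed ensembles at σ = 5°,
15°, 30°, 60°).

## What the generator does and does not emulate

It reproduces the analysis-relevant structure of DAM records — 1-min
bins, LD-entrained sleep pressure, a starvation effect gated at the first
LD shift acting on initiation only — and of traced arbors — a rooted
polyline skeleton with controlled angular dispersion. It does **not**
model circadian siesta shape within a phase, homeostatic rebound,
locomotor hyperactivity under starvation, dying flies, or image
segmentation noise in tracings. Passing recovery tests therefore shows
the pipeline measures what it claims on data with known truth; it does
not certify any biological claim about real flies.

# Numerical choices and degenerate inputs

* Geometric tolerance 1e-9 µm for ring-crossing deduplication and
  segment-endpoint decisions; angular tolerance 1e-9° for cone
  membership.
* Monitor files must be strictly minute-spaced; gaps are a hard error by
  default, and the optional repair mode inserts flagged zero-count
  minutes rather than interpolating, because silent interpolation would
  bias sleep scoring. Rows with invalid status codes are kept and
  flagged, never dropped; `scoreSleep(treatFlaggedAsActive = TRUE)`
  excludes them from sleep.
* Empty series, empty windows, Dunnett without a control, a fed mean of
  zero, and zero-crossing skeletons are all errors with specific
  messages, not silent sentinel values.
* A configurable dead-fly rule (`flagDeadFlies`: all-zero counts over the
  final N hours, default 12) is provided; its parameters are a
  convention, not a claim about any particular published protocol.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
generated at run time: 1,000 random activity vectors for the scoring
oracle, 200 arbors against a 0.01-µm dense-resampling crossing oracle
composed with an exhaustive cone-orientation oracle, 100 replicate
32-fly-per-arm cohorts for effect-structure detection, 2,000 replicates
for the t-test type-I calibration, and 100 fixed-seed arbors per spread
level for the DI monotonicity ensemble. These sizes give Monte-Carlo
standard errors comfortably below the effects being checked while keeping
a full run in the tens of seconds on one core.

# Known limitations

* DI is 2-D by construction; arbors that defasciculate mostly in z are
  under-measured by any projection-based index.
* The exact cone search is O(n²) in the number of crossings — negligible
  for Sholl counts (tens to hundreds) but not meant for thousands.
* The sleep generator's geometric dwell times are a modeling convenience;
  quantities beyond stationary fractions (e.g. bout-length tails) should
  not be read as realistic.
* `compareMany` fits a fixed-effects one-way layout only; repeated
  measures or mixed designs are out of scope.
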