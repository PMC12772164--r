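---
title: "Fishing fleets as ecosystem sentinels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fishing fleets as ecosystem sentinels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleetsentinel)
```

## The question and the observing system

Species distribution shifts under ocean warming are hard to observe
directly: surveys are sparse, telemetry is biased toward tagged
individuals, and correlative species distribution models (SDMs) carry
their own assumptions. A commercial fleet that targets one species is a
different kind of instrument. Its vessels integrate environmental cues,
market conditions and fishing success into a decision about where to
fish, and regulation makes the outcome observable: vessel monitoring
system (VMS) transponders report position roughly hourly, and landings
receipts record what each trip brought ashore. This package operationalises
the question *"does the fleet's behaviour predict extreme distribution
shifts of its target species?"* as a reproducible pipeline, with a
synthetic study system standing in for the confidential vessel-level data.

## Linking pings to landings

The join is the pipeline's foundation and is deliberately conservative.

* **Receipt filter.** Only receipts with at least 90% of landed weight in
  albacore are used (inclusive boundary: exactly 90% qualifies). Mixed
  tickets dilute the link between position and albacore catch.
* **Trip windows.** Pings are attributed to the receipt that follows them
  in time, back to the previous receipt or at most one trip cap — the
  75th percentile (nearest-rank) of per-vessel inter-receipt durations,
  with a configurable fixed override (default 16 days) when durations
  cannot be computed. The window is half-open `(prev, receipt]`, so a
  ping at the earlier receipt's exact timestamp belongs to the earlier
  trip and no ping is ever double-assigned. Two receipts of one vessel at
  the same instant are processed in ticket-id order and the later ticket
  takes the shared boundary ping.
* **Fishing filters.** Quality-flagged pings are dropped; only `at_sea`
  event types are kept; `time_forward > 121` min (more than one missed
  hourly ping) marks a signal break and removes the ping; speeds must be
  *strictly* below 3.74 kn to count as trolling. The boundary conventions
  — keep `time_forward = 121`, remove `speed = 3.74` — are exposed as
  arguments; the speed equality case is not observable in practice but a
  fixed convention keeps the filters idempotent and order-free
  (intersection semantics).
* **Allocation.** Each receipt's albacore pounds are split over its
  fishing pings proportionally to `time_forward`. Conservation is exact
  up to floating point and is asserted at `rtol = 1e-9` in the tests.
  Receipts whose assigned pings all have zero `time_forward` cannot be
  allocated; they are dropped with a warning rather than silently
  assigned.

## Indicator construction

Three fleet series are built per day: the albacore-pounds-weighted
latitude centroid (`vms_y`, °N), the pounds-weighted mean great-circle
distance to the coastline (`vms_shore`, km), and CPUE (`vms_cpue`,
lbs landed per minute of fishing time). Two environmental series mirror
them: SST averaged inside the fleet's utilization kernel (`ssta`, °C) and
the core-habitat centroid/distance series per species (°N, km).

Every series passes through the same fixed chain, in this order:

1. **Monthly climatology anomalies.** Each day minus the mean of its
   calendar month over the reference years. A monthly rather than daily
   baseline is used because a 15-year record gives each calendar day at
   most 15 samples. Anomalies have exactly zero mean per calendar month
   over the climatology period (a tested invariant).
2. **30-day right-aligned rolling mean.** The value at day *t* averages
   the available values in `[t−29, t]` — right alignment preserves the
   real-time character of the indicator (nothing future leaks in). A
   smoothed value is emitted only when at least 15 of the 30 window days
   are present; sparser windows would let a couple of trips masquerade as
   a monthly signal. The threshold is configurable.
3. **Season restriction** to July–October, the peak fishing season.
   Restriction comes *after* smoothing so early-July values still
   integrate late-June days; reversing the order changes season-edge
   values and is pinned by a regression test.

Ordering matters: anomalies before smoothing keeps the seasonal cycle out
of the rolling mean; smoothing before restriction keeps window support
intact at season edges.

**Utilization kernel.** The SSTa mask is the level set of a weighted
bivariate Gaussian kernel density estimate over ping positions (weights =
`time_forward`), evaluated at SST grid cell centres, normalized, ranked,
and cut at 75% cumulative probability of use. The bandwidth is a full
(anisotropic) normal-reference matrix `H = n_eff^(−1/3) Σ̂`, the
Wand–Jones normal-scale rule for two dimensions, with `Σ̂` the weighted
sample covariance and `n_eff` the Kish effective sample size. A full
matrix is essential here — coastal effort clouds are strongly elongated
alongshore — and the normal-scale rule is an analytic, deterministic
choice whose 75% mass property is verified directly against synthetic
clouds (observed mass within ±0.05). The kernel is estimated once from
all years pooled (a static footprint); an annual variant is a one-line
change but the pooled mask matches how a fleet's grounds are described.
Degenerate (zero-variance) clouds get a small diagonal bandwidth floor
with a warning.

**Core habitat.** Habitat suitability is masked to the EEZ polygon (kept
wide so distribution shifts stay inside the mask), then each day's cells
strictly above that day's 75th-percentile suitability form the core. The
percentile is computed *per day*, so the indicator tracks the shape of
the distribution rather than its long-term amplitude; the alternative
(one global threshold) is exposed through the percentile argument but
per-day is the default. With a strict `>` rule a perfectly uniform field
has an empty core and the day is missing — an honest answer for a
degenerate input. One percentile definition — nearest-rank (inverse
empirical CDF) — is used everywhere in the package so thresholds are
always attained sample values.

**Distance to shore.** Nearest points on coastline segments are located
in a local equirectangular projection (exact for the straight synthetic
coastline, sub-1% error at these scales for gently curved ones) and the
reported distance is the great-circle distance to that nearest point.
The implementation is validated against `geosphere::dist2Line` in tests.

**Confidentiality grid.** Fishing hours are summed on a 0.1° grid and
cells with fewer than four distinct vessels are suppressed (exactly four
is retained), with the suppressed share of hours and pings reported —
the standard rule for publishing vessel-derived maps.

## Extreme-event skill: SEDI

Extremes are defined by percentile thresholds on the pooled multi-year
seasonal series — "extreme" means rare over the record, not rare within a
year — at six levels, 0.70 to 0.95 in steps of 0.05. A day is an event
when its smoothed anomaly strictly exceeds the nearest-rank threshold.
For a predictor/response pair the 2×2 table of joint events gives the
hit ratio `H` and false-alarm rate `F`, and

$$\mathrm{SEDI} = \frac{\log F - \log H - \log(1-F) + \log(1-H)}
                       {\log F + \log H + \log(1-F) + \log(1-H)}.$$

SEDI was chosen for exactly the regime this analysis lives in: it does
not degenerate as events become rare and its value is comparable across
event frequencies. It is bounded in [−1, 1], zero for `H = F`
(random), positive iff `H > F`, increasing in `H` — all verified by
exhaustive enumeration of small tables and dense grid sweeps in the test
suite. The score is invariant to the logarithm base (numerator and
denominator scale identically); natural logs are used.

**Degenerate tables.** When any of `H`, `F` hits 0 or 1 the logs diverge.
Rather than dropping those grid cells (which would blank exactly the most
extreme, most interesting percentiles), rates are clamped to
`[1e−9, 1−1e−9]` and the result is flagged `degenerate`. A perfect table
then scores within `1e−6` of 1. When an entire margin is empty (no
observed events at all) the score is undefined and returned as missing
with a reason. Days missing in either series are deleted pairwise before
the table is built.

**Uncertainty.** A 30-day-smoothed seasonal series is so autocorrelated
that day-level resampling would be meaningless; the bootstrap therefore
resamples whole years with replacement (block bootstrap at the season
scale) and reports percentile intervals. With only a few heatwave years
in a 15-year record these intervals are wide — that is the honest
statement of how much a short record can certify.

## Driver attribution

Two ordinary-least-squares models — fleet latitude and fleet shore
distance — regress on five candidate drivers: the same-axis habitat
shift, SSTa, fuel price, weather-alert area, and price per pound. All
variables, response included, are z-scored over complete-case days
(standardizing both sides is what makes β a standardized effect size),
so coefficients are directly comparable and invariant to shifting or
rescaling any raw series (tested). Driver series are gap-filled by
linear interpolation before processing, interior gaps only — no
extrapolation past the record ends. p-values are plain OLS by default;
a Newey–West robust option exists (`robust = TRUE`) but is off by
default because the smoothed series' autocorrelation is part of the
estimand's context, and the plain version is the baseline analysis this
package mirrors. Rank-deficient designs fail with the collinear
predictors named.

## The synthetic study system

`gen_scenario()` emulates the features of the real system that the
pipeline must survive, with known ground truth:

* a fixed West-Coast-like box (131–124.5°W, 38–49°N) with a straight
  meridional coastline and a rectangular EEZ;
* 15 seasons (2010–2024 by default), 20 vessels, 4 trips per season of
  ~8 days, hourly pings; trips run port → fast transit (7–10 kn) →
  fishing (0.5–3.2 kn, jittered around the chosen grounds) → return, so
  the speed filter separates cleanly;
* injected signal breaks (runs of dropped pings leaving
  `time_forward > 121`), GIS quality flags, port events, and a fraction
  of receipts below the 90% albacore rule — every filter has something
  to remove;
* heatwave years (2014–2016 by default) add a +2 °C fishing-season SST
  anomaly, shift the habitat centre 1.5° north and 30 km inshore, and
  halve CPUE (factor 0.54 against a 7.8 lbs/min base — an availability
  collapse of the size a disaster declaration would cite);
* the fleet follows the *anticipatable* habitat centre (seasonal cycle
  plus heatwave shift) with probability `effort_tracking` (0.8 by
  default), else fishes uniformly at random. Day-to-day habitat noise
  (AR(1), 0.15° sd) is deliberately *not* tracked: fishermen respond to
  regimes, not to daily wiggles of a model field. This is also what makes
  the null scenario genuinely null — with no heatwave shift, fleet and
  habitat anomalies share nothing but climatology, and SEDI is
  statistically indistinguishable from zero (bootstrap interval covers
  0, a tested acceptance property);
* receipts' albacore pounds equal the trip's true fishing minutes times
  a per-trip CPUE rate — exact by construction, so allocation
  conservation can be asserted tightly;
* drivers are autocorrelated daily series (near-random-walk fuel and
  ex-vessel price, seasonal weather-alert area) with missing-day runs
  for the interpolation path; configured "true" standardized effects are
  wired into a synthetic response column for recovery tests.

Everything is deterministic given the seed, byte-for-byte.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: real geography and bathymetry,
multi-fishery and multi-gear behaviour, port-choice economics, spatially
correlated SST noise and fronts, preferential sampling (the fleet
observing only where it chooses to go), management closures, and any
behavioural response of effort to the driver series. Results on the
synthetic system validate the *machinery*; ecological conclusions still
require the confidential data the real analysis uses.

## Problem sizes and numerical choices

The test suite exercises a 6-year, 8-vessel scenario (~35k pings) for
module checks and a 15-year, 20-vessel scenario (~190k pings) plus its
null twin for the sentinel-recovery check; both run in a couple of
minutes on one core. Grid resolution defaults to 0.5° for the synthetic
fields — fine enough that the 1.5° habitat shift spans several cells,
coarse enough to keep field arrays small. Key numeric conventions, in
one place: nearest-rank percentiles everywhere; allocation conservation
at `rtol 1e−9`; SEDI clamp `ε = 1e−9`; smoothing coverage ≥ 15/30 days;
KDE mass property ±0.05; bandwidth floor `1e−4` deg² on degenerate
clouds. All thresholds are arguments with these defaults, not constants.

## Limitations

Skill estimates from short records are fragile at the most extreme
percentiles (the 0.95 level often has single-digit event counts; the
degenerate flag marks where the clamp, not the data, sets the value).
The OLS p-values ignore residual autocorrelation unless `robust = TRUE`.
The synthetic coastline makes "distance to shore" essentially a
longitude transform; with real coastlines the densified-segment distance
is approximate at the sub-percent level. And SEDI measures association
of extremes, not causation — the driver regression is attribution by
correlation, nothing stronger.
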