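---
title: "Methods: models, estimators and design choices in classair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in classair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classair)
```

`classair` analyses before/after portable-HEPA deployments in classrooms
exposed to roadway and aircraft pollution. This vignette explains the
underlying models, the estimators and their assumptions, the tunable
parameters, what the bundled simulator does and does not emulate, and the
design choices made where the field protocol leaves the analysis
under-determined.

## The single-zone mass balance

All particle analyses treat the classroom as one well-mixed zone. With
outdoor concentration $C_{out}(t)$, the indoor concentration obeys

$$\frac{dC_{in}}{dt} = P\,a\,C_{out} - \left(a + k_{dep} + \frac{CADR}{V}\right) C_{in},$$

where $a$ is the outdoor air-exchange rate (AER, 1/h), $P \in (0,1]$ the
envelope penetration factor, $k_{dep}$ the first-order deposition rate to
indoor surfaces (1/h), $CADR$ the clean-air delivery rate of the portable
filter (m³/h, zero when off) and $V$ the room volume (m³). For constant
inputs the indoor/outdoor ratio settles at

$$I_\infty = \frac{P\,a}{a + k_{dep} + CADR/V},$$

the model-implied infiltration factor ([`steady_state_ratio()`]). Removal
effectiveness follows as $E = 1 - I_{on}/I_{off}$, which for constant
parameters reduces to $1 - (a+k_{dep})/(a+k_{dep}+CADR/V)$ when $P$ and $a$
do not change with the intervention.

Assumptions worth keeping in view: a single perfectly mixed zone, no indoor
particle sources, first-order losses only, and HVAC recirculation
filtration lumped into $k_{dep}$. Multi-zone behaviour, coagulation and
size-distribution dynamics are out of scope.

### Numerical integration

`simulate_indoor()` advances the state with the exact per-step exponential
solution, holding the outdoor concentration constant within each step:

$$C_{n+1} = C_{ss} + (C_n - C_{ss})\,e^{-L\,\Delta t}, \qquad
  C_{ss} = \frac{P\,a\,C_{out,n}}{L},$$

with total loss rate $L$. Unlike a naive Euler update, this is
unconditionally stable and does not bias the steady state, so halving the
step changes long-run windowed ratios only through the zero-order hold on
the driver (verified to be under 0.1% in the test suite). Integration
starts at the steady state implied by the first outdoor sample, which
removes an arbitrary burn-in transient. The degenerate case $L = 0$ (no
exchange, deposition or filtration) falls back to the exact linear
accumulation rule.

## What the simulator emulates — and what it does not

`simulate_outdoor()` produces `baseline + diurnal + plumes`, with
multiplicative lognormal noise:

| parameter | default | meaning |
|---|---|---|
| `baseline` | 5000 #/cc | urban near-airport background; 5000 #/cc is a typical study-median outdoor level |
| `diurnal_amplitude` | 2000 #/cc | sinusoidal traffic cycle peaking at 08:00 |
| `plume_rate` | 3 /h | Poisson arrivals of aircraft plumes |
| `plume_peak`, `plume_decay` | 15000 #/cc, 20 /h | plume onset height and washout (e-folding ≈ 3 min) |
| `noise_cv` | 0.2 | multiplicative lognormal measurement scatter |

These defaults are fixed study conditions, not tuning knobs: they describe
a plausible instrumented day at a school under a flight path. CO₂
experiments instead carry additive Gaussian noise (default 5 ppm), the
conventional error model for NDIR gas analyzers.

`add_instrument_noise()` overlays a measurement model (multiplicative CV
plus an additive floor) on a simulated physical series. The floor matters
for one qualitative result: in the mass balance alone, running the filter
*shortens* the indoor response time constant and therefore *improves*
indoor–outdoor tracking. The observed decoupling under filtration arises
only when the collapsed indoor signal approaches the instrument noise
floor (or unmodelled indoor variability). The correlation-ordering test
therefore simulates a calm day at 1-min sampling with a few-hundred-#/cc
floor, the regime where a scanning sizer's precision genuinely limits the
signal. Passing tests consequently validate the estimators under
well-mixed single-zone physics with instrument noise; they do not
demonstrate robustness to indoor sources, zonal heterogeneity, or
size-dependent penetration, none of which the generator produces.

The synthetic flight generator constructs straight-line tracks that either
pass through the exposure geofence (closest approach at most 0.85 of the
radius, altitude at most 0.9 of the ceiling) or demonstrably miss it
(either 1.2 radii to the side, or overhead above 1.1 ceilings), so the
per-flight ground truth is known by construction with margins, independent
of the counting code under test.

## From raw series to windows

Instrument files are read into a tidy per-sample table with a quality flag
(`ok`, `error`, `trimmed`, `substituted`). Design choices in this layer:

- **Valve demultiplexing** assigns each sample of an alternating-inlet
  series to indoor or outdoor by its position in the cycle; the cycle is
  indoor-first from `phase_origin` by default (configurable — the switch
  times alone do not identify which location starts). The first 2 min of
  each 5-min interval are flagged `trimmed` to discard line-purging air.
  Trimming is applied uniformly to all valve-switched channels, not only
  the scanning sizer: uniform trimming keeps channels aligned, at the cost
  of discarding some valid data on fast instruments. This is an assumption,
  flagged as such.
- **CPC substitution** fills error gaps in the total-UFP channel with the
  nearest condensation-particle-counter sample within 30 s. It never
  applies to size-resolved channels, which the CPC cannot represent, and it
  can only increase the usable-sample count.
- **Window averaging** uses half-open 30-min windows aligned to the hour
  (the alternation protocol switches on round 5-min marks, so hour
  alignment keeps whole valve cycles inside windows). Coverage is the
  usable-sample fraction at the native sampling rate; windows under 50%
  coverage are flagged unusable. The 0.5 threshold balances bias from
  partially sampled windows against discarding data — the protocol itself
  sets no missing-data rule.
- All timestamps are normalised to one configured timezone (UTC by default)
  at read time; instrument clocks frequently disagree on offset.

## Estimating infiltration and effectiveness

Per-window ratios $I_w = \bar C_{in,w} / \bar C_{out,w}$ are computed on
aligned usable windows. Windows whose outdoor mean is at or below a floor
(default 50, in the channel's units — about 50 #/cc for counts; an
analogous 0.05 µg/m³ is appropriate for black carbon) are excluded to keep
near-zero denominators from dominating. The aggregate infiltration is the
**mean** of window ratios, with the median reported alongside: the field
convention speaks of average infiltration, while medians are more robust to
plume-transient windows — exposing both avoids the choice becoming silent.
Ratios are deliberately not capped at 1: values above 1 indicate indoor
sources and should be visible, not clipped, since the outdoor-origin
assumption is exactly what they violate.

Confidence intervals are percentile bootstrap over windows (2000 resamples,
seeded). For effectiveness, the filter-off and filter-on window sets come
from disjoint periods, so the bootstrap resamples the two sets
independently — there is no natural pairing of an off-window with an
on-window. Windows are treated as exchangeable; serial correlation between
adjacent 30-min windows will make these intervals somewhat anti-conservative
on strongly autocorrelated data, which coverage is checked against in
simulation rather than assumed.

The one-sided Wilcoxon rank-sum test asks whether pre-intervention
infiltration is stochastically greater than post-intervention, at
$\alpha = 0.05$. The exact null distribution is used for combined $n \le 20$
without ties; otherwise the normal approximation with tie correction. The
fully tied case is degenerate and reported as $p = 1$ with a warning.

## The lagged log-log regression

`build_design()` pairs each indoor window with the outdoor window one lag
earlier (default 30 min — indoor peaks trail outdoor peaks by roughly one
window) and attaches a HEPA indicator and school label. Natural logs are
used, and the slope on lagged outdoor concentration is *estimated*, not
fixed at 1: the model lists it as a regressor, and an estimated slope lets
the data speak about proportionality. Rows with non-positive indoor or
outdoor means are dropped and counted — zeros cannot enter a log model —
and a session is flagged when more than 20% of its rows drop; whole-session
exclusion (the choice made for heavily zero-inflated sites) is then the
analyst's call rather than an automatic rule.

`fit_loglog()` is ordinary least squares with school fixed effects
(reference: first school alphabetically). Mixed-effects and
autocorrelation-robust variants are deliberate non-goals. The HEPA
coefficient acts multiplicatively, so effectiveness is $1 - e^{\beta_H}$
and its interval is the transformed Wald interval of $\beta_H$ (equivalent
to the delta method on the coefficient scale). Predictions at a fixed
outdoor level (default 5000 #/cc) exponentiate the linear predictor with
its standard error propagated through the coefficient covariance. These are
confidence intervals for the *mean* indoor concentration, not prediction
intervals for a new window, and the point prediction is the conditional
median on the raw scale (no lognormal back-transformation correction is
applied); the ratio of on/off predictions, which effectiveness rests on, is
unaffected by that choice.

## The CO₂ decay fit

`fit_decay()` fits $C(t) = C_{bg} + A_0 e^{-k\,\Delta t}$ over the decay
window by Levenberg–Marquardt nonlinear least squares, with starting values
from the log-linear regression of $\ln(C - C_{bg})$ on elapsed time — the
log-linear slope is also reported as a cross-check, and the two agree
within 2% on clean data. Choices:

- **Background is fixed**, not jointly fitted: it is the mean ambient
  outdoor CO₂ over the window (a configurable constant, 420 ppm, stands in
  when no outdoor record exists). Fixing it matches the protocol's
  definition of the quantity of interest (in-room minus ambient) and avoids
  the strong $A_0$–$C_{bg}$–$k$ trade-off of a three-parameter exponential
  on short windows.
- Samples at or below background are excluded (their log-elevation is
  undefined and they carry no decay information); at least 10 usable
  samples are required.
- **Adequacy** follows the protocol: the elevation must have fallen to at
  most one-third of its starting value within the window; otherwise the
  fit is still reported with a warning and `adequate = FALSE`. Short means
  over the first and last six samples damp instrument noise in that check.
- **Uniformity** across the two room monitors uses a rolling (5-min)
  relative difference with a 10% tolerance — a concrete reading of
  "equivalent or very similar". Concurrent monitors are merged by pointwise
  averaging.
- $k$ is reported as the outdoor air-exchange rate. The decay of a
  conserved gas tracer in an unoccupied room is driven by infiltration and
  mechanical ventilation, not deposition, so the CO₂ simulator and the fit
  exclude deposition and filtration terms for this channel.

## Flight-operation counting

A flight counts at a site if *any* track point is strictly below the
altitude ceiling (default 750 m) and strictly within the radius (default
one statute mile, 1609.344 m) by haversine great-circle distance on a
sphere of radius 6371.0088 km. Each `flight_id` counts at most once per
site; a flight near two sites counts at both. Altitude is passed through as
given — whether it is above ground level or mean sea level is a property
of the source data, not resolved here. Per-group summaries use type-7
(linear-interpolation) quantiles, R's default.

## Unit conventions

Room metadata arrives in US units: `ft3_to_m3()` uses 1 ft = 0.3048 m
exactly, and `cfm_to_m3h()` uses 1 CFM = 1.699011 m³/h, so a 500-CFM
portable unit delivers 849.5 m³/h.

## Problem sizes and determinism

The validation suite runs at deliberately desk-friendly sizes chosen to
make Monte Carlo conclusions stable: 48-h sessions at 10-s resolution
(17 280 samples), 50 replicate deployments for effectiveness recovery and
interval coverage, 100 simulated decay experiments across the 0.6–4.4/h
AER range, a 24-configuration steady-state grid, 100-replicate power checks
for the rank-sum comparison, and 120-flight geofence ensembles. Every
stochastic step takes an explicit seed, and identical seeds give
bit-identical simulator output.

## Known limitations

- Penetration $P$ and deposition $k_{dep}$ are scenario parameters, not
  estimated quantities; field values for UFP vary widely with envelope and
  surface characteristics.
- Window-level bootstrap intervals ignore serial correlation between
  adjacent windows.
- The regression assumes one common outdoor slope and HEPA effect across
  schools; school-by-HEPA interactions are not modelled.
- The simulator's instrument model (lognormal CV + additive floor) is a
  simplification; real scanning sizers have size-bin-dependent counting
  statistics and occasional correlated error bursts, which appear here only
  as independent per-sample flags.
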