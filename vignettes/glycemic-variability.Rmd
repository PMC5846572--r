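---
title: "Arc-length glycemic variability: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arc-length glycemic variability: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvp)
```

## The statistic and its assumptions

A CGM trace is treated as a polyline in the (time, glucose) plane.
Between successive readings, $\Delta x_i$ is the elapsed time in minutes
and $\Delta y_i$ the glucose change in mg/dL; the trace length and
flat-line baseline are

$$L = \sum_{i=1}^{n} \sqrt{\Delta x_i^2 + \Delta y_i^2},
\qquad L_0 = \sum_{i=1}^{n} \Delta x_i,$$

and the glycemic variability percentage is
$\mathrm{GVP} = (L/L_0 - 1)\times 100$.

Three modelling commitments follow directly from this definition:

* **Mixed units are accepted as defined.** $L$ adds minutes and mg/dL in
  quadrature, with no rescaling of the time axis. This makes GVP
  unit-dependent: the same physiology expressed in mmol/L gives a
  different (much smaller) number, because the vertical components shrink
  18-fold against an unchanged horizontal axis. The package therefore
  refuses mmol/L input to `gvp()` unless `allow_mmol = TRUE` is passed
  explicitly, in which case it computes on the given scale and warns.
  We chose an error over silent conversion because a silently converted
  result would be numerically right but the caller's mental model wrong;
  and we chose warn-and-proceed for the override (rather than converting)
  so the unit dependence itself can be demonstrated and tested. A
  principled time-axis rescaling that would make the statistic
  unit-invariant is possible in theory, but there is no canonical scale
  factor, so none is guessed.
* **Actual timestamps, not the nominal grid.** $\Delta x$ always comes
  from the recorded times, so transmission jitter in real data is handled
  exactly; the nominal interval is used only to derive defaults.
* **Amplitude and frequency both count.** Doubling the amplitude of an
  oscillation or doubling its frequency both lengthen the trace. This is
  the property that separates GVP (and MAG, distance traveled) from SD
  and CV, which depend only on the marginal distribution of glucose
  values — `square_wave_experiment()` demonstrates it on four waves with
  identical SD/CV and ~27-fold different GVP.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `nominal_interval` | trace | 5 min | standard CGM transmission rate |
| `gap_threshold` | `detect_gaps()`, `gvp()` | 1.5 × nominal (7.5 min) | tolerates jitter; catches one missed transmission |
| `lag_hours` | `conga()` | 1 h | the conventional CONGA1 lag |
| pairing tolerance | `conga()` | nominal/2 | pairs sample *i* with *i − 12* on clean 5-min data |
| MAGE threshold | `mage()` | 1 sample SD | the classic excursion criterion |
| classification bands | `classify_gvp()` | 20 / 30 / 50 | minimal / low / moderate / high |

## Gap handling

Consecutive readings more than `gap_threshold` minutes apart split the
trace into runs; segments are formed only within runs, so both $L$ and
$L_0$ exclude the bridging interval. This implements "shorten the ideal
line by the missing time" while also avoiding a spurious long chord
across the hole, which would otherwise *add* arc length exactly where
data are absent. Leading, interior and trailing gaps are treated
identically (run-wise exclusion); nothing in the definition distinguishes
them, and a uniform rule is the only one that keeps the gap-accounting
identity `excluded + within-run = total span` exact. A run reduced to a
single sample contributes nothing; if *all* runs are singletons the
metrics raise an insufficient-data error rather than returning 0.

## Sampling interval

Decimating a trace (`resample_trace()`) acts as a low-pass filter: each
retained chord is no longer than the path it replaces, so GVP can only
decrease. The qualitative picture survives mild coarsening (10–15 min),
but the band thresholds are calibrated for 5-min data, and 30–60 min
sampling suppresses most of the frequency content the statistic exists to
measure; the package exposes decimation precisely so users can quantify
this on their own data. The decimation-monotonicity tests use traces
whose length is 1 mod 6 so that factors 2 and 3 preserve the final
sample; when decimation drops trailing samples the comparison is between
different time windows and the inequality can genuinely reverse — that is
a windowing effect, not a property violation.

## Numerical choices

* **Sample SD (n−1) everywhere** — trace SD, CONGA, the MAGE threshold.
  On a 2016-sample equal-dwell 40/400 wave this gives
  $180\sqrt{2016/2015} = 180.045$, matching the reference table at its
  printed precision; population SD (180 exactly) would not.
* **CONGA uses signed differences.** The standard definition is the SD
  of $G(t) - G(t-\text{lag})$. Published values computed by one external
  tool for the square-wave experiment (242.8–283.5, *increasing* with
  period) are not reproducible from this definition, which yields smaller
  values *decreasing* with period; that tool's internal variant is
  undocumented, so those numbers are not used as references anywhere in
  the test suite.
* **MAGE** collapses plateaus, finds turning points as sign changes of
  the move directions (endpoints included), keeps excursions whose
  amplitude exceeds one SD, and averages them in the direction of the
  first qualifying excursion. Several computerized MAGE variants exist
  and disagree; this is the classic turning-point reading, and the tests
  pin it against an independent state-machine oracle rather than against
  any published clinical value.
* **Percentiles** use linear interpolation between order statistics
  (`quantile()` type 7). The convention is pinned by tests against a
  sort-based oracle; nearest-rank would differ in the tails of small
  cohorts.
* **Band boundaries go to the lower class** (20 → minimal, 30 → low,
  50 → moderate): the published band edges overlap at 30 and 50, and
  left-closing from above gives every value exactly one label.
* **Duplicate timestamps are rejected**, not averaged: silent
  aggregation would change $L$.
* **Unit conversion** uses 18.016 mg/dL per mmol/L (glucose molar mass).

## The square-wave experiment

`square_wave()` samples at $t = 0, s, \dots, (N-1)s$ with
$N = \lfloor 60\,\text{duration}/s \rfloor$ — 2016 samples and
$L_0 = 10{,}075$ min for 7 days at 5 min. The final half-period boundary
at $t = 10{,}080$ is never sampled, which is what makes the transition
counts (27, 13, 5, 1 for full periods 12, 24, 56, 168 h) and hence the
reference GVP/MAG values come out exactly. Rows of
`square_wave_experiment()` are labelled by *half* period — the dwell time
at each level (6, 12, 28, 84 h) — matching how the reference table
indexes them; the generator itself is parameterized by the full period.
The start level is a free choice (all reported metrics are
dwell-symmetric); waves start low. All generated-wave metrics are tested
against closed forms: with $k$ sampled transitions of amplitude
$A = 360$, $\mathrm{GVP} = k(\sqrt{s^2+A^2}-s)/L_0 \times 100$ and
$\mathrm{MAG} = kA/(L_0/60)$.

## What the synthetic cohorts are — and are not

`synth_cohort()` builds each subject as baseline + randomly timed
raised-cosine "meal" bumps (2 h span) + AR(1) noise, clipped to the
40–400 mg/dL CGM reporting range, fully determined by its seed. The five
`cohort_preset()` profiles were calibrated once so that 50-subject
cohorts at 7 days/5 min land their median GVP in the intended bands
(≈14% nondiabetic, ≈26% type-2 adult, ≈42% type-1 adult, ≈55–60%
pediatric type 1), then frozen.

This generator emulates the *statistical envelope* of CGM cohorts —
plausible amplitudes, per-step changes, and a reproducible spread of GVP
across the four bands. It does **not** emulate circadian structure,
insulin dynamics, sensor dropout/compression artifacts, or
inter-metric correlations of real cohorts. Consequently, passing cohort
tests shows the pipeline (generation → gap handling → GVP → percentiles →
classification) is correct and reproducible; it does not validate the
clinical percentile values reported for real study cohorts, whose
subject-level data are not public and are not reproduced here.

## Problem sizes

The test suite and the acceptance script run everything at the scale the
analyses themselves specify: 2016-sample waves, 50-subject cohorts at
168 h, and property sweeps over 200 seeded 97-sample traces — a few
seconds end to end on a single core.

## Known limitations

* GVP is unit- and sampling-rate-dependent by construction; values are
  comparable only at matched conventions (mg/dL, ~5-min sampling).
* No imputation is offered: gap interiors are excluded, never filled.
* MAGE on real, noisy traces is sensitive to the plateau-collapsing rule;
  small sensor noise can create spurious turning points (no pre-smoothing
  is applied).
* The CONGA variant implemented is the standard one; numbers from tools
  using undocumented variants will differ.
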