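---
title: "Isometric dynamometry: signal conditioning, RFD algorithms, and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isometric dynamometry: signal conditioning, RFD algorithms, and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdtools)
```

## The measurement problem

A maximal isometric contraction recorded by a dynamometer is a force-time
trace: a rapid rise from rest to a plateau held for a few seconds.
Strength is the peak force (kg). Power is summarised by the rate of force
development (RFD, kg/s), some slope of the rising limb. Devices differ in
sampling behaviour — a stable 40 Hz hand-held unit, a hand-held unit
sampling "approximately" 100 Hz with a jittery clock, and a fixed
laboratory dynamometer at a stable 1000 Hz — so raw traces must be
brought onto a common footing before any cross-device quantity is
meaningful. And because RFD has no consensus definition, a toolkit must
compute the whole family of candidate algorithms and provide the
reliability statistics used to choose among them.

`rfdtools` treats every stage as a tidy operation: traces are tibbles
with attributes, batteries and agreement reports are tibbles, and
everything chains with the pipe.

## Signal conditioning

Two operations, in a deliberate order:

1. **Resample** to a uniform grid (default 1000 Hz) by cubic-spline
   interpolation. Output times are `t0, t0 + 1/rate, ...` truncated at
   the last recorded time — the spline is never extrapolated. Input
   samples that land on the output grid are preserved exactly.
2. **Filter** with a zero-phase low-pass Butterworth: a 10 Hz cutoff,
   order-4 design applied forward and backward, so the phase is exactly
   zero and the effective magnitude response is `1/(1 + (f/10)^8)`.

Resampling comes first because zero-phase filtering is only well defined
on a uniform grid; for devices whose clock is already stable the reverse
order (`filter_first = TRUE`) agrees within filtering tolerance, and both
orders are exposed. Jittered timestamps are trusted as recorded — the
generator jitters the clock, so the resampler must cope with it, and no
clock "correction" is attempted.

**Spline end conditions.** We use `stats::splinefun(method = "fmm")`,
which fits an exact cubic through the four points nearest each end. Like
the not-a-knot condition it reproduces cubic polynomials exactly (the
property the tests assert to 1e-9), and it is the natural choice in R;
no boundary-derivative information exists in a force trace that would
justify anything stronger.

**Filter edge handling.** `signal::butter` supplies the coefficients, but
the forward-backward application is the package's own: the trace is
extended by odd reflection at both ends (three filter-state lengths) and
each pass starts from the filter's steady state. This is the conventional
`filtfilt` construction; it makes constant traces exactly invariant
(`DC gain 1`) and suppresses the start-up transient that naive
forward-backward filtering leaves at the edges. Downstream searches can
exclude a configurable edge margin, but the default margin is 0 ms:
RFD algorithms deliberately run from the first recorded sample.

**Near-idempotence.** Running the pipeline twice is not bit-identical:
the second pass re-attenuates energy near the cutoff by up to ~0.4%
(about 0.007 kg on a 50 kg logistic trace). That is a property of any
realisable low-pass, not an implementation artifact; the resampling stage
alone *is* exactly idempotent, and the test suite asserts both facts.

## The RFD family

All methods run on the preprocessed trace, from the first recorded
sample, with no contraction-onset detection. Onset definitions are a
known source of arbitrariness; searching the whole trial instead means an
initial contact artifact only matters if its slope beats the
contraction's, and the optional edge margin exists for pathological
cases.

- **Time to peak** (`time_to_peak()`): seconds from the first sample to
  the first maximal sample. Ties go to the earliest sample everywhere in
  the package — determinism is a design rule.
- **Percent-of-peak window** (`rfd_percent_window(trace, lo, hi)`):
  thresholds at `lo`% and `hi`% of the trial's own peak (each trial is an
  independent contraction, so thresholds reference the per-trial peak,
  not the across-trials peak). Threshold times are first upward crossings
  on the rise to the first maximum, linearly interpolated between the
  bracketing samples for sub-sample accuracy. The value is the endpoint
  slope `(hi - lo)%·peak / (t_hi - t_lo)`; a maximal sub-slope search
  restricted to the same segment is available via `subslope = TRUE`, but
  the endpoint slope is primary — the force interval is fixed by
  construction, only the duration varies. A threshold never crossed
  before the peak (e.g. a large contact spike) yields a flagged `NA`,
  never an exception, so one bad trial cannot abort a batch.
- **Moving window** (`rfd_moving_window(trace, window_ms)`): the maximum
  of `(F[i+w] - F[i])/(w·Δt)` over every start sample, window lengths
  10-200 ms converted to samples by `round(window_ms·rate/1000)` (exact
  at 1000 Hz). Because a long window's mean slope is an average of short
  window slopes, the 10 ms value can never be below the 200 ms value —
  a property the tests check on random traces.

`compute_battery()` evaluates all 14 methods per trial. Peak force
follows the two-trial rule (highest sample across both trials); the
across-trials RFD aggregate defaults to the maximum, mirroring that rule,
with `mean` and `best_trial` as explicit alternatives since the
convention is genuinely underdetermined.

## Agreement statistics

For a test-retest, between-rater or between-device pair `(x, y)` over n
subjects:

- **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures: `(MSR - MSE) / (MSR + MSE + (2/n)(MSC - MSE))` from the
  two-way ANOVA mean squares. Absolute agreement means a systematic
  offset between occasions lowers the coefficient even when the ranking
  is perfect; estimates can legitimately be negative. The 95% CI uses
  the F-distribution method with Satterthwaite degrees of freedom.
- **SEM** — `SD₁·√(1 - ICC)`, with SD₁ the first-occasion standard
  deviation. A negative ICC inflates the SEM above SD₁, as it should.
- **MDC** — two multiplier conventions circulate in the clinimetric
  literature and published tables genuinely use both, so both are
  first-class and every report labels its variant: `sqrt2` gives
  `1.96·√2·SEM` (ratio 2.7719), `plain` gives `1.96·SEM`. Percent
  versions are expressed against the first-occasion mean by default
  (`mean_ref = "pooled"` is available); worked-example parity checks
  supported that reading.
- **Pearson r** with the Fisher-z interval; **Lin's concordance rc**
  with biased (1/n) moments and Lin's 1989 asymptotic variance of the
  z-transform. `|rc| ≤ |r|` always, with equality only when the pair
  sits on the identity line's location and scale.
- **Bland-Altman** — differences vs averages. If
  `|corr(d, a)| > 0.50` (absolute value, so negative proportional bias
  also triggers), the regression-based variant is used: a regression
  line of `d` on `a` for the bias, plus `±1.96·√(π/2)` times a fitted
  regression of absolute residuals on `a` for the limits.
- **Interpretation bands** — excellent ≥ 0.90, good 0.75-0.89, moderate
  0.50-0.74, poor < 0.50, applied after rounding to two decimals half
  away from zero so that a printed 0.75 classifies as good. All
  report-parity rounding in the package uses half-away-from-zero.
- **Method comparison** — per-method columns of per-muscle ICCs
  summarised by median, type-7 quantile IQR, and the count strictly
  below 0.75.

`run_comparison()` assembles the pairs per analysis cell
(muscle × metric × remaining fixed factors) with pairwise complete-case
handling; cells with fewer than 3 complete pairs are flagged, not fatal.
Missing values stay `NA` end to end — they are never coerced to zero.

## The synthetic generator

`simulate_trace()` models a contraction as a logistic rise
`F(t) = baseline + f_max / (1 + e^{-k(t - t0)})` over a 4 s trial
(within the 3-5 s protocol window). The logistic was chosen for its
closed forms, which double as test oracles: instantaneous peak RFD
`f_max·k/4` at `t0`; percent crossings at `t0 + log(p/(1-p))/k`; the
width-`w` chord slope `f_max·tanh(k·w/4)/w`. Defaults
(`f_max = 50 kg, k = 20 s⁻¹, t0 = 1 s`) give a plateau and rise steepness
in the range of lower-limb maximal efforts. Device grids: exact 40 Hz and
1000 Hz, and a 10 ms nominal grid with i.i.d. uniform ±3 ms jitter for
the unstable device. Optional extras: Gaussian measurement noise and a
half-sine contact bump at the start.

`simulate_cohort()` draws additive Gaussian components per
subject-by-factor combination, so the theoretical test-retest ICC for any
within-cell pairing is
`(σ²_subject + σ²_rater + σ²_device) / (… + σ²_session + σ²_error)` in
closed form. Fixed device offsets and heteroscedastic noise
(SD proportional to the expected value) are available to exercise the
concordance penalty and the regression-based Bland-Altman branch.

What the generator does *not* emulate: fatigue across trials,
non-logistic rise shapes (double-peaked efforts, tremor), correlated
noise, or rater behaviour beyond an additive effect. Passing tests
therefore demonstrate that the algorithms and statistics are computed
correctly and recover known ground truth under the stated model — not
that any particular device is reliable in humans; the coefficients for
real cohorts must come from real data run through the same functions.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen so the
whole suite runs in well under a minute of CPU: oracle equivalence uses
200 random traces of ≤ 750 samples; ICC parameter recovery averages 50
replicate cohorts of n = 2000 (a single n = 2000 draw has sampling SD
~0.024 at ICC 0.5, so a one-draw ±0.01 check would be testing luck, not
the estimator); CI coverage uses 100 replicates at n = 50 against the
93-97% binomial band. Degenerate inputs error informatively: zero total
variance (ICC), zero variance (Pearson), zero variance and mean gap
(concordance), zero reference mean (percent SEM), fewer than 3 complete
pairs, fewer than 4 samples (spline), traces shorter than the filter
padding or the RFD window.

Measurement-table CSVs write doubles with `%.17g` and parse them with
base R's correctly-rounded `strtod`, so write-then-read reproduces every
value to the last bit.

## Known limitations

- Lin's CI is asymptotic and undefined at `|rc| = 1` or `r = 0`; those
  cells report the estimate with `NA` bounds.
- The F-based ICC interval assumes the two-way normal model; heavy-tailed
  data will degrade coverage.
- The percent-window family is undefined for non-monotone artifacts that
  keep the trace above a threshold from the first sample; such values
  propagate as flagged missing.
- Only two MDC conventions are implemented; reports always label which
  one produced their numbers, since the two differ by √2.
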