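---
title: "State-partitioned maintenance metabolism: models, generators and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-partitioned maintenance metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrmosaic)
```

## The model in one paragraph

Maintenance metabolism is modelled as a mosaic of processes whose costs are
unevenly expressed across three behavioural states — quiet wakefulness, NREM
sleep and REM sleep. Each process `p` has a whole-day SMR share
(`total_smr_pct`, per cent of integrated daily maintenance costs) and a
partition of that share across states (`wake_pct`, `nrem_pct`, `rem_pct`).
A rate measurement made wholly within state `i` sees
`total_smr_pct_p * partition_{p,i} / 100` from process `p`; summing over
processes gives the state totals `M_i`, the relative metabolic rate levels
of the three states. With a time budget `T_i` (fractions of the 24-h day,
summing to 1), the integrated daily maintenance expenditure is
`IDME = sum_i M_i * T_i`, and any state-restricted measurement is a
time-weighted mean of the `M_i` over the measured states. Everything else in
the package — error curves, the individual-based simulation, treatment
detectability — is arithmetic on this object plus explicit stochastic
machinery for realistic measurement.

Two interpretive choices are worth stating. First, the per-state
contribution columns are read as *rate levels while in that state*, not as
time-integrated shares; this is the reading under which the ratios of the
state totals reproduce the familiar wake-referenced correction factors
(0.83 for NREM, 0.44 for REM at two decimals) and it is the one the package
adopts throughout. Second, the residual-background row is stored exactly as
conventionally printed (33/33/33, summing to 99, not renormalized):
bit-fidelity to the source table is preferred over tidiness, and
`validate_table()` reports rather than repairs the 1-point shortfall (its
default tolerance is 1 percentage point for precisely this reason). A side
effect is that the grand sum of all per-state contributions is 99.94 rather
than 100 — the spread-out accounting identity that *does* hold exactly is
`sum(total_smr_pct * row partition coverage)`, and that is what the tests
assert.

Percent/fraction conventions: files and the partition table use the 0–100
scale; programmatic time budgets and shares use 0–1 fractions; conversions
are explicit at the interfaces and never implicit.

## Sampling-error curves

For a day with wake fraction `p` and a fixed REM share of sleep `r`, the
architecture is `(p, (1-p)(1-r), (1-p)r)`. The sleep-only estimate
`((1-r) M_NREM + r M_REM)` is constant in `p` while the true integrated rate
increases with `p` (wake is the costliest state), so the sleep-only error is
negative and monotonically more negative in `p`. The wake-only estimate is
`M_WAKE`, so its error is positive and shrinks to zero as `p -> 1`:
overestimation grows with the *unmeasured sleep fraction*. Raising `r`
lowers both the sleep estimate and the truth, amplifying both error
magnitudes. All errors vanish identically when the three state rates are
equal, and are invariant to rescaling the profile by any positive constant.
The default grid is 81 points over wake fractions 0.10–0.90; the endpoints
are excluded because an animal that never wakes (or never sleeps) cannot be
measured in the opposite mode at all.

The REM share is exposed as a parameter (default 0.25, a mid-range mammalian
value) rather than fixed, since sources differ on whether such curves hold
it constant across the wake-fraction axis.

## The hypnogram generator

Bouts are drawn with state-specific exponential lengths (defaults WAKE 30,
NREM 20, REM 8 minutes — fragmented, mammal-like sleep) and the next state
is sampled *with rejection of the current state*. Under that scheme the
stationary visit frequency of state `i` is proportional to `w_i (1 - w_i)`
for sampling weights `w`, so the weights are solved by damped fixed-point
iteration such that stationary time shares `w_i (1 - w_i) m_i` match the
target fractions. Two refinements matter in practice:

- **Residual bout-mean correction.** With only two active states the
  alternation pins visit frequencies at 1/2 and no choice of weights can hit
  an arbitrary time split; any residual between implied and target shares is
  absorbed into per-state effective bout means. Fraction targeting takes
  precedence over exact bout-length means (the correction factor is ~1
  whenever the weight solve succeeds).
- **Deficit feedback.** A plain semi-Markov realization has `1/sqrt(T)`
  fluctuations in realized fractions, which is slower convergence than the
  generator contracts (mean absolute deviation from targets below 0.01 by
  1000 h on any seed). The sampler therefore up-weights states running
  behind their target time share, exponentially in the deficit measured in
  units of the state's own mean bout length (capped at `e^±5`). Measured
  over 30 seeds this brings the maximum deviation at 240 h under 0.006 and
  the MAD at 1000 h under 0.001, while bouts remain exponential and
  self-transitions remain excluded.

`exact = TRUE` rescales each state's bout durations after generation so the
realized fractions equal the targets exactly (splicing in one bout of any
targeted state that failed to appear in a short window). This mode backs the
fixed overnight windows of the individual-based simulation and the analytic
cross-checks, where the time budget is a specification, not a random
outcome.

## Rate traces and extraction estimators

A trace samples the hypnogram at bin midpoints (default 1-minute intervals,
an intermittent-flow-respirometry-like resolution). The state-conditional
mean is `baseline * M_state / M_WAKE`; noise is multiplicative Gaussian with
coefficient of variation `noise_cv`, truncated at zero so rates stay
non-negative (CV-stable and sign-safe; for the small CVs used here the
truncation is almost never active).

Three standard SMR extraction methods are included to study their
state-linked bias:

- `quantile_smr()` — the empirical `q`-quantile (R's default interpolation).
  On any trace spanning sleep, low quantiles disproportionately sample sleep
  states and undershoot the 24-h mean.
- `mlnd_smr()` — the mean of the lowest normal distribution: a two-component
  Gaussian mixture fitted by EM. Initialization is deterministic (means at
  the 10th/90th percentiles, equal weights, equal variances at half the
  sample SD) so the fit is reproducible without random restarts; the E-step
  runs in log space and component SDs are floored at
  `max(1e-8, 1e-6 * sd(x))` so that noise-free two-level traces converge
  cleanly instead of collapsing. A constant trace returns the constant with
  a warning. The in-package EM is cross-checked against an independent
  mixture fitter (mclust) in the test suite.
- `activity_extrapolation()` — OLS of rate on activity score; the intercept
  estimates SMR at zero activity. Degenerate designs (all scores equal)
  error rather than silently extrapolate.

## The individual-based measurement simulation

Defaults describe the simulated study population: 200 diurnal individuals
measured on 5 nights over fixed 12-h overnight windows; true integrated SMR
~ Normal(0.35, 0.05) truncated positive (arbitrary units); nightly sleep ~
Normal(9, 1) h truncated to [6, 12]; REM share of sleep ~ Beta(2, 2) mapped
to [0.10, 0.35]; night-to-night sleep jitter SD 0.5 h; per-sample
measurement noise CV 0.05; MMR = 3 × true SMR, held constant across states
(whether maximum performance itself varies over the diel cycle is untested
in most species, so the simulation deliberately does not model it). The
window-level parameters are fixed by the study design; the distributional
defaults are the package's own documented choices of realistic mammalian
values, set once.

Each individual's state rates are the packaged-table ratios scaled so its
24-h time-weighted rate equals its true SMR *exactly* (conservation to
1e-9 is a tested invariant). Consequently the *relative* sleep-only error is
a function of architecture alone, while the *absolute* error scales linearly
with true SMR — which is why higher-SMR individuals show larger absolute
underestimates even though the proportion of SMR missed is constant.

Measurement-noise convention: a "measurement" is the mean of a per-sample
noisy trace over its window. The noise on a window mean is therefore
`noise_cv / sqrt(n samples)` (about 0.2% for a 12-h window at 1-minute
sampling), not `noise_cv` itself. This convention is applied consistently in
the overnight estimates and in the treatment-discrepancy experiment, and it
is why essentially every simulated individual-night falls below the
identity line: the architecture-driven bias (typically −7 to −11%) dwarfs
the averaged-out trace noise.

## Treatment detectability

A treatment multiplies the whole-day cost of its target processes by a
constant factor, across all states (partitions unchanged). Detected effect
under a window is the proportional change of that window's rate; the
integrated window uses the time-weighted rate and decomposes exactly as the
base-rate × time-share weighted mean of the state effects (a tested 1e-9
identity). The heatmap normalizes each treatment row by its
largest-magnitude entry, preserving sign in the signed matrix and reporting
magnitudes in the normalized one; ties in the row maximum (possible only in
contrived tables) are broken in window order WAKE < NREM < REM < INTEGRATED
and flagged. Reference treatments: protein-synthesis inhibitor ×0.5 (the
one magnitude the model narrative fixes), ion-transport blocker ×0.5 on
both ion-regulation rows, thermal stress ×1.5 on thermoregulation — the
latter two magnitudes are config-exposed defaults, since only the direction
of those manipulations is specified. Pharmacokinetics and time-varying
effects are out of scope; factors are constant within a run.

The sleep-only discrepancy experiment reports both the sleep-only and the
24-h integrated treatment effect *relative to the untreated time-integrated
SMR*, per individual-day. Because the per-individual rate scaling cancels in
these ratios, the scatter across individuals is driven by sleep duration and
REM:NREM variation — exactly the point: apparent between-individual
variation in treatment response can be pure sleep architecture. An
individual-day with zero sleep cannot be sampled sleep-only and is flagged
rather than imputed.

## Numerical and design notes

- Internal arithmetic uses exact ratios; rounding (e.g. multipliers to two
  decimals) happens only at presentation or on request.
- State labels are exactly `WAKE`, `NREM`, `REM` in every file, config and
  report. `compute_idme()` accepts any number of labelled states matched by
  name (e.g. splitting NREM into light/deep), since the time-weighted sum is
  generic; the three-state set is just the default.
- Tolerances: architecture fractions must sum to 1 within 1e-9; cross-module
  identities (IDME vs integrated rate; effect decomposition) are tested to
  1e-12 / 1e-9; table validation defaults to 1 percentage point.
- Reproducibility: every stochastic entry point takes a seed; the workbench
  records seed, options and package version in a JSON manifest next to each
  output, and repeated runs with the same seed are byte-identical.
- Problem sizes used by the test suite (chosen to make distributional checks
  stable at interactive runtimes): populations of 200 × 5 nights for the
  bias and treatment experiments, hypnograms of 240–1000 h for convergence
  properties, traces of 24 h at 1-minute resolution for estimator bias.

## What the synthetic data does and does not emulate

The generator reproduces per-individual variation in integrated SMR, sleep
duration and REM share, bout-structured state alternation, and noisy rate
traces with state-conditional means. It does **not** emulate: circadian
drift within states (each state has one characteristic rate); transitional
dynamics between states (switches are instantaneous, though real transitions
likely involve overlapping activation of processes); activity-driven
metabolic excursions during wake (all wake time is quiet wakefulness — an
SMR context); apparatus effects (flush/closed cycles, chamber stress);
unihemispheric sleep; or ectotherm-specific parameterizations (the packaged
thermoregulation row is endotherm-like; users can supply their own table).
Passing tests therefore demonstrate internal consistency of the
state-partitioned model and the behaviour of estimators *under that model*,
not the accuracy of the partition values themselves, which carry the
uncertainty rankings shipped with the table.
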