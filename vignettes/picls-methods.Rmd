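---
title: "Methods: PI-based chronological lifespan quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PI-based chronological lifespan quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picls)
library(dplyr)
```

## The assay and its model

Chronological lifespan (CLS) is measured on non-dividing yeast in
stationary phase. Propidium iodide (PI) is membrane-impermeant and stains
only dead cells, so a stained culture read in a plate reader yields two
channels per well: PI fluorescence (excitation 535 nm / emission 617 nm),
proportional to dead-cell density, and OD600, proportional to total cell
density. The survival statistic normalizes fluorescence by OD, subtracts
the unstained-cell background, and scales by the dynamic range between the
two on-plate controls:

$$\mathrm{Survival} = \left(1 - \frac{I_{ij}/OD_{ij} - I_c/OD_c}
  {I_D/OD_D - I_c/OD_c}\right)\times 100\%$$

with $c$ the unstained negative control (100% live by definition) and $D$
the boiled positive control (0% survival). Two properties follow directly
and are enforced by tests: the statistic is invariant to rescaling either
channel (gains cancel), and the controls' own means map exactly to 100%
and 0%.

Assumptions worth stating: fluorescence per unit OD is the same for dead
cells in a sample well and in the boiled control (same staining, same
plate); OD normalization is only trustworthy inside the calibrated linear
range; and controls are summarized **per plate per age day**, because
staining efficiency and optics drift between plates and days.

The clock starts at day 1 = the 72-h growth time point; all curves are
indexed in days from there.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `od_floor` | 0.05 OD | wells below it are excluded, not scored: division by near-zero OD is unstable and 0.05 is the lower edge of the validated calibration range |
| `min_controls` | 3 per role | minimum control wells per plate/day; triplicates are the floor for a usable SD |
| `r2_threshold` | 0.98 | linear-range trimming target; see below |
| `cv_warn`, `cv_fail` | 0.20 / 0.35 | replicate-CV QC bands (unitless CV of I/OD) |
| `delta_threshold` | 15 pp | minimum survival gain for a hit; clear lifespan extension in this assay separates curves by 30–55 pp, so 15 pp is a conservative codification |
| `consecutive_days` | 2 | a hit must persist across consecutive age days |
| `n_boot` | 1000 | bootstrap draws for CIs (resampling wells within arm and day) |

Survival percentages are clamped to [0, 100] for reporting (noise pushes
the formula outside the interval), but the raw value and a clamp flag are
always kept: the *raw* per-well mean is the unbiased estimator of
viability, and the convergence tests use it, because the clamped mean is
biased upward wherever true viability is near 0.

## The simulator

The generator exists so that every stage — file parsing, normalization,
curve assembly, QC, hit calling — can be tested against known ground
truth. It emulates:

* **Mortality kinetics.** Viability follows a Weibull survivor function
  anchored at day 1, $V(t) = \exp(-((t-1)/\lambda)^k)$. Shape $k = 1.3$
  (accelerating mortality) is used throughout: an exponential decline
  through a ~50% day-4 point would still hold 25% at day 7, whereas real
  control cultures are below 20% by then; $k = 1.3$ reconciles both. The
  default screen's scales are $\lambda$ = 4 (untreated control, also the
  inert-sugar arm), 9 (calorie-restriction-like), 13 (rapamycin-like) and
  38 days (long-lived fructose-analog arm), chosen to reproduce the
  canonical trend values: control ≈ 50% at day 4 and < 20% at day 7,
  rapamycin-like ≈ 70% at day 7, the analog arm ≈ 65% at day 21. These are
  emulation targets, not measurements.
* **Measurement physics.** Fluorescence is density-proportional:
  $(f_{bg} V + f_{dead}(1-V)) \cdot OD_{true}$, with $f_{bg} = 50$ and
  $f_{dead} = 1050$ a.u. per OD — free instrument constants with
  documented defaults; their ratio only sets the assay window. The OD
  channel is linear up to a knee (default cuvette OD 12) and compressed
  above it, $knee + (x - knee)^{0.7}$. Both channels carry independent
  multiplicative Gaussian noise, CV 5% by default (3% for calibration
  series), typical plate-reader repeatability.
* **Controls** come from the same measurement model with viability pinned
  to 1 (unstained, background only) or 0 (boiled, fully stained).

With noise off, the pipeline inverts the generator exactly (survival
$= 100\,V(t)$ to 1e-9), which pins down the algebra; with noise on, means
converge to $V(t)$ by the law of large numbers.

What the simulator does **not** emulate: plate-position (edge) effects,
instrument drift within a read, staining-efficiency variation between
wells, autofluorescence differences between plate types, non-Gaussian
outliers, and any mechanistic aging biology. Passing tests therefore
demonstrate that the *analysis* is correct and well-calibrated for an
idealized instrument, not that the wet-lab assay is free of systematic
error.

### Control wells as normalization anchors

The per-plate control means enter every well's score, so their standard
error is a plate-wide, perfectly correlated error term: it does not
average out over sample wells. At CV 5% the boiled-control I/OD mean from
3 wells carries ≈ 4 pp of survival-scale error, which would dominate a
12-well arm mean (replicate SE ≈ 1.8 pp). The simulator therefore defaults
to 8 control wells per role — one 96-well plate column each, the usual HTS
layout — which balances the two error sources. The layout validator keeps
the configurable minimum of 3.

## Numerical choices

* **Calibration fits** are ordinary least squares (`stats::lm`); tests
  check them against a normal-equations oracle to 1e-9.
* **Linear-range detection** trims greedily from the top of the dilution
  series until $R^2 \ge 0.98$, because saturation is a monotone
  compression at high density — a changepoint model is unnecessary. The
  0.98 default is a judgment call and deliberately tight; on the emulated
  series the noiseless $R^2$ with the first saturated dilution included is
  0.974, so at 3% CV the threshold separates the knee reliably only with
  replicated dilutions (the calibration design here uses triplicates, as a
  careful dilution series would). The lower bound uses the 3×blank-SD rule
  when blanks exist, else the smallest dilution: the bottom of the tested
  range is a design choice, not a detection limit.
* **Mortality fits** minimize RSS on the viability scale with
  `stats::optim` (Nelder–Mead, fixed tolerances), initialized at the exact
  log–log linearization $\log(-\log V) = k\log(t-1) - k\log\lambda$ of the
  interior points — exact on noiseless data, so noiseless recovery is to
  machine-level precision and the fit is deterministic.
* **Ties and degenerate inputs**: constant-response calibrations, flat
  100%/0% curves, identical Z-factor arms and single-day curves raise
  typed errors (`picls_*_error` classes) rather than returning NaN.
* **Bootstrap** CIs are percentile intervals over wells, resampled
  independently within each arm and day; seeds are recorded in the result
  for bit-reproducibility. Holm step-down across conditions controls the
  family-wise rate in the confirm-by-retest screening workflow (FDR is a
  config alternative via `adjusted = FALSE` plus external adjustment).

## Design decisions that were genuinely open

* **Z-factor arms and signal.** The assay-quality window is computed on
  OD-normalized fluorescence (I/OD) of intervention vs untreated wells at
  the same age day — I/OD is the quantity the survival formula consumes,
  and arm labels are symmetric in the statistic. Per-well survival is a
  config option. No attempt is made to reproduce any particular published
  Z value, whose exact arm definitions are not recoverable; the check is
  that a clearly separated day-7 comparison lands in the excellent band
  (≥ 0.5).
* **Hit rule.** `delta ≥ 15 pp` with a positive bootstrap CI on ≥ 2
  consecutive days, after a growth-toxicity gate (conditions whose 72-h
  growth is < 80% of control are `toxic`, never `hit`). Under the null
  the empirical false-positive rate is far below nominal — the
  consecutive-days requirement compounds two ~2.5% one-sided tests — and
  the power against a threefold λ extension at n = 6, CV 5% exceeds 90%.
* **Outgrowth anchoring.** Outgrowth survival is *defined* relative to
  day 1, so the anchor is mandatory there; the PI statistic is absolute,
  so for it day 1 is reporting only.
* **Dose–response** is summarized by AUC-vs-concentration Spearman trend
  only. The concentration grids this assay uses are 4–6 point double
  dilutions — too short for stable EC50/Hill fits.

## Problem sizes used in the test suite

Simulation-based tests use: 200 wells/day (with 24 control wells per
role) for law-of-large-numbers convergence at 2 pp; 100 seeds at n = 6,
CV 5% for mortality-parameter recovery (median relative error ≤ 10%);
500 simulated null screens (bootstrap B = 400) for the false-positive
bound and 60 for the power bound; 12 wells/arm for the trend and
Z-factor checks. These sizes give comfortable Monte-Carlo margins for
the assertions made while keeping the suite quick to run.

## Known limitations

* The measurement-model constants ($f_{bg}$, $f_{dead}$, knee exponent,
  noise CV) are free parameters; absolute fluorescence values are not
  meaningful, only the normalized statistic is.
* The per-plate/day control requirement is strict: plates without both
  control roles fail rather than borrowing controls across plates.
* Parsers target 96-well geometry; the data model (letter-row/number
  column) would extend to 384 wells but the grid reader does not.
* The mean of clamped percentages is reported for curves (bounded,
  plot-ready) although it is biased near the 0% and 100% rails; the raw
  mean is available from `survival_by_well()` when unbiasedness matters.
* `detect_linear_range` assumes saturation only at the top of the series;
  a nonlinearity in the middle of the range would not be excluded.
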