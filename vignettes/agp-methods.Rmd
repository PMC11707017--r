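---
title: "Methods: synthetic CGM cases and rule-based AGP summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic CGM cases and rule-based AGP summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agpkit)
```

This vignette is the package's own account of its modelling and design
choices: what the simulator actually solves, which constants drive the
metrics and summaries, where a convention had to be chosen, and what the
synthetic cases do and do not tell you about real CGM data.

## The patient model

Synthetic traces come from a Bergman-type minimal model of
glucose–insulin dynamics with a two-compartment meal absorption chain:

$$\frac{dG}{dt} = -p_1\,(G - G_b) - X\,G + f_{\mathrm{carb}}\,k_a\,Q_2$$
$$\frac{dX}{dt} = -p_2\,X + p_3\,(I - I_b), \qquad
  \frac{dI}{dt} = -k_i\,(I - s\,I_b)$$
$$\frac{dQ_1}{dt} = -k_a\,Q_1, \qquad
  \frac{dQ_2}{dt} = k_a\,(Q_1 - Q_2)$$

$G$ is plasma glucose (mg/dL), $X$ remote insulin action (1/min), $I$
plasma insulin (µU/mL), $Q_1, Q_2$ carbohydrate mass in transit (g). A
meal of $c$ grams is an impulse $Q_1 \mathrel{+}= c$; a bolus of $u$
units an impulse $I \mathrel{+}= s \cdot \mathrm{gain} \cdot u$. The
dimensionless dose scale $s$ multiplies all insulin delivery and is the
single calibration knob: at $s = 1$ with no meals, $(G_b, 0, I_b, 0, 0)$
is an exact equilibrium, and mean glucose is monotone decreasing in $s$,
which is what makes one-dimensional bisection to a target GMI reliable.

This is a deliberate simplification of full physiological T1D
simulators. It reproduces the phenomenology the downstream tasks need —
meal excursions, insulin-driven dips, a controllable mean — not
pharmacokinetic fidelity. Rescue carbohydrates after lows, compression
artifacts, sensor drift over a wear, and circadian insulin-sensitivity
rhythms are all unmodelled.

### Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `Gb` | 120 | mg/dL | basal glucose, the no-input equilibrium |
| `p1` | 0.010 | 1/min | glucose effectiveness (insulin-independent uptake) |
| `p2` | 0.020 | 1/min | decay of remote insulin action |
| `p3` | 2.2e-5 | 1/min per µU/mL | insulin sensitivity gain |
| `Ib` | 12 | µU/mL | basal insulin |
| `ka` | 0.035 | 1/min | meal absorption rate (~30 min to peak appearance) |
| `f_carb` | 4.5 | mg/dL per g | total glycemic impact of one carb gram |
| `ki` | 0.012 | 1/min | insulin absorption/decay (~80 min time constant) |
| `bolus_gain` | 9 | µU/mL per U | plasma increment per bolus unit |
| `dose_scale` | calibrated | — | global insulin multiplier, in [0.1, 10] |

Rates sit in the range minimal-model literature uses for adults with
T1D (low glucose effectiveness, sluggish insulin action). The
meal-impact and bolus-gain values were chosen once so that the default
three-meal day produces realistic traces across the calibrated
spectrum: an overall CV around 25%, excursions above 250 mg/dL in
poorly controlled cases, and a mild hypoglycemia burden only in the
tightest-control cases — the phenotype mix a clinician actually sees.
They are parameters, not fit results, and are not revisited per case.

### Sensing model

The sensor applies, in order: a first-order interstitial lag
(`tau_lag`, default 10 min, discretized exactly on the 1-min trace
grid), subsampling to the case grid (default 5 min, 288 readings/day),
multiplicative AR(1) Gaussian noise (stationary CV `noise_cv` 0.05,
autocorrelation `ar_phi` 0.7 between consecutive samples — CGM errors
are strongly autocorrelated, so white noise would understate
run-lengths of error), rounding to 0.1 mg/dL and clamping to the
reporting range [39, 401] mg/dL. Missingness then removes, per day with
probability 0.3, one contiguous block of 30–120 min at a uniform clock
position.

### Reproducibility

Each case owns one integer seed. Meal jitter, sensor noise and gap
placement draw from three fixed substreams derived from it (seeds
`(seed·7919 + stage·104729) mod (2^31 − 1)` for stages 1–3), so adding
draws to one stage can never silently shift another, and an identical
config reproduces the CSV byte for byte. A suite spreads calibration
targets evenly over the requested GMI interval and uses seeds
`base_seed + 1 … base_seed + n`.

### Calibration

The GMI target is inverted analytically to a mean-glucose target
(`mean = (GMI − 3.31)/0.02392`), then `dose_scale` is bisected
(geometric midpoints, since the dose acts multiplicatively) until the
noise-free clamped 1-min trace realizes the target GMI within ±0.05
percentage points, with an explicit error naming the achievable
interval when the target is outside it. Sensor noise is mean-zero and
multiplicative, lag only delays, and gaps are uniform over the day, so
the realized GMI after sensing stays within ±0.1 of target; the test
suite asserts exactly that for every default-suite case.

## Metric conventions

All constants live in one exported object, `agp_conventions`, and are
never inlined. The consequential choices:

* **GMI constants** 3.31 and 0.02392 (the standard linear mapping of
  mean CGM glucose to the HbA1c scale).
* **Population SD for CV**: the series is the whole observation window,
  not a sample from it. `cv_glucose(..., "sample")` exists for
  comparison.
* **Reading-count weighting**: every percentage is a fraction of
  observed readings; gaps shrink the denominator rather than being
  imputed. Duration-weighting would require inventing data inside gaps.
* **Boundaries**: in-range is inclusive 70–180; above 250 and below
  70/54 are strict. Hence the banded level-1 band is exactly 181–250
  for integer-valued readings, and the two time-above-range conventions
  reconcile exactly at the count level (`attr(x, "counts")`), to
  floating-point rounding at the percentage level.
* **Both TAR conventions are first-class** because reading "level 1"
  literally instead of cumulatively is a real and consequential
  misreading of CGM targets; exposing it makes the discrepancy
  diagnosable rather than silent. Cumulative is the default and the
  package's ground truth.
* **% captured** is defined over the configured wear period (default
  14 days), a documented choice where "expected readings" is ambiguous.

## AGP bands

Readings pool across days into clock-time bins (default 60 min, so 24
bins; any divisor of 1440 works). Percentiles 5/25/50/75/95 use the
linear-interpolation definition (`stats::quantile` type 7, R's
default). Empty bins are reported with `NA` and a zero count, never
interpolated — a bin with no data must not read as euglycemic. The
maximal-IQR window breaks ties by earliest clock time so narratives are
deterministic.

## Episodes and summaries

Episode conventions follow the international consensus definitions: a
candidate episode needs ≥ 15 min beyond threshold; level 2 is < 54
(hypo) or > 250 mg/dL (hyper); "prolonged" is ≥ 120 min; an episode
closes only after ≥ 15 min back in range (shorter interludes merge);
and any gap > 30 min censors the episode, because asserting an episode
continued across missing data would be inference, not observation.
Duration runs from the first to the last excursion reading plus one
nominal interval (four 5-minute readings = 20 min). The nocturnal
window is 00:00–06:00, configurable in `agp_conventions`.

The five summarization tasks are deterministic rules over the metrics,
bands and episodes. Each encodes a guard against a specific failure
mode of free-text CGM summarization:

* severity labels for hyperglycemia are gated by a fixed mapping
  (none / mild / moderate / notable) on cumulative TAR, TAR > 250 and
  prolonged episodes, so a record with 8% TAR and nothing above 250 can
  only ever be "mild";
* nocturnal and level-2 hypoglycemia always appear in the narrative, no
  matter how brief, and overnight readings at 70–79 mg/dL are reported
  as near-misses;
* the variability narrative refuses the word "stable" whenever
  GMI ≥ 8%, because low variance around a high mean is not stability;
* "no hypoglycemia" claims are qualified whenever the record has gaps;
* the main-concern cascade is strictly ordered (level-2/4%-TBR
  hypoglycemia → nocturnal hypoglycemia → hyperglycemia burden
  (TIR < 70% or GMI ≥ 8) → variability (CV > 36%) → meets targets) and
  its narrative always restates GMI and TIR.

Narratives are filled from templates with at most six prioritized
sentences (and always at least two), so every numeral in the text is
present in the finding's structured facts.

## Rating aggregation and agreement

The rubric has five binary categories; completeness and safety are
inverted at scoring time because their "yes" marks a flaw. Totals are
per rater over cases, and the headline figure is the mean of the two
raters' totals — with a complete grid, averaging per case first and
then across raters gives the same number, so the ambiguity between the
two readings of "mean score" is immaterial here but documented.
Gwet's AC1 is implemented for exactly this design (two raters, binary
answers): $p_a$ is the fraction of identically answered items,
$\pi = (\pi_A + \pi_B)/2$, $p_e = 2\pi(1-\pi) \le 1/2$, and
$AC_1 = (p_a - p_e)/(1 - p_e)$. The general multi-rater, multi-category
coefficient is out of scope.

## Numerical notes

* ODE integration uses `deSolve::ode` (lsoda) with meal/bolus impulses
  as add-events on whole-minute times; output is the dense 1-min trace.
  Non-finite or non-positive glucose aborts with a parameter-rejection
  error rather than clamping silently.
* `regularize()` snaps timestamps to the grid anchored at the first
  reading's midnight; half-interval ties go to the later grid point,
  collisions keep the first reading. The operation is idempotent and
  never lengthens a series.
* Degenerate inputs: empty series are valid for I/O, gap listing,
  `days_active` (0) and episode detection (no episodes); metrics,
  bands and summaries require at least one reading and say so.
* CSV glucose is written at 0.1 mg/dL precision; round-trips are exact
  at that precision.

## What the tests do and do not show

The test suite checks the metric engine against brute-force loop
oracles on random series, the episode scanner against an independent
split-rule transcription on random-walk fixtures, the ODE solution
against a fixed-step RK4 transcription, AC1 against its literal
formula, and the full generator end-to-end: the default suite of ten
14-day cases realizes GMIs 6.0–9.0 within ±0.1 and regenerates
byte-identically under a fixed seed. Property suites run at small sizes
(hundreds of random series of up to a few hundred readings; one
14-day suite per run) — sizes chosen to exercise every code path, not
to stress throughput.

Passing them shows the pipeline is a faithful implementation of the
stated conventions on data *shaped like* CGM exports. It does not show
that the simulator reproduces any particular patient population:
real CGM data carry sensor drift, compression lows, behavioral
feedback (rescue carbs, corrections) and device-specific artifacts
that the generator deliberately omits. Conclusions about summarization
quality on real data need real data.
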