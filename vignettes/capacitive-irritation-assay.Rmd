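---
title: "Methods: capacitive irritation assays on an artificial stratum corneum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capacitive irritation assays on an artificial stratum corneum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irritrace)
```

## The measurement principle

A pair of coplanar electrodes is covered by a dielectric stack — insulating
tape, an adhesive spacer, an absorbent filter, and a lanolin coating that
stands in for the stratum corneum. Each electrode sees the stack as a
parallel-plate capacitor, `C_s = ε₀ ε_r A / d` per layer combined in series
(`layer_capacitance()`, `stack_capacitance()`); the two electrode stacks are
in turn in series with whatever bridges the gap between them. In air that
contact path is a small capacitance `C_a`; under a droplet it is the
electrolyte-path capacitance `C'_a`, so the instrument reads

$$C_\mathrm{total} = \left[\frac{2}{C_s} + \frac{1}{C'_a}\right]^{-1},$$

which saturates at the conductive limit `C_s/2` as the contact path becomes
fully conductive (`total_capacitance()`, `conductive_limit()`). We adopt the
two-stack series reading of the total-capacitance relation because it is the
only reading that reduces exactly to the `C_s/2` limit; contact-path
resistances are carried in the circuit state but, at the 1 kHz measurement
frequency, enter only through the leakage term below.

An intact lanolin barrier keeps electrolyte away from the electrodes and
the reading stays at its designed working point (≈220 fF). An irritant
disrupts the barrier: electrolyte ingress raises the effective permittivity
of the contact path and opens conductive channels through the membrane. We
model both as first-order relaxations (`disruption_kinetics()`): the contact
capacitance relaxes toward an asymptote at rate `rate_perm_per_s`, and the
leakage resistance `R_leak` decays toward its disrupted value at
`rate_leak_per_s`. The leakage path contributes an equivalent series-path
capacitance `1/(ω R_leak)` at the measurement frequency ω = 2π·1 kHz —
about 159 fF per (GΩ)⁻¹ — negligible for intact barriers (`R_leak` ~ 10⁴
GΩ) and growing as the barrier fails. The exponential form is the simplest
kinetics consistent with the observed slow transient followed by a gradual
rise; nothing downstream depends on that choice, because the generator tunes
kinetics to a *target slope* rather than fixing rate constants a priori.

## The irritation endpoint

The decision metric is the capacitance change rate ΔC/Δt in fF/s. Two
estimators are implemented:

- `rate_windowed()` — the OLS slope of C against t over a window 60–450 s
  after sample application. The window skips the droplet-spreading
  transient and captures the steady penetration phase; this is the
  canonical estimator and the classification default.
- `rate_max()` — the maximum of a moving-window OLS slope (default span
  30 s) after application, for transients that peak early.

Which of the two the classification consumes is a config switch
(`classification_config(estimator = )`), since published group values do
not always state which definition they used. Classification is a strict
threshold: Category 2 iff the per-substance mean rate exceeds the cutoff
(default 3.5 fF/s); a rate exactly at the cutoff maps to No Classification,
a tie-break we fixed because the boundary case is otherwise unspecified.

Group statistics follow the assay's published analysis plan: two-sample
t-tests of each substance against the PBS negative control with Bonferroni
correction and significance at p < 0.01. We default to the Welch test
(unequal variances) with a `var_equal` switch to the pooled Student
variant — with n = 3 replicates either is defensible, and Welch is the
safer default when irritant groups have visibly larger spread. The
Bonferroni divisor defaults to the number of non-control substances in the
run, the natural comparison family for a single panel.

## Blank quality control

Each assay starts with ≥400 s of PBS on the intact barrier. The blank
passes when the OLS slope over that segment is (i) below the classification
cutoff in magnitude and (ii) within three standard errors of zero. The
second arm makes the check statistical rather than purely thresholded; on a
noiseless flat blank both slope and SE are at floating-point zero, so the
comparison carries a 1e-9 fF/s epsilon. Traces failing QC are flagged and
excluded from group statistics; a substance with no passing replicate is
reported unevaluable, never dropped silently.

## What the synthetic generator emulates

The generator reproduces the instrument characteristics the hardware
validation reported, as defaults of `noise_model()` and `generate_batch()`:

| quantity | default | origin |
|---|---|---|
| sampling interval | 0.1 s | readout rate |
| white noise RMS | 1.8 fF | measured 1.8 ± 0.3 fF over 600 s |
| temperature drift | 0.012 fF/°C | measured 0.012 ± 0.004 fF/°C |
| baseline CV (device level) | 0.7 % | batch variation bound |
| rate CV (device/day/replicate) | 3 % | batch/intra/inter-day CVs 2.3–3.5 % |
| blank/sample protocol | 20 s baseline, 400 s PBS, sample from 430 s | droplet protocol |
| droplet volume | 50 µL | metadata only |

Variability is injected as independent multiplicative Normal(1, CV)
perturbations at device, day and replicate level; the published CVs are
level-wise summaries without a variance decomposition, so applying the
stated magnitude at each level is the simplest structure that reproduces
them. Temperature defaults to a constant 25 °C; drift only appears when a
temperature trajectory is supplied. Removal events relax the signal back
toward baseline at a configurable recovery rate (partial recovery is shown
in the source data but not modelled there; 0.01 s⁻¹ is our choice).

The default reference panel spans the published group ranges: PBS 0.4,
PEG 400 0.7, 50 % isopropanol 1.3 fF/s (No Classification) and
glutaraldehyde 8, KOH 20, SDS 40 fF/s (Category 2). Only the PBS and
isopropanol values are individually published; the others are
representative assignments inside the stated ranges.

What the generator does **not** emulate: droplet spreading hydrodynamics,
electrode fouling, humidity effects, non-Gaussian noise, 1/f drift, or the
material-specific deviations that make real tapes read below the log
calibration. Passing tests therefore demonstrate that the *analysis* is
correct under the stated statistical model of the instrument, not that the
physical sensor meets those statistics.

## Calibration model

Spacer thickness x (µm) maps to capacitance as `C = a ln(x) + b`
(`fit_log_model()`), an empirical relation: the layered coplanar geometry
does not follow the ideal-plate 1/d law. The fit is unweighted OLS on
(ln x, C) — no replicate or weighting scheme is published. The 0 µm blank
cannot enter a log fit and is treated as a separate constant. Inverse
prediction `x = exp((C − b)/a)` is the exact algebraic inverse;
`working_point_report()` composes it with a detection margin (distance from
the working point to the C = 0 floor) and, when a measured value at a known
thickness is supplied, the model-vs-material discrepancy. Note that the
published worked example for this calibration (264.14 fF at 170 µm) is not
reproducible from the published coefficients, which give 265.38 fF; the
package computes the model honestly and surfaces both sides of any
discrepancy rather than choosing.

## Numerical choices

- **Units**: capacitance in fF, lengths in µm, ε₀ = 8.854×10⁻³ fF/µm;
  open circuits are encoded as IEEE `Inf`, which makes the series formulas
  exact (`1/Inf = 0`) without branching.
- **Rate matching** (`match_kinetics_to_rate()`): the contact-capacitance
  asymptote is found by bracketing-and-`uniroot` on the noiseless windowed
  slope, which rises with the asymptote until the reading saturates at
  `C_s/2` before the window opens; infeasible targets raise an explicit
  error naming the ceiling. Matched slopes are within 0.1 % of target.
- **Default circuit state**: `C_s = 2×10⁵ fF` with the air path tuned so
  the intact sensor reads 220 fF. The generous ceiling is deliberate: a
  windowed slope of 40 fF/s sustained over 60–450 s implies a multi-pF
  excursion, far above what a 220 fF ceiling could carry, so the simulator
  needs headroom to realise the full span of reported rates.
- **Rolling slopes** are computed by convolution (closed-form OLS on a
  uniform grid), so maximum-rate and plateau scans are O(n) per trace.
- **Plateau detection**: the slope window length equals the minimum
  quasi-equilibrium span (60 s), so "slope below tolerance" and "stays
  below for the span" coincide; the earliest qualifying window wins, and
  absence is a value (`NA`), not an error.
- **RMS noise** defaults to mean-removal only, matching a "baseline
  fluctuation" reading of the published figure; linear detrending is
  opt-in.
- **Degenerate inputs** are errors with typed condition classes
  (`irritrace_window_error`, `irritrace_infeasible_target`, ...): zero
  `C_s`, non-uniform grids, empty stacks, constant temperature for drift,
  sub-minimal windows, non-finite samples at file read.
- **Reproducibility of randomness**: one root seed; each trace draws from a
  child stream derived by an affine counter modulo a prime below 2³¹, so
  any subset of a batch is reproducible in isolation. Seeded sections
  restore the caller's RNG state.

## Problem sizes

The shipped tests run the panel at the published design point — six
substances × 3 replicates, 900 s traces at 0.1 s sampling — and repeat the
full panel 100 times with different seeds for the label-agreement check;
estimator calibration uses 100-replicate noise ensembles at the 2 fF
instrument bound. These sizes give Monte-Carlo error well below the
tolerances being checked while keeping a full run in minutes on one core.

## Known limitations

- The disruption kinetics are phenomenological; rate constants are not
  interpretable as physical permeation parameters.
- Frequency-domain behaviour (impedance spectroscopy, double-layer
  electrochemistry) is out of scope; the leakage term is a fixed-frequency
  equivalent.
- The classification is binary (Category 2 vs No Classification); finer
  GHS gradations would need additional reference substances.
- Published endpoint magnitudes that depend on physical sensors or
  untabulated raw data (figure endpoint values, the hardware R², measured
  CVs) are represented by generator parameters, not reproduced from first
  principles.
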