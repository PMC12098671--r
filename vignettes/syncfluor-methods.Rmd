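---
title: "Resolving overlapped fluorophores by first-derivative synchronous scanning"
author: "syncfluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapped fluorophores by first-derivative synchronous scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncfluor)
```

## The analytical problem

Aspirin (ASP) and atorvastatin (ATO) are co-formulated in cardiovascular
tablets and both fluoresce natively in ethanol — ASP around 405 nm
(excited near 285 nm), ATO around 364 nm (excited near 300 nm). Their
emission bands overlap so heavily that conventional emission scans cannot
quantify one drug in the presence of the other. The classical
separation-free answer is *synchronous fluorescence scanning* followed by
*first-derivative, zero-crossing* measurement, and that pipeline —
together with a simulator that generates excitation–emission matrices
(EEMs) with the statistical structure the method assumes, and the full
ICH Q2 validation arithmetic — is what this package implements.

## The model

### Fluorophores and EEMs

Each fluorophore is modelled as a separable pair of symmetric Gaussian
bands. Its contribution to the EEM at excitation $\lambda_{ex}$ and
emission $\lambda_{em}$, per unit concentration, is

$$ B \cdot
\exp\!\left(-\frac{(\lambda_{ex}-\mu_x)^2}{2\sigma_x^2}\right)
\exp\!\left(-\frac{(\lambda_{em}-\mu_m)^2}{2\sigma_m^2}\right), $$

with $B$ the brightness in arbitrary fluorescence units (AFU) per
(µg/mL). A simulated sample is the concentration-weighted sum of its
fluorophores plus a flat, non-fluorescent excipient background;
replicate noise is additive Gaussian plus proportional Gaussian applied
cell-wise. The Gaussian shape is the simplest one that admits a
closed-form oracle for the synchronous trace (below); the real compounds'
band shapes are more structured, and the frozen widths are a modelling
stand-in, not a claim about the true spectra.

### The synchronous trace and its closed form

A constant-offset synchronous scan moves both monochromators together
with $\lambda_{em} = \lambda_{ex} + \Delta\lambda$. The package reports
synchronous spectra on the emission axis:

$$ S(\lambda_{em}) = \mathrm{EEM}(\lambda_{em} - \Delta\lambda,\ \lambda_{em}). $$

For a single Gaussian-band fluorophore this diagonal slice is again a
Gaussian — the product of the excitation Gaussian evaluated at
$\lambda_{em}-\Delta\lambda$ and the emission Gaussian — peaking at the
precision-weighted mean

$$ \lambda_{em}^{*} =
\frac{(\mu_x + \Delta\lambda)/\sigma_x^2 + \mu_m/\sigma_m^2}
     {1/\sigma_x^2 + 1/\sigma_m^2}, $$

implemented as `syncPeakTheory()` and used throughout the test suite as
an independent oracle for the numerical slice (agreement is required to
0.5 nm). Off-grid excitation coordinates are resolved by linear
interpolation along the excitation axis; the emission coordinate is
always on-grid, so this is the bilinear rule restricted to one axis.

### First derivative and zero crossings

The quantitative response is the signed first derivative
$^1D = dS/d\lambda_{em}$ in AFU/nm, computed with a Savitzky–Golay
filter of polynomial order 2 and a 15-point window by default, scaled by
the grid step. The filter's polynomial edge fit preserves the trace
length; the edge half-window is excluded from zero-crossing searches
because those points are extrapolations of the local polynomial, not
smoothed data. A plain 15-point central-difference mode
(`derivativeMode = "lagged"`) is provided because instrument software is
ambiguous about whether a "data interval" is a smoothing window or a
differentiation gap; Savitzky–Golay is the default since it is what
modern spectrometer software applies.

Sign convention: amplitude is positive where intensity rises with
wavelength, and calibration consumes the *signed* amplitude —
negative-slope channels are legal and occur in practice (the ATO channel
of the default system calibrates with a negative slope).

### Zero-crossing measurement wavelengths

Analyte A is measured where interferent B's derivative crosses zero for
every B concentration, so the reading is interference-free. The selector
works on derivative spectra of pure-interferent panels plus a
pure-analyte reference:

* candidate wavelengths are the non-edge grid points **plus** the
  interpolated zero crossings of every interferent trace — at a
  crossing, the linearly interpolated interferent amplitude is exactly
  zero for noiseless traces of any concentration, because noiseless
  traces of the same fluorophore are proportional;
* candidates must retain at least `sensitivityFloor` (default 0.2) of
  the analyte's maximum $|^1D|$ — a wavelength with no analyte signal is
  useless no matter how quiet the interferent is;
* among those, the selector minimises the *worst-case relative
  interference*: the largest interferent $|^1D|$ across the panel
  divided by the analyte's own $|^1D|$, i.e. the worst concentration
  bias the interferent can cause. Normalising by the analyte's
  sensitivity is essential: the raw interferent amplitude is also tiny
  in remote band tails, and an absolute objective drifts there, where
  the analyte sensitivity is poor and the choice is fragile under noise.
  Ties go to the strongest analyte signal.

With no interferent signal anywhere the rule degenerates to the
floor-constrained argmax of the analyte's $|^1D|$. For the default
simulated pair at $\Delta\lambda = 80$ nm the selected wavelengths are
384.0 nm (ATO channel, ASP's crossing) and 365.2 nm (ASP channel, ATO's
crossing), matching the landmarks reported for the real assay.

### Choosing the scan offset

$\Delta\lambda$ trades band position against sensitivity. Candidates
(20–120 nm by default) are scored on pure panels as

$$ \mathrm{score}(\Delta\lambda) = |S_A| \cdot |S_B| \cdot
\min(\mathrm{separation},\ 50\ \mathrm{nm}), $$

where $S_A, S_B$ are the calibration sensitivities (slopes) at the
auto-selected wavelengths and the separation term rewards two
well-resolved channels, capped at 50 nm so that remote peaks do not
dominate. Ties take the smallest offset; candidates with insufficient
grid overlap score $-\infty$ and are flagged; spectrally identical
analytes give zero separation and an "unresolvable" flag. On the default
simulated system the score peaks at 90 nm, adjacent to the 80 nm
operating point the real assay uses; the package's default stays at
80 nm, which the scan table shows to be nearly as good.

## Calibration and validation arithmetic

* **Calibration** is ordinary least squares of signed amplitude on
  concentration (≥ 3 distinct levels). $\sigma$ for the detection
  limits is the standard deviation of the y-intercepts of per-replicate
  refits (3 replicate curves by default), unavailable (NA) with fewer
  than two replicate curves.
* **LOD/LOQ** $= 3.3\,\sigma/|S|$ and $10\,\sigma/|S|$; their ratio is
  $10/3.3$ by construction and the report renderer embeds a warning if a
  hand-assembled report violates it.
* **Inverse prediction** $C = (^1D - b)/S$ always carries an
  out-of-range flag outside the validated range — no silent
  extrapolation.
* **Recovery** is $100 \cdot \mathrm{found}/\mathrm{added}$; accuracy
  studies run at 80/100/120% of the assay concentration in triplicate
  against a 98.0–102.0% band. Standard addition uses subtraction
  accounting (pure found = total found − base found), the convention of
  the reference study's tables, rather than extrapolation to zero.
* **Precision** uses the sample (n−1) standard deviation throughout —
  the convention that exactly reproduces the reference study's printed
  standard-addition %RSDs (1.097, 1.036) — with a 2.0% acceptance limit.
* **Method comparison** is the pooled-variance two-sample t (reported
  unsigned) and the variance-ratio F in the larger/smaller convention,
  with critical values from `qt`/`qf` at 95%, not hard-coded.
* **Robustness** perturbs one knob at a time ($\Delta\lambda \pm 1$ nm;
  a ±1% brightness jitter standing in for the pH/buffer chemistry the
  simulator does not model) and reports the across-level %RSD of three
  concentration determinations per drug under the perturbed condition —
  the compendial statistic, which a proportional rescaling leaves small.
  The systematic response to the knob itself is reported separately as
  `sensitivity_rsd`, the spread of per-condition mean recoveries across
  $\{-\delta, 0, +\delta\}$; for a pure proportional perturbation of
  size $d$ it approaches $100d$. The two statistics answer different
  questions and conflating them makes a method with a perfectly benign,
  recalibratable sensitivity look non-rugged.

## Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `deltaLambda` | 80 | nm | the assay's operating point; scan confirms 80–90 is optimal |
| `derivativeInterval` | 15 | points | the assay's stated data interval, as an SG window |
| excitation grid | 220–500 × 1 | nm | covers every cited wavelength |
| emission grid | 250–600 × 1 | nm | ditto |
| ASP bands | 285/405, SD 28/29.4 | nm | crossing lands at 384.0 nm at $\Delta\lambda=80$ |
| ATO bands | 300/364, SD 60/17 | nm | crossing lands at 365.2 nm |
| brightness ASP/ATO | 100/150 | AFU/(µg/mL) | balances worst-case mixture repeatability across channels |
| noise | additive 0.1 AFU, CV 0.2% | — | mixture triplicate %RSD ≈ 0.5–1.3%, the magnitude of bench repeatability |
| background | 2 | AFU | flat excipient term; a constant has zero derivative |
| `sensitivityFloor` | 0.2 | fraction | excludes band tails from wavelength selection |
| calibration levels | 6 per analyte | µg/mL | spanning 0.4–6 (ATO) and 1–10 (ASP), in triplicate |

The band widths, brightness ratio and noise level were fixed once by the
grid-search/calibration script in `tools/tune-defaults.R` (closed-form
crossing positions; scan-optimum and repeatability checks) and are
frozen; they are package constants, not fitted quantities.

## What the simulator does and does not emulate

It reproduces: linear additive fluorescence of two overlapped bands at
the stated maxima, the validated linear ranges, replicate noise of
realistic magnitude, a non-fluorescent excipient background, and
deterministic seeding (one master seed, per-sample children).

It does **not** model: inner-filter effects or quenching at high
concentration, Rayleigh/Raman scatter ridges, pH-dependent hydrolysis of
ASP to salicylic acid, surfactant or solvent effects, wavelength-dependent
instrument response, or drift between days beyond a per-day seed offset.
Passing tests therefore demonstrate that the *pipeline arithmetic* is
correct under the method's own assumptions — not that those assumptions
hold for any particular instrument or matrix. Real-data use enters
through the CSV readers, which accept any rectangular EEM or 1-D trace.

## Numerical choices and degenerate inputs

* All wavelength handling is in physical nm; grids are uniform, and
  non-uniform 1-D input is linearly resampled with a warning.
* Zero crossings are refined by linear interpolation between bracketing
  samples; the refinement error against the analytic Gaussian oracle is
  bounded by half a grid step. A `minFlank` guard suppresses crossings
  whose flanking amplitudes are both below a noise threshold.
* Exact-zero samples inside a genuine sign change count once; flat zero
  runs do not produce crossings.
* Synchronous slicing requires ≥ 20 points of diagonal overlap and
  reports the usable emission range when refused.
* Blank samples predict 0 µg/mL with the below-range flag set; a zero
  calibration slope is an error, never a division.
* Scan problem sizes in the tests and acceptance script: 281 × 351-point
  EEMs (1 nm grids), six-level calibrations in triplicate, five-mixture
  panels in triplicate, eleven scan candidates — a full run takes a few
  seconds.

## Known limitations

Univariate, two-analyte design: more than two co-eluting fluorophores
need multivariate calibration, which is out of scope. The zero-crossing
rule assumes the interferent's spectral *shape* is concentration
invariant (no inner-filter distortion); where that fails the selected
wavelength is no longer concentration-stable. Derivative amplitudes are
in arbitrary units, so calibrations do not transfer between instruments
without re-measurement. The simulator's Gaussian bands underestimate the
spectral structure of real excipient-laden extracts; specificity against
a structured background must be established on real blanks.
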