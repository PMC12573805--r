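---
title: "Models and methods behind cuboflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuboflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuboflow)
```

`cuboflow` implements the quantitative analysis chain used to study how
microfluidic hydrodynamic flow focusing controls the size of cubosomes —
colloidal particles of an inverted bicontinuous cubic lipid phase
(phytantriol, stabilised by Pluronic F127) formed by solvent exchange
when an ethanolic lipid stream is focused between two aqueous streams.
This vignette explains each model, its assumptions, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was
genuinely open.

## 1. The flow-focusing mixing model

In a cross junction, the central precursor stream (flow rate $Q_m$) is
squeezed by two side streams (each $Q_s$).  Two numbers characterise a
condition: the total flow rate $Q_T = Q_m + 2 Q_s$ and the flow rate
ratio $Q_R = 2 Q_s / Q_m$.  All derived quantities are elementary but
unit-sensitive, so the package works in SI internally and converts at
the interface (flow rates in uL/min, lengths in um/mm, times in s):

* **Focused width.**  Neglecting the viscosity contrast between the
  ethanolic and aqueous streams, the height-averaged width of the
  focused sheet is $\bar{w}_f = w_c / [1.5\,(1 + Q_R)]$, where $w_c$ is
  the channel width and the factor 1.5 accounts for the focused sheet
  moving about 1.5 times faster than the mean flow.  The
  proportionality is implemented as an equality; a viscosity-corrected
  focusing law is a non-goal.
* **Mixing time.**  Solvent interdiffusion across the sheet takes
  $\tau_{mix} = \bar{w}_f^2 / (4 D_m)$.  The mutual diffusion
  coefficient of water/ethanol depends on composition; the package uses
  a constant average $D_m = 6.53\times10^{-10}\,$m^2/s as an explicit,
  overridable default.  Because $\bar{w}_f \propto (1+Q_R)^{-1}$,
  $\tau_{mix} \propto (1+Q_R)^{-2}$ — the central scaling of the whole
  analysis.  At the default geometry (100 × 100 um^2, 81 mm outlet)
  and $Q_T = 100$ uL/min this spans ~21 ms at $Q_R = 8$ down to
  ~1.8 ms at $Q_R = 30$.
* **Residence time and Reynolds number.**  $\tau_{res} = L A / Q_T$
  (0.486 s at the default working point) and
  $Re = \rho v D_h / \mu$ with the hydraulic diameter
  $D_h = 2wh/(w+h)$.  Density and viscosity default to pure water at
  25 °C (1000 kg/m^3, 1.0 mPa s), giving $Re \approx 16.7$; both are
  configurable since the solvent is actually a water/ethanol mixture.
  $\tau_{res}/\tau_{mix} \gg 1$ (≈23–275 over the working $Q_R$ range)
  indicates mixing completes well inside the device.
* **Dilution bookkeeping.**  The side streams are the anti-solvent, so
  $Q_R$ doubles as a dilution ratio.  `final_concentration()` treats it
  as a volume ratio between equal-density liquids, so weight fractions
  combine as $C/(1+Dil_R)$ — an approximation adequate at the per-cent
  concentrations involved.  `postdilution_volume()` solves the volume
  balance for standardising collected samples to a common target ratio.
* **Damköhler framing.**  $Da_p = \tau_{mix}/\tau_{assbl}$ compares
  mixing with the (unknown) lipid assembly time; $Da_p < 1$ favours
  homogeneous supersaturation and nucleation (small particles).  The
  classical-nucleation scaling $J \propto \exp[-(\ln S)^{-2}]$ is
  provided as a dimensionless helper, defined only for supersaturation
  $S > 1$.
* **Lipid partition.**  `lipid_partition_fraction()` compares a
  cubosome (sphere at lipid volume fraction $\phi$) with a same-size
  vesicle (lipid in a shell of one bilayer thickness).  For a 70 nm
  particle, $\delta = 2.87$ nm and $\phi = 0.74$ this yields ≈0.77.
  Published discussions of the same comparison quote ≈0.85 under
  unstated geometric assumptions; the package deliberately reports the
  naive sphere/shell number and does not force agreement.

## 2. SAXS structural analysis

The double-diamond $Pn\bar{3}m$ phase shows allowed reflections
{110}, {111}, {200}, {211}, {220}, {221} at
$q_{hkl} = (2\pi/a)\sqrt{h^2+k^2+l^2}$.  The lattice parameter comes
from an origin-constrained least-squares slope of $q_{hkl}$ versus
$\sqrt{h^2+k^2+l^2}$: $m = \sum q s / \sum s^2$, $a = 2\pi/m$.  Peaks
are assigned to reflections in ascending order; weakly ordered samples
that show only the first reflections are handled by trailing
truncation, and a `mask` argument supports gaps.

**Peak detection** finds local maxima of the square-root intensity — a
variance-stabilising scale for counting statistics that still
compresses the dynamic range — after a 5-point running median (which
removes single-bin counting spikes) and a 3-point mean.  Maxima are
kept when their topographic prominence above the flanking valleys
exceeds `min_prominence` (default 0.02) of the global signal range; the
default resolves a sixth-order reflection at the generator's default
amplitude decay while rejecting Poisson background bumps by a factor of
about three.  Kept positions are refined by a three-point parabolic
interpolation of the raw log-intensity, giving sub-grid accuracy.

**Domain size.**  The first Bragg peak is fitted with
$I(q) = A/(k^2 + (q-q_0)^2) + B$ (unweighted least squares on linear
intensity, Levenberg–Marquardt, initialised from the window maximum,
half-maximum crossings and window minimum; default window
$q_0 \pm 5k$).  The coherent domain size is reported as the lower bound
$\xi \ge \pi/k$, since instrumental resolution and thermal fluctuations
also broaden the peak.

**Bilayer thickness.**  For nodal-surface cubic phases the lipid
volume fraction obeys
$\phi = 2 A_0 x + \tfrac{4\pi\chi}{3} x^3$ with $x = \delta/(2a)$,
$A_0 = 1.919$ and $\chi = -2$ for $Pn\bar{3}m$.  On $x \in (0, 0.39)$
the cubic is strictly increasing (derivative $2A_0 + 4\pi\chi x^2 > 0$)
and attains $\phi$ up to ≈1.0, so bracketed bisection
(`uniroot`, tolerance near machine precision) finds the unique physical
root.  The default $\phi$ derives from the 28 wt% water phase-boundary
composition via an ideal-mixing weight-to-volume conversion with a
phytantriol density of 0.90 g/mL — the density is not published
alongside the thickness value, and 0.90 g/mL reproduces the reported
$\delta = 2.87$ nm at $a = 6.7$ nm to within 0.005 nm; it is a
configurable argument, not a hidden constant.  The broad low-$q$
feature near 0.045 1/Å is only converted to its real-space spacing
($d = 2\pi/q \approx 14$ nm); its physical origin is left open.

## 3. Multi-angle DLS cumulants analysis

Autocorrelation curves are fitted with the cumulants model
$g^{(2)}(\tau) - 1 = B + \beta\,[e^{-\bar{\Gamma}\tau}(1 +
\tfrac{1}{2}\mu_2\tau^2)]^2$ by unweighted nonlinear least squares
(baseline from the tail mean, $\beta$ from the head, $\bar{\Gamma}$
from a log-linear fit of the early decay, $\mu_2$ started at 0 and
bounded below by 0).  An optional truncation drops lags beyond where
the decayed signal falls below 1% of $\beta$.

The polydispersity index is implemented as the dimensionless
normalised second cumulant $PDI = \mu_2/\bar{\Gamma}^2$.  (The source
formula is sometimes typeset as $\mu_2/\bar{\Gamma}$, which is
dimensionally inconsistent with the reported dimensionless values in
the 0.15–0.19 range; the squared form is the standard definition.)
Each angle's PDI is the mean over its repeats and the reported PDI is
the arithmetic mean over angles.

Decay rates from all repeats at all angles (typically 3 × {90°, 173°}
= 6 points) are pooled into a zero-intercept regression
$\bar{\Gamma} = D q^2$, whose closed-form slope is
$D = \sum \bar{\Gamma} q^2 / \sum q^4$, with
$q = 4\pi n \sin(\theta/2)/\lambda$.  The hydrodynamic diameter
follows from Stokes–Einstein, $D_H = k_B T / (3\pi\eta D)$.  The
instrument optics are not part of the data files, so defaults
($\lambda = 532$ nm, $n = 1.33$, $T = 298.15$ K,
$\eta = 0.89$ mPa s) are explicit per-curve metadata; absolute sizes
from real instrument exports require the true values.  Strongly
bimodal samples violate the cumulants assumption and surface as poor
fits; resolving sub-populations is a non-goal.

## 4. The empirical size model and its statistics

Since particle size tracks the mixing time, the package fits
$$D_H = \beta_1 (1+Q_R)^{-\beta_2} + D_{H.0}$$
and the equivalent mixing-time form
$D_H = \alpha_1 \tau_{mix}^{\alpha_2} + D_{H.0}$ with
$\beta_2 = 2\alpha_2$ (the reparameterization is exercised as a
consistency test).  Fits default to the per-ratio mean sizes,
unweighted — mirroring how such summary tables are usually produced —
with SEM-weighted and replicate-level modes behind flags because the
original convention is not inferable with certainty.  Standard errors
come from the Jacobian-based covariance at the optimum.  With five
ratios and realistic noise the three-parameter fit is weakly
identified: $\beta_1$ and $D_{H.0}$ compensate for changes in
$\beta_2$.  The fit therefore reports their estimate correlation
(typically |corr| > 0.5), and a fixed-$\beta_2 = 2$ variant is
provided; on well-determined data both agree in $D_{H.0}$ within one
standard error, and recovery tests target $D_{H.0}$ and $\beta_2$, not
$\beta_1$'s scale.

The trend statistics run on replicate-level points: Kendall's
$\tau$-b and Spearman's $\rho$ (monotonicity, no functional
assumption; asymptotic two-sided p-values by default, exact
permutation p behind a flag for small tie-free samples) and Pearson's
r of $D_H$ against $1/Q_R$ and $1/Q_R^2$ (the focused-width and
mixing-time scalings).  No multiple-testing correction is applied, by
design.  Formulations are compared by ANCOVA: `lm(dh ~ predictor *
group)` with the interaction coefficient testing slope equality and
the group main effect testing intercept equality.

## 5. What the synthetic generators emulate

Every generator inverts the model its analysis stage fits, with one
integer seed fixing all randomness:

* `gen_dls_curves()`: 200 log-spaced lags from 1 us to 1 s (covering
  decay rates for 50–1000 nm particles at both angles), two angles ×
  three repeats, multiplicative Gaussian noise on $g^{(2)}-1$ (0.5%
  default) emulating correlator noise.
* `gen_saxs_pattern()`: 1500 q points over the instrument span
  0.0125–0.75 1/Å, six Lorentzian reflections with geometric height
  decay 0.5 per order (cosmetic — indexing uses positions only),
  optional broad Gaussian bump at 0.045 1/Å, optional Poisson counting
  noise (1e4 first-peak counts in the recovery studies).
* `gen_size_series()` / `gen_bulk_series()`: the study design of five
  ratios {8, 10, 15, 20, 30} with 3 (or 5) runs and 4 nm additive
  noise; the bulk counterpart uses a shallow +0.3 nm per ratio drift
  with 8 nm noise and 2 runs, chosen so that its trend is weak and
  mostly nonsignificant, as observed for bulk solvent exchange.
* `gen_study_bundle()`: three concentrations with asymptotic sizes
  133/135/160 nm and 3/3/5 runs, plus bulk counterparts, optionally
  written as CSVs.

The generators deliberately omit several features of real data:
vesicle/cubosome coexistence and intensity weighting in DLS, bimodal
populations, instrument resolution smearing and form-factor modulation
in SAXS, pump pulsation, and any concentration dependence beyond the
asymptotic size.  Passing recovery tests therefore demonstrates the
*estimators* are correct and well-conditioned under the stated noise
models — not that real measurements will match them.

## 6. Numerical choices and degenerate inputs

* Nonlinear fits use `minpack.lm::nlsLM` (Levenberg–Marquardt with
  bounds); closed-form estimators (origin-constrained slopes) are
  evaluated directly and cross-checked against brute-force
  minimisation in the tests.
* Constant size series return $\beta_1 \approx 0$ with a warning, not
  an error; constant correlation inputs return flagged `NA`
  coefficients; a flat pattern yields zero detected peaks.
* Perfect (noise-free) fits have singular covariance; standard-error
  and correlation slots are then `NA` rather than misleading numbers.
* Peak-position refinement falls back to the grid maximum whenever the
  three-point parabola is degenerate or its vertex escapes the
  bracket.
* All statistical simulation sizes in the tests (50–200 seeds, 5
  ratios × 3 runs) match the study-scale designs they emulate while
  keeping a full test run in a few seconds.

## 7. Reproduction entry points

`run_flow_calc()` prints the flow sweep table; `run_reproduce(seed)`
generates a complete synthetic study, analyses it and checks every
recovery tolerance (D_H within 3%, PDI within 0.03, lattice parameter
within 0.5%, domain size within 5%, asymptotic size within 8 nm plus
trend significance, bulk trends mostly nonsignificant), returning a
machine-readable report.  `scripts/acceptance.R` recomputes the
desk-scale headline numbers (mixing times, bilayer thickness) and
writes them as JSON.
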