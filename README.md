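# cuboflow

Analysis chain for **size-controlled cubosome formation by microfluidic
hydrodynamic flow focusing**.

Cubosomes are colloidal nanoparticles of an inverted bicontinuous cubic
lipid phase (here phytantriol, sterically stabilised by Pluronic F127),
of interest as drug-delivery carriers.  When an ethanolic lipid stream
is focused between two aqueous streams in a cross-junction chip, the
flow rate ratio `Q_R = 2*Q_s/Q_m` sets the width of the focused sheet,
hence the solvent-exchange mixing time, hence the nucleation/growth
balance and the final particle size.  `cuboflow` is aimed at soft-matter
and formulation scientists who want to run or audit this analysis:

* **Flow model** — stream partitioning, focused width
  `w_f = w_c/(1.5 (1+Q_R))`, diffusive mixing time
  `tau_mix = w_f^2/(4 D_m)`, residence time, Reynolds number, dilution
  bookkeeping, Damköhler number `Da_p = tau_mix/tau_assbl` and a
  nucleation-rate helper.
* **SAXS** — Pn3̅m reflection indexing
  (`q_hkl = (2π/a)·sqrt(h²+k²+l²)`), origin-constrained
  lattice-parameter regression, Lorentzian Bragg-peak fitting with the
  domain-size bound `ξ ≥ π/k`, and the nodal-surface bilayer-thickness
  relation `φ = 2A₀x + (4πχ/3)x³` (`x = δ/2a`, `A₀ = 1.919`,
  `χ = −2`).
* **DLS** — cumulants fit of `g²(τ)−1`, `PDI = μ₂/Γ̄²`, pooled
  zero-intercept `Γ̄ = D q²` regression across angles, Stokes–Einstein
  diameter `D_H = k_B T/(3πηD)`.
* **Size model & statistics** — fits of
  `D_H = β₁(1+Q_R)^(−β₂) + D_H0` (free or fixed `β₂ = 2`; equivalent
  mixing-time form with `β₂ = 2α₂`), Kendall/Spearman/Pearson trend
  tests and ANCOVA between formulations.
* **Synthetic data** — seeded generators for DLS curves, SAXS patterns
  and size series with known ground truth, so every stage is verified
  by parameter recovery without any external data.

## Worked example

```r
library(cuboflow)

run_flow_calc(c(8, 10, 15, 20, 30))
#> Flow sweep at Q_T = 100 uL/min (100 x 100 um^2 channel, L = 81 mm):
#>  Q_R    Q_m   Q_s w_f_um tau_mix_ms tau_res_s res_mix_ratio reynolds Dil_R
#>    8 11.110 44.44  7.407     21.010     0.486         23.14    16.67     8
#>   10  9.091 45.45  6.061     14.060     0.486         34.56    16.67    10
#>   15  6.250 46.88  4.167      6.647     0.486         73.12    16.67    15
#>   20  4.762 47.62  3.175      3.858     0.486        126.00    16.67    20
#>   30  3.226 48.39  2.151      1.771     0.486        274.50    16.67    30
```

Raising the flow rate ratio from 8 to 30 narrows the focused stream
from 7.4 to 2.2 um and cuts the mixing time from ~21 ms to ~2 ms while
the residence time (0.486 s) and Reynolds number (~17, laminar) stay
fixed — the operating window in which particle size is set by mixing.

A synthetic SAXS pattern with Poisson counting noise, indexed and
fitted end to end, and the bilayer thickness at the 28 wt% water
boundary (72 wt% lipid, density 0.90 g/mL):

```r
pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 81, peak_height = 1e4,
                        poisson = TRUE, seed = 1)
fit_lattice_parameter(detect_peaks(pat))
#> Cubic lattice fit: a = 6.7 nm (slope 0.09378 1/A, 6 peaks, rms 0.00031 1/A)
fit_lorentzian(pat)
#> Lorentzian peak: q0 = 0.1327 1/A, HWHM k = 0.003761 1/A, domain size xi >= 83.52 nm
bilayer_thickness(6.7, weight_to_volume_fraction(0.72))
#> Bilayer thickness: delta = 2.875 nm (a = 6.7 nm, phi = 0.7407, x = 0.2146)
```

Multi-angle DLS and the empirical size model on synthetic study data:

```r
analyze_dls(gen_dls_curves(dh_nm = 143, pdi_true = 0.16, seed = 1))
#> DLS analysis: 6 curves, D_H = 142.9 nm, PDI = 0.161

s <- gen_size_series(seed = 1)   # truth: beta1 2000, beta2 2, D_H0 134
fit_size_model(s, fix_beta2 = 2)
#> Empirical size-model fit: D_H = beta1 * (1 + Q_R)^(-beta2) + D_H0
#>   beta1 = 1905 +/- 2.7e+02 nm
#>   beta2 = 2 +/- 0 (fixed)
#>   D_H0  = 134.9 +/- 1.9 nm
#>   R^2 = 0.944 on 5 points (corr(beta1, D_H0) = -0.80)
correlation_suite(s)
#> Correlations of D_H with Q_R (15 points):
#>   Kendall tau        -0.802 (p = 7.83e-05)
#>   Spearman rho       -0.917 (p = 1.57e-06)
#>   Pearson r vs 1/Q   0.917 (p = 1.53e-06)
#>   Pearson r vs 1/Q^2 0.891 (p = 8.24e-06)
```

The asymptotic size `D_H0` is recovered within its standard error, the
negative Kendall/Spearman trends confirm that size falls monotonically
with `Q_R`, and the reported `corr(beta1, D_H0)` makes the
amplitude/offset compensation of the three-parameter model explicit.

`run_reproduce(seed)` chains all of the above — generate, analyse,
compare to truth — and returns a pass/fail check table;
`inst/scripts/flow-calc.R` and `inst/scripts/reproduce.R` are thin
command-line wrappers.

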