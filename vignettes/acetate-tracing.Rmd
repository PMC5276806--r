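---
title: "Models and methods for quantitative acetate tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative acetate tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetrace)
```

## The scientific problem

Cancer cells both consume and release acetate, and the two-carbon (acetyl)
units derived from it feed mitochondrial oxidation, fatty-acid synthesis and
histone acetylation. Because intracellular acetate cycles rapidly with
acetyl-CoA and exchanges with the medium, the fractional ¹³C labeling of
downstream products alone cannot quantify net carbon transfer. acetrace
implements the quantitative machinery needed to go further: absolute medium
acetate quantification against a ²H₃-acetate internal standard,
growth-normalized net exchange with deconvolution into simultaneous uptake
and release, isotopomer spectral analysis (ISA) of palmitate labeling to
infer lipogenic acetyl-CoA enrichment, kinetic flux profiling (KFP) of
palmitate synthesis, and aggregate histone-bound acetate labeling.

## Mass isotopomer distributions and natural-abundance correction

A measured MID over shifts M+0..M+n mixes tracer incorporation with
naturally occurring heavy isotopes of every atom in the derivatized ion.
`correction_matrix()` builds, by per-atom convolution, the matrix `M` whose
column *j* is the natural mass-shift distribution of a molecule carrying
exactly *j* tracer-labeled carbons; `na_correct()` solves `raw = M x` for
the tracer-only MID. We correct for ¹³C (0.0107), ²H (0.000115) and
¹⁷O/¹⁸O (0.00038/0.00205) because fatty-acid methyl esters carry many H and
O atoms and a carbon-only correction biases the high-mass isotopomers.
Shifts heavier than the measured window are truncated, making `M` lower
triangular with sub-stochastic columns.

Numerical choices: the solve is refused when the condition number exceeds
`cond_max` (default 1e8) rather than returning amplified noise; negative
corrected fractions (a standard noise artifact) are clipped to zero and the
MID renormalized, with a warning whenever the clipped mass exceeds 1e-3 so
the artifact stays visible.

`fraction_labeled()` reports `1 - f(M+0)`; `mean_enrichment()` reports the
carbon-weighted average `sum(k f_k)/n`. The two summaries answer different
questions and are deliberately distinct functions.

## Internal-standard acetate quantification

Medium or histone-hydrolysate acetate is derivatized and monitored at
m/z 61 (¹²C), 63 (¹³C) and 64 (²H₃ internal standard). With 40 µL of 1 mM
standard added to a 200 µL sample the effective standard concentration is
200 µM, and

$$c_{12} = \frac{I_{61}}{I_{64}} C_{IS}, \qquad
  c_{13} = \frac{I_{63}}{I_{64}} C_{IS}.$$

Equal response factors for the three esters are assumed (single-point
within-run quantification; no calibration curve). The M+2 natural
abundance of the light two-carbon fragment that would leak m/z 61 signal
into 63 is below 0.1% — under measurement noise — and is neglected; the
constant `.mz61_to_63_crosstalk` in the source re-enables the subtraction.
Samples without internal-standard signal are flagged, never silently
zeroed. A cell-free blank correction is not modeled because medium acetate
is stable without cells.

## Exchange fluxes and the uptake/release deconvolution

The net exchange flux (release-positive) is

$$e = \frac{\Delta C_{total}}{T}, \qquad
  T = \int \frac{V_{cell}(t)}{V_{medium}}\,dt$$

with `T` the trapezoidal growth-curve integral (packed cell volume per
medium volume), giving mmol/hr/L cell volume. Uptake `u` and release `r`
follow from the balance equations `e = r - u` and `x e = a r - b u`, where
`x` is the ¹²C share of the concentration change, `b` the average medium
¹²C fraction and `a` the average intracellular ¹²C fraction. Working from
Δ-quantities keeps the `e = 0` case well defined:
`r = (ΔC12/T - b ΔCtotal/T)/(a - b)`, `u = r - ΔCtotal/T`.

`a` is unidentifiable (the free intracellular pool is too small to
quantify), so `estimate_exchange()` scans it. Endogenous acetate production
(from glucose/glutamine-derived acetyl-CoA) is unlabeled, so the
intracellular ¹²C fraction cannot fall below the medium's: the default grid
is 101 uniform points on `[b, 1]`. Grid values yielding negative `r` or `u`
violate the physical constraint and are excluded, not clipped. The reported
`r_q05`/`u_q05` are 5% quantiles over the retained scan (pooled with a
seeded well bootstrap, default 1000 draws, when ≥ 3 replicate wells exist):
one-sided lower bounds in the spirit of "with 95% confidence the flux is at
least this high". `b` defaults to the mean of the endpoint medium fractions
(`b_method = "integral"` gives the cell-volume-weighted time average
instead). `|a - b|` below 1e-6 is treated as singular.

`release_uptake_ratio()` — accumulated ¹²C over consumed ¹³C — is
cell-number independent and operationalizes how efficiently a cell line
recaptures endogenously produced acetate.

## Isotopomer spectral analysis of palmitate

Palmitate is built from 8 two-carbon units. With a fraction `D` of
lipogenic acetyl-CoA units fully labeled (a two-state unit: M+2 or M+0),
newly synthesized palmitate occupies even shifts M+2k with probability
`choose(8,k) D^k (1-D)^(8-k)`; a fraction `g` of the pool synthesized since
tracer addition mixes with pre-existing M+0 palmitate. `fit_isa()` fits
`(D, g)` by an exhaustive grid at resolution 0.005 followed by one
box-constrained local refinement — grid-plus-refinement keeps the optimum
deterministic and the runtime bounded, unlike a purely gradient-based fit.
Ties break toward smaller `g`, then smaller `D`, so an all-M+0 input
returns (0, 0). Odd-shift mass (possible via single-carbon exchange, e.g.
through glutamine) is outside the two-state model: it is diagnosed with a
warning and ignored in the residual, never fitted.

We fit `g` jointly with `D` even for steady-state panels: at long labeling
times `g → 1` and `D` is identified by the even-shift shape alone, while at
incomplete turnover a fixed `g = 1` would bias `D` downward. Other
saturated fatty acids are supported through the `n_units` argument
(chain length / 2).

## Kinetic flux profiling

At constant pool size `P`, label incorporation obeys
`dg/dt = (J_syn/P)(1 - g)`, so `g(t) = 1 - exp(-k t)` with
`k = J_syn / P`. `newly_synthesized_series()` extracts `g(t)` from a MID
time course by a joint fit — one `D` shared across the course, one `g` per
time point (closed-form projection per candidate `D`) — and `fit_kfp()`
recovers `k` by bounded one-dimensional least squares. The synthesis flux
is `J_syn = k P` and the two-carbon acetyl demand is `8 J_syn` for C16,
exactly. The constant-pool first-order form is the canonical KFP model;
growth dilution is folded into `k`, and the declared-assumption status of
this choice is the reason the fit operates on `g` (decoupled from MS
response) with `P` supplied externally (absolute palmitate quantification
is out of scope).

## Histone-bound acetate

Hydrolysis of purified histones releases all bound acetate, so the measured
labeling reflects the aggregate histone-bound pool — a proxy for nuclear
acetyl-CoA, with no per-site resolution, quantified through the same SIM
pathway as medium acetate (equal matrix effects assumed).
`compartment_contrast()` reports lipogenic/histone labeling ratios per
tracer; a ratio well above 1 for acetate quantifies how little exogenous
acetate reaches the nuclear pool relative to the cytosolic one.

## What the simulator emulates — and what it does not

`simulate_scenario()` generates every input table the pipeline consumes:

* exponential growth `pcv(t) = pcv0 · 2^(t/td)`;
* medium acetate under constant per-cell-volume fluxes, integrated with
  fixed-step RK4 (step 0.1 hr, via deSolve) of
  `dC_total/dt = (r - u_eff) pcv/V` and `dC12/dt = (a r - b(t) u_eff) pcv/V`,
  with a linear substrate-limited uptake taper below 5 µM so concentrations
  cannot go negative when labeled acetate is nearly exhausted;
* binomial palmitate MIDs convolved with the natural-abundance matrix of
  the methyl ester (C17H34O2);
* first-order labeling kinetics `g(t) = 1 - exp(-k t)`;
* mean-one multiplicative lognormal intensity noise (default CV 2%) and
  replicate wells (default 3).

Preset conditions encode the experimental design: 90 µM U-¹³C-acetate with
~15 µM residual unlabeled acetate in 3 mL medium per well; MDA-MB-468
uptake and release of 3.5 mmol/hr/L cell each; 30% lipogenic acetyl-CoA
enrichment from acetate in hypoxia; BT-474 low-serum net uptake of
8 mmol/hr/L cell with ACSS1 silencing scaling uptake by 0.7; an acetyl
demand of 2.5× net uptake in the hypoxia/low-serum demand condition; halved
palmitate turnover under free-fatty-acid supplementation; histone acetate
contributions of 8% (normoxia) and 15% (hypoxia/low serum).

Values the design does not pin down were chosen once as realistic culture
parameters: doubling times of 30 hr (normoxia) and 48 hr (hypoxia/low
serum); seeding densities of 0.33 µL packed cell volume per well for
flux-window experiments (~1.6×10⁵ cells) and 2.5 µL for the dense 72-hr
hypoxic depletion course; an intracellular ¹²C fraction `a = 0.95`
(released acetate is overwhelmingly unlabeled); a palmitate pool of
20 mmol/L cell volume with `k = 0.0625 /hr` in the demand condition
(`J_syn = 1.25`, demand `= 10` mmol/hr/L cell). The exchange flux window
defaults to 24 hr for the near-balanced normoxic condition — short enough
that the medium ¹²C fraction drifts only modestly, which keeps the
endpoint-mean estimate of `b` close to the cell-volume-weighted average —
and 48 hr for net-uptake conditions.

The simulator reproduces the statistical structure the analysis assumes;
it does not emulate chromatographic artifacts, medium evaporation,
derivatization-yield drift, day effects, or biological well-to-well
variability beyond multiplicative measurement noise. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every failure mode of real GC-MS data.

## A worked pass

```{r demand}
cfg <- scenario("hypoxia_lowserum_demand", noise_cv = 0)
mids <- lapply(mids_from_table(simulate_palmitate_mids(cfg)),
               na_correct, formula = cfg$fame_formula)
ser <- newly_synthesized_series(mids, cfg$kfp_times)
kfp <- fit_kfp(ser$times, ser$g, cfg$palmitate_pool)
kfp
e <- net_exchange(simulate_medium_acetate(cfg)$concentrations,
                  simulate_growth(cfg))
demand_vs_uptake(kfp, e)
```

## Known limitations

* The two-state acetyl unit cannot represent M+1 units; odd-shift signal is
  diagnosed only.
* ACLY- versus ACSS2-derived cytosolic acetyl-CoA sub-pools are not
  identifiable from these data and are not modeled.
* The exchange deconvolution assumes fluxes constant per unit cell volume
  over the window; strongly time-varying fluxes bias the endpoint-based
  estimates.
* Pool expansion during growth is folded into the KFP rate constant rather
  than modeled explicitly.
* Problem sizes used throughout the tests (≤ 101-point a-grids, ≤ 1000
  bootstrap draws, 200-replicate noise studies, 0.1-hr integration steps)
  are the package's defaults and complete in seconds on one core.
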