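# acetrace

Quantitative analysis of ¹³C-acetate tracing in cultured cells.

Cancer cells exchange acetate with their medium while the derived two-carbon
acetyl units feed mitochondria, fatty-acid synthesis and histone
acetylation. Because intracellular acetate cycles rapidly with acetyl-CoA,
fractional labeling of downstream products alone cannot quantify net carbon
transfer. acetrace implements the full quantitative chain for researchers
analyzing GC-MS stable-isotope tracing experiments:

* **MID handling** — natural-abundance correction of mass isotopomer
  distributions by per-atom convolution (¹³C, ²H, ¹⁷O/¹⁸O), with explicit
  conditioning and clipping diagnostics (`correction_matrix`, `na_correct`,
  `fraction_labeled`).
* **Absolute acetate quantification** — ¹²C and ¹³C acetate from selected-ion
  intensities (m/z 61/63/64) against a ²H₃-acetate internal standard:
  `c12 = (I61/I64)·C_IS`, `c13 = (I63/I64)·C_IS` (`quantify_acetate`).
* **Exchange fluxes** — net exchange `e = ΔC_total/T` per growth-integrated
  cell volume `T = ∫ V_cell/V_medium dt`, deconvolved into simultaneous
  release and uptake via the balance equations `e = r − u` and
  `xe = ar − bu`, scanning the unidentifiable intracellular ¹²C fraction
  `a` and reporting one-sided 5%-quantile lower bounds (`estimate_exchange`).
* **Isotopomer spectral analysis** — lipogenic acetyl-CoA enrichment `D` and
  fraction newly synthesized `g` from palmitate MIDs by best fit against
  binomial distributions, `P(M+2k) = C(8,k) D^k (1−D)^(8−k)` (`fit_isa`).
* **Kinetic flux profiling** — palmitate synthesis flux from
  `g(t) = 1 − exp(−kt)`: `J_syn = kP`, two-carbon acetyl demand `8·J_syn`
  (`fit_kfp`, `demand_vs_uptake`).
* **Histone-bound acetate** — aggregate labeling of hydrolysate acetate and
  the lipogenic-versus-nuclear contrast (`histone_fraction_labeled`,
  `compartment_contrast`).
* **Scenario simulator** — seeded generator of every input table under
  preset culture conditions, for end-to-end recovery testing
  (`simulate_scenario`, `scenario_presets`).

## Worked example

Simulate a BT-474 low-serum condition (net acetate uptake ~8 mmol/hr/L cell
volume, 30% lipogenic acetyl-CoA enrichment from acetate, 2% measurement
noise) and run the whole pipeline on the written CSV bundle:

```r
library(acetrace)
dir <- tempfile()
simulate_scenario(scenario("BT474_lowserum", noise_cv = 0.02),
                  seed = 42, out_dir = dir)
res <- run_pipeline(dir, seed = 42, n_boot = 200)
res$fits$exchange
#> Acetate exchange flux estimate (mmol/hr/L cell volume, release-positive)
#>   window: 0-48 hr;  T = 0.007618 L cell*hr/L medium;  b = 0.157
#>   net exchange e: median -7.715  (95% CI -7.993 to -7.533)
#>   release  r >= 0.2345  (5% quantile)
#>   uptake   u >= 7.866  (5% quantile)
#>   intracellular 12C fraction retained: [0.157, 1.000]  (3 wells, 200 bootstrap draws)
res$fits$isa
#> Isotopomer spectral analysis fit
#>   lipogenic AcCoA enrichment D = 30.1%
#>   fraction newly synthesized g = 0.950
#>   SSR = 5.33e-05 (grid 0.005, 8 two-carbon units)
res$fits$kfp
#> Kinetic flux profiling fit (first-order incorporation)
#>   k = 0.06286 /hr   pool P = 20 mmol/L cell
#>   synthesis flux J_syn = k*P = 1.257 mmol/hr/L cell
#>   two-carbon acetyl demand = 8*J_syn = 10.06 mmol/hr/L cell
#>   RSS = 0.000142 over 5 points
```

Reading the numbers: the cells take up a net ~7.7 mmol acetate/hr/L cell
volume (negative `e` = uptake; the truth in this preset is 8). The release
lower bound is near zero — this high-capture condition releases little
unlabeled acetate. 30% of the acetyl-CoA consumed by fatty-acid synthase
derived from the acetate tracer, and ~95% of the palmitate pool turned over
during the 48-hr course. The fitted two-carbon demand for palmitate
synthesis alone (≈10 mmol/hr/L cell) exceeds the net acetate uptake —
`res$summary$demand_vs_uptake` ≈ 1.3 here.

The methods vignette (`vignettes/acetate-tracing.Rmd`) documents the
models, assumptions, numerical choices and the simulator's scope.

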