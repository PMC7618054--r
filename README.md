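# atosensor

Mechanistic modelling and global sensitivity screening for whole-cell
acetoacetate biosensors built on the *Escherichia coli* AtoSC two-component
system (TCS).

Acetoacetate is a ketone body whose levels matter in diabetic ketoacidosis,
ketosis in dairy cattle, and several bioproduction settings.  Engineered
*E. coli* strains sense it through the AtoS histidine kinase (HK) / AtoC
response regulator (RR) phosphorelay driving GFP from the Pato promoter.
This package is for synthetic biologists designing such sensors: it answers
*which parts of the system are worth re-engineering* (expression levels?
copy number? binding rates?) before anything is cloned.

It provides:

* a mass-action ODE model of the AtoSC phosphorelay (12 species, one
  reaction per named rate constant, conserved HK/RR/promoter totals) with a
  stiff-capable steady-state solver (`deSolve` + a Newton-type root polish);
* dose-response sweeps over the HK autophosphorylation rate `k_ap` — the
  model's acetoacetate proxy — summarised by the Hill transfer function with
  basal expression,

  `y(d) = fmin + (fmax − fmin) · dⁿ / (Kⁿ + dⁿ)`,

  with half-maximal dose `K` (the biosensor's K1/2), dynamic range
  `(fmax − fmin)/fmin` and fold change `fmax/fmin`;
* a from-scratch Morris elementary-effects screen (candidate trajectories,
  Campolongo optimal-subset selection, signed effects, `mu`/`mu*`/`sigma`
  and the normalised-`mu*` heatmap) of all 16 TCS parameters against the
  fitted response features;
* a synthetic flow-cytometry generator (log-normal single-cell events,
  rainbow-bead calibration to molecules of equivalent fluorophore,
  median-per-well summaries, ≥3 biological replicates) that stands in for
  wet-lab dose-response assays in parameter-recovery experiments;
* a configuration-driven pipeline (`run_pipeline()`, plus a thin CLI at
  `inst/scripts/atosensor`) with seeded, manifest-tracked, reproducible runs.

## Worked example

```r
library(atosensor)

# 1. model dose-response at the nominal operating point
curve <- sweep_dose_response(tcs_parameters(), default_kap_grid(13))
fit_hill(curve)
#> Hill transfer-function fit
#>   fmin       0.01818  (se 0.0001343)
#>   fmax         1.816  (se 0.0001665)
#>   K          0.01004  (se 4.103e-06)
#>   n           0.9989  (se 0.000376)
#>   dynamic range 98.87, fold change 99.87
```

The default model is a working switch: ~99-fold induction of steady-state
mature GFP, half-maximal at `k_ap ≈ 0.01`, an essentially hyperbolic
response (`n ≈ 1`).

```r
# 2. synthetic recovery experiment for the genome-expressed sensor
#    (truth: K = 344 uM, fold change 115; 3 replicates, 5% well noise)
study <- generate_study(hill_fixture("asah0"), noise_cv = 0.05, seed = 1)
fit_study(study)
#> Hill transfer-function fit
#>   fmin         64.13  (se 144.9)
#>   fmax     1.198e+04  (se 177.9)
#>   K            381.5  (se 21.15)
#>   n            1.371  (se 0.09816)
#>   dynamic range 185.9, fold change 186.9
```

One noisy 39-well study recovers K1/2 within ~11% (381 vs 344 uM, inside
2 SE); basal-level-derived quantities (dynamic range) are noisier because
`fmin` is small and weakly determined — exactly the behaviour real
characterisations show.  Averaging over 20 seeded studies recovers the
generating K1/2 to within a few percent (see the acceptance script below).

```r
# 3. scaled-down sensitivity screen: which parameters shape the response?
res <- morris_screen(design = morris_design(R = 100, r = 10, seed = 42),
                     kap_grid = default_kap_grid(9))
round(res$mu_star_normalised, 2)   # parameters x {fmin, fmax, K, n, fold_change}
rank_parameters(res)
```

The normalised-`mu*` heatmap flags the leaky/induced transcription rates,
promoter availability (`pato`), promoter binding, and the HK/RR totals
(`S`, `C`) as influential — the concentrations of the three TCS components
are tunable via copy number and constitutive expression, which is what makes
the screen actionable for design.

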