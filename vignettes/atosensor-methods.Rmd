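---
title: "Modelling and screening the AtoSC acetoacetate biosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and screening the AtoSC acetoacetate biosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atosensor)
```

## The system and the model

The AtoSC two-component system (TCS) is the acetoacetate-sensing module of
*Escherichia coli*: the membrane histidine kinase AtoS (HK)
autophosphorylates in the presence of acetoacetate, transfers the phosphoryl
group to the response regulator AtoC (RR), and phospho-AtoC activates
transcription from the Pato promoter.  Engineered whole-cell biosensors put a
GFP reporter under Pato control, so the cell's fluorescence transduces the
extracellular acetoacetate concentration.

`atosensor` implements a mass-action ODE model of this module with twelve
species: free and phosphorylated HK (`S`, `Sp`), free and phosphorylated RR
(`C`, `Cp`), the three HK:RR complexes (`SpC`, `SCp`, and the dead-end `SC`),
free and occupied promoter (`P`, `PCp`), and the reporter cascade (mRNA `M`,
immature GFP `Gi`, mature GFP `Gm`).  Each named rate constant corresponds to
one elementary process (see `build_reaction_network()`): HK
autophosphorylation (`k_ap`) and autodephosphorylation (`k_ad`); reversible
binding of phospho-HK to RR (`k_b1`/`k_d1`) followed by phosphotransfer
(`k_pt`, releasing HK and phospho-RR in one step); reversible binding of HK
to phospho-RR (`k_b2`/`k_d2`) followed by phosphatase action (`k_ph`,
releasing HK and RR); reversible dead-end HK:RR binding (`k_b3`/`k_d3`);
reversible promoter occupancy by phospho-RR (`k_bnd`/`k_unbnd`); leaky and
induced transcription (`k_lgexp` from free Pato, `k_pmgexp` from occupied
Pato); and a one-mRNA, one-maturation-step reporter cascade (`k_trl`,
`k_mat`, `d_m`, `d_g`).

Three structural assumptions are worth stating explicitly:

* **Conserved totals.**  HK, RR and promoter are neither synthesised nor
  degraded on the timescale of an assay; `S_tot`, `C_tot` and `P_tot` are
  conserved moieties, treated as parameters.  This is how "expression level"
  and "copy number" enter the model — as totals, not as synthesis rates — and
  the integrator is required to conserve them to 1e-6 relative.
* **`k_ap` as the dose.**  Acetoacetate is not a species; the HK
  autophosphorylation rate is swept as its proxy.  Dose-response curves are
  steady-state `Gm` against `k_ap`.
* **Single-step phosphotransfer and phosphatase.**  `SpC -> S + Cp` and
  `SCp -> S + C` release both partners at once, the standard coarse-graining
  for TCS kinetics.

All reactions are mass action.  Stochastic simulation, spatial effects and
growth dilution of HK/RR are out of scope; the reporter dilution rate `d_g`
is the only growth-like term.

### Parameter values and units

Time and concentration units are arbitrary but consistent.  The nominal
defaults in `tcs_parameters()` are a stand-in operating point — not fitted
values — chosen once so that the default sensor is a working switch: binding
constants of order 1–10, phosphotransfer/phosphatase of order 1, a 100-fold
ratio of induced to leaky transcription, and totals `S_tot = 1`, `C_tot = 2`,
`P_tot = 0.1`.  Under these defaults the dose-response in `k_ap` is sigmoidal
with its half-maximal dose inside the default sweep grid
(`default_kap_grid()`: zero plus twelve log-spaced points over
`1e-4`–`1`).  The reporter constants only scale the output and are excluded
from sensitivity rankings, so their values are immaterial to the screen.

## Steady states

`simulate_to_steady_state()` integrates with the stiff solver
`deSolve::lsoda` (compiled derivative, `rtol = 1e-8`, `atol = 1e-10`) over
geometrically growing horizons, declaring convergence when every species
changes by less than `rel_tol` (default 1e-6) across a probe window covering
the final 10% of elapsed time.  Species smaller than 100x `atol` are treated
as zero rather than held to a relative criterion.  The bail-out horizon is
`t_max = 1e6` time units.

Some parameter corners relax extremely slowly (small `k_ap` combined with
slow unbinding can push the dominant timescale past `1e7`).  After each
unconverged probe the solver therefore also attempts the algebraic steady
state directly: the rank-9 right-hand side is augmented with the three
conservation constraints and solved by Levenberg–Marquardt in
log-concentration coordinates (equilibrium abundances span ten-plus decades;
the log transform repairs the conditioning), with residual rows scaled by
each species' total turnover.  A candidate root is accepted only if its
residuals are small against those scales *and* a short re-integration from it
stays within `rel_tol` — so the convergence criterion is never weakened, slow
corners just become cheap.  Tiny negative excursions (below 1e-9) are
clamped; anything larger is treated as an integrator bug and raised.

## Hill characterisation

Dose-response curves are summarised by the four-parameter Hill function with
basal expression

$$y(d) = f_{min} + (f_{max} - f_{min}) \frac{d^{\,n}}{K^{n} + d^{\,n}},$$

fitted by Levenberg–Marquardt least squares (`minpack.lm`).  Derived
quantities follow the conventional definitions: dynamic range
$(f_{max}-f_{min})/f_{min}$ and fold change $f_{max}/f_{min}$, which differ
by one identically.

Choices that were genuinely open, and what this package does:

* **Initialisation.**  Multi-start over Hill coefficients
  $n_0 \in \{0.5, 1, 2, 4\}$, with $f_{min,0}$/$f_{max,0}$ at the observed
  extremes and $K_0$ at the dose nearest the half-range response; the lowest
  converged residual wins.  The starting amplitude is kept at least 5% above
  $f_{min,0}$ so that flat (insensitive) curves do not start at a singular
  point of the objective.
* **Bounds.**  All parameters non-negative, $n \le 10$, and $K$ capped at
  1000x the largest sampled dose.  The cap is an identifiability bound: for
  curves that never approach saturation, $K$ and $f_{max}$ drift along a flat
  ridge; the cap terminates the ridge without affecting any fit whose
  half-maximal dose the data can actually locate.
* **Hill coefficient.**  Estimated by default; `n_fixed` clamps it, for
  protocols that fit a fixed-shape response.
* **Weighting.**  Unweighted unless per-point dispersions are supplied, in
  which case inverse-variance weights are used.
* **Uncertainties.**  Asymptotic standard errors from the curvature at the
  optimum (reported fit uncertainties are treated as standard errors
  throughout).  For degenerate fits the information matrix is singular and
  the standard errors are `NA` while the point estimates remain defined.

## Morris elementary-effects screening

The screen asks which of the 16 TCS parameters (the 14 rate constants plus
the `S`, `C` and `pato` totals — the swept `k_ap` and the reporter cascade
are excluded) most influence the fitted response features
$\{f_{min}, f_{max}, K, n, \text{fold change}\}$.

Sampling follows the Morris one-at-a-time design on a $p$-level grid in the
unit hypercube ($p = 4$ levels and step $\Delta = p/(2(p-1)) = 2/3$, the
standard choice), with each unit coordinate mapped to its parameter range.
Ranges default to two decades centred on the nominal value, sampled uniformly
in log10 — rates and concentrations are scale parameters, and linear sampling
would let absolute magnitudes dominate the design.  These bounds are the
package's stand-ins and are fully configurable via `parameter_space()`.

From `R` candidate trajectories (default 1000), the `r` kept (default 50)
maximise the Campolongo spread criterion — the root of the summed squared
pairwise trajectory distances, a trajectory distance being the sum of
Euclidean distances over all point pairs.  Exhaustive search over
$\binom{1000}{50}$ subsets is impossible, so selection is a deterministic
greedy build (best pair, then best single extensions) refined by single-swap
hill climbing until no swap improves the criterion.  The test suite holds
this heuristic to the exhaustive optimum on every random small instance it
draws.  Note that two *identical* trajectories have positive mutual distance
under the all-point-pairs definition (the within-trajectory spread), so
duplicates are discouraged but not formally excluded by the criterion.

Each trajectory point becomes a full parameter set, is swept over a
9-to-13-point `k_ap` grid to steady state, and Hill-fitted.  Elementary
effects are the signed finite differences along each trajectory step divided
by the signed step; per (parameter, feature) cell the screen reports the
signed mean $\mu$, the mean absolute effect $\mu^*$, and the standard
deviation $\sigma$ (denominator $r-1$).  For display, $\mu^*$ is normalised
per feature column by its maximum, the usual heatmap convention.

Failure policy: a point whose steady states or fit fail is recorded as
missing — never zero-imputed, which would bias $\mu$ toward zero — and
individually non-finite features (fold change when the fitted basal level is
exactly zero) are likewise missing.  A run aborts if more than 10% of points
fail.  Ranking (`rank_parameters()`) orders by $\mu^*$ within each feature
after removing excluded parameters, breaking ties by $\sigma$ then name;
reporter parameters never enter the space, so rankings reflect the TCS
itself.

## The synthetic cytometry generator

The experimental characterisations this package's recovery experiments stand
in for are plate-based dose-response assays read by flow cytometry: per well,
10,000 single-cell GFP events; rainbow-bead calibration converting arbitrary
units (a.u.) to molecules of equivalent fluorophore (MEF); the per-well
median as the summary statistic; at least 3 biological replicates per
concentration.

`generate_study()` emulates exactly that pipeline:

* **Single-cell noise** is log-normal — the standard model for fluorescence
  distributions, strictly positive — with the log-median at the true well
  median and dispersion set so the coefficient of variation equals
  `event_cv` (default 0.4, a typical single-cell CV).
* **Replicate variation** is a multiplicative log-normal factor on the well
  median with CV `noise_cv`; biological repeats scatter around the curve
  without a claimed mechanism.
* **Calibration** is an OLS fit of log10(MEF) on log10(a.u.) over bead peaks
  (`fit_calibration()`), the standard MEF conversion; because the map is
  monotone it commutes with the median, so summarising in a.u. and
  converting is exact.
* **`noise_cv = 0`** defines the idealised noise-free assay: the replicate
  factor is 1 *and* the event distribution degenerates to the true median,
  so the round trip through events, medians and fitting is exact up to
  optimiser tolerance.

The default concentration grid spans 0–20 mM (thirteen points), covering the
physiological ketone-body range up to the concentrations used for maximal
induction; it is a stand-in, not a printed protocol.

Three fixtures pin the generator to reported biosensor characterisations:
`asah0` (genome-expressed AtoS/AtoC, K1/2 = 344 uM, fold change 115),
`asah2j06` (high-copy plasmid expression, K1/2 = 31.7 uM) and `asal2j06`
(low-copy plasmid expression, K1/2 = 40.1 uM).  Only the half-maximal doses
and the `asah0` amplitude ratio are pinned to printed numbers; absolute
fluorescence levels and Hill coefficients (n = 1.5) are stand-ins that
preserve the qualitative ordering between constructs (lowest basal level and
largest amplitude for the genome-expressed sensor; the low-copy plasmid
variant below the high-copy one in both extremes).

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: autofluorescence and its subtraction,
gating and debris, instrument saturation, day effects correlated across
wells, growth-condition dependence of the response, and any deviation of the
true transfer function from Hill form.  Recovery experiments demonstrate
that the fitting pipeline is unbiased and correctly calibrated under the
stated noise model, not that the model captures every feature of a real
assay.

## A worked example

```{r example, eval = FALSE}
# model dose-response and its Hill summary
curve <- sweep_dose_response(tcs_parameters(), default_kap_grid(13))
fit_hill(curve)

# synthetic recovery experiment for the genome-expressed sensor
study <- generate_study(hill_fixture("asah0"), noise_cv = 0.05, seed = 1)
fit_study(study)

# scaled-down sensitivity screen
res <- morris_screen(design = morris_design(R = 100, r = 10, seed = 42),
                     kap_grid = default_kap_grid(9))
round(res$mu_star_normalised, 2)
rank_parameters(res)
```

## Problem sizes, tolerances and reproducibility

The test suite and the acceptance script run the full pipeline at sizes
chosen to exercise every code path at interactive cost: recovery experiments
use 20 seeded studies of 39 wells with 10,000 events each; the sensitivity
screen in the checks uses 100 candidate trajectories, 10 selected, and a
9-point dose grid (the full 1000/50 design of `morris_design()` remains the
default for real runs and is configurable end to end).  Every stochastic
stage takes an explicit seed, restores the caller's RNG state, and is
byte-reproducible given (inputs, seed); `run_pipeline()` records the seed
and a configuration hash in each run's manifest.

Numerical tolerances are stated where they bind: integration at
`rtol = 1e-8` / `atol = 1e-10`, conservation enforced at 1e-6 relative,
steady-state convergence at `rel_tol = 1e-6` over the probe window,
steady-state residual acceptance at 1e-9 of per-species turnover, and exact
noise-free Hill recovery verified to 1e-4 relative.

## Known limitations

* The model omits regulation of the *ato* operon beyond the TCS itself
  (catabolite repression, small-RNA effects), so quantitative agreement with
  in vivo dose-response data is not expected — the intended use is ranking
  parameters and exploring qualitative design moves.
* Hill features of nearly flat or unsaturated curves are weakly identified;
  the screen inherits that noise in the `K` and `n` columns, which is
  visible as elevated $\sigma$ rather than hidden.
* The Morris screen's bounds are stand-ins; conclusions about specific rate
  constants should be re-run with bounds grounded in measurements via
  `parameter_space()`.
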