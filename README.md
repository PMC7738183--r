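# granuleFusion

Simulation and analysis of insulin-granule subpopulation experiments in
R. Insulin-secreting beta cells carry two kinds of dense-core granule,
distinguished by their synaptotagmin calcium sensor: **syt7** granules
(high calcium affinity, slow content release, ~175 nm) and **syt9**
granules (low affinity, fast release, ~215 nm). Diabetes-model
treatments delete one subpopulation — palmitate ("ffa") leaves syt7-like
granules; an inflammatory cytokine cocktail leaves syt9-like granules —
and this shows up quantitatively in calcium dose-response curves,
single-event release kinetics, size distributions, lipid composition and
KCl-stimulated secretion.

The package provides, for each of those readouts, both the analysis and
a seeded generator that produces realistic synthetic input with ground
truth attached, so every estimator can be audited end to end:

* **TIRF single-event photometry** — spot detection on maximum-intensity
  projections, 5x5 ROI traces, a two-step content-release model whose
  fitted intensity step at granule collapse (delta-I_C) separates slow
  from fast release modes, per-cell release durations, Manders
  colocalization.
* **Calcium dose-response** — fraction-fused curves with Wilson
  intervals, one/two-component Hill decomposition
  F(C) = F_max * sum_j w_j C^h/(C^h + K_j^h), AICc model selection, and
  scenario comparison (which affinity component a treatment lost).
* **FCS hydrodynamic sizing** — 3D diffusion autocorrelation models with
  blinking/triplet photophysics, confocal-volume calibration, Vogel
  viscosity eta(T) = exp(A + B/(C+T)) and Stokes-Einstein conversion
  R_h = kT/(6 pi eta D), with per-run temperature correction.
* **Diameter mixtures** — Gaussian-mixture EM with restarts and an
  explicit separability flag.
* **Biochemical statistics** — lipidomics normalisation, Welch volcano
  (-log2 p), class enrichment, immunodepletion protein fractions,
  secretion normalisations.

## Worked example

```r
library(granuleFusion)

scen <- makeScenario("untreated")
sim  <- simulateFusionOutcomes(scen, nGranules = 300, seed = 11)
curve <- assembleDoseResponse(sim$outcomes)
sel <- selectDoseModel(fitDoseResponse(curve, 1), fitDoseResponse(curve, 2))
sel$chosen
#> HillFit: 2 component(s), fMax=0.623, AICc=50.9
#>   component 1: w=0.45 K_1/2=11.2 uM h=6.35
#>   component 2: w=0.55 K_1/2=40.8 uM h=6.35
```

The untreated granule pool is decomposed into two Hill components whose
half-activations (11.2 and 40.8 uM here) recover the generating
high-affinity (syt7, 12 uM) and low-affinity (syt9, 41 uM) sensors with
roughly equal weights; a palmitate-scenario curve run through the same
code keeps only the high-affinity component.

```r
report <- runScenarioPipeline("untreated")
report
#> granuleFusion run report -- scenario 'untreated' (seed 1, v0.99.0)
#>   dose-response: 2 component(s), K_1/2 = 11.7/41.4 uM
#>   sizing: 196 +/- 52 nm (n=2000)
#>   FCS: hydrodynamic diameter 195 nm
#>   lipids: 7 significant species (PC 40:6, PE 38:3, PI 34:1, PI 36:1,
#>           SM 42:1, LPC 36:4, DAG 36:4)
#>   secretion: rel. 25 mM 0.52, 90 mM 1.00
```

The composite run adds the size summary (the 50/50 mixture of 175 and
215 nm populations pools to ~195 nm), the FCS round trip (synthetic
correlation curves fitted, viscosity-corrected and converted back to a
195 nm hydrodynamic diameter), the lipid volcano (the 3-fold SM 42:1
enrichment in syt7 granules is the strongest signal; the handful of
other flagged species are the expected ~5% false positives of the
per-species p < 0.05 rule) and secretion ratios. See `vignettes/granule-subpopulations.Rmd` for the models,
parameter defaults and their rationale.

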