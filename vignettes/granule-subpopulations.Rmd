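---
title: "Models and methods: distinguishing insulin granule subpopulations"
author: "granuleFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: distinguishing insulin granule subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granuleFusion)
```

# The scientific problem

Insulin is stored in dense-core secretory granules and released by
calcium-triggered exocytosis. This package models a system in which the
granule pool of an insulin-secreting beta-cell line consists of two
subpopulations defined by which synaptotagmin calcium sensor a granule
carries: **syt7 granules** (high calcium affinity, slow content release,
smaller diameter) and **syt9 granules** (low calcium affinity, fast
release, larger diameter). Diabetes-model treatments delete one
subpopulation: palmitate ("ffa", a type-2-diabetes lipotoxicity model)
leaves only the syt7-like population; a cytokine cocktail (a
type-1-diabetes inflammation model) leaves only the syt9-like population.

The quantitative signatures of the two populations are:

* a **biphasic calcium dose-response** of granule-to-planar-bilayer
  fusion, decomposable into two Hill components with half-activations
  K_1/2 near 12 and 41 uM (whole-pool curves) or 10 and 48 uM
  (immunodepleted pools);
* a **bimodal distribution of the content-release intensity step**
  (delta-I_C) in single-event TIRF photometry, defining slow and fast
  release modes;
* a **two-component diameter mixture** (about 175 vs 215 nm) whose pooled
  mean is about 195 nm, measurable by cryo-EM sampling or by FCS
  hydrodynamic sizing;
* a **lipid composition difference**: one sphingomyelin species (SM 42:1)
  about 3-fold enriched in syt7 granules.

Every analysis stage is paired with a seeded generator that produces the
corresponding raw input with ground truth attached, so the full pipeline
can be exercised and its estimators audited end to end.

# Generative model and calibration

`makeScenario()` builds one of six scenario configurations. Fusion of a
docked granule at calcium concentration $C$ (uM) is Bernoulli with

$$P(\text{fuse}) = p_{\max}\,\frac{C^h}{C^h + K_{1/2}^h},$$

and a scenario's curve is the weight-mixture of its populations'
responses. Calibration choices:

* **K_1/2**: 12/41 uM for treatment scenarios, 10/48 uM for depletion
  scenarios, as fitted for the respective experiments; two-population
  scenarios mix 50/50.
* **$p_{\max} = 0.6$** for both populations, so the untreated pool fuses
  at about 60% at 100 uM calcium (the closed-form value at the defaults is
  59.7%).
* **Hill coefficient $h = 5$.** The cooperativity of calcium-triggered
  exocytosis is not identifiable from the summary values we calibrate to,
  so it is set from the field's consensus that fast, synaptotagmin-driven
  exocytosis has steep calcium cooperativity (Hill coefficients of 4-5 in
  chromaffin and synaptic preparations). The choice matters: a biphasic
  curve built from two Hill components with a K ratio of only 3.4 is
  statistically indistinguishable from a single shallow Hill curve when
  the components are themselves shallow ($h \le 3$) at realistic counting
  depth (8 dose levels x 300 granules). With $h = 5$ the untreated curve
  has a visible intermediate plateau, as the two-population model
  predicts, and model selection resolves it reliably. `hill` is
  configurable per population.
* **Dose ladder** `defaultCalciumLadder()` = 4, 9, 13, 18, 24, 32, 45,
  300 uM: eight levels bracketing both transitions, with a saturating top
  level.
* **Diameters**: syt7 ~ N(175, 40) nm, syt9 ~ N(215, 50) nm, truncated at
  zero; the 50/50 mixture has mean 195 nm (`diameterMixtureMoments()`).
  The mixture SD (49.5 nm) is below the cryo-EM spread reported for real
  granule pools, which also carry measurement error; only the mean is
  treated as a calibration target.
* **Release kinetics**: the pore phase loses content exponentially at
  `poreRate` (0.4/s slow, 2/s fast) and ends after one time constant,
  when the granule collapses and the remaining content produces an
  intensity step delta-I_C = `collapseGain` x (pre-collapse intensity);
  `collapseGain` is 0.3 (slow) vs 0.8 (fast), putting the two delta-I_C
  modes at a 2.7-fold separation at equal brightness. The post-collapse
  decay rate is 1/s vs 4/s. The "true" release duration is defined as the
  pore phase plus three post-collapse time constants (97.5% of remaining
  content).
* **Fusion delay** after calcium arrival is exponential with mean 2 s
  (`delayMean`), truncated to the recording; events are aligned to the
  20 Hz frame grid (sub-frame timing is out of scope).
* **KCl-to-calcium surrogate** for the secretion generator: 25 mM -> 30
  uM, 90 mM -> 100 uM effective calcium. 30 uM places the untreated pool
  at ~60% of its 90 mM response while a syt7-only pool is already at ~87%
  of saturation, reproducing the qualitative pattern that the
  palmitate-model cells respond almost fully at the low stimulus.
  Because treatments *delete* a subpopulation rather than renormalising
  the pool, single-population scenarios secrete from half of the
  untreated releasable pool, so their absolute high-stimulus response is
  about half that of untreated cells.

## What the generators do and do not emulate

The stack generator renders granules as 2D Gaussian spots (sigma 1.2 px)
over a constant background with Poisson pixel noise; it does not model
bleaching, TIRF penetration-depth variation, drift, or realistic PSF
side-lobes. The FCS generator adds stationary Gaussian noise proportional
to $G(\tau) - 1$ plus a floor; real correlator noise is lag-correlated.
Lipid peak areas are independent log-normals; real lipidomics data have
correlated species. Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to every instrument
artefact.

# TIRF single-event photometry

Stacks are temporally filtered by a moving average (`preprocessStack`),
max-projected, and spots are detected as local maxima above the
background median + 6 MAD with a 4 px minimum separation and sub-pixel
centroid refinement (`detectGranules`); the detection algorithm of the
original instrument software is not public, so robust-statistics
thresholding is used. Traces are 5x5 pixel sums around each centre with
an annulus-median background (radii 4-7 px, also unspecified upstream and
chosen here) -- photometry is taken from the *raw* stack; the filtered
stack is used for detection only.

`segmentEvent` finds the onset as a sustained one-sided (downward)
departure of the smoothed trace from the docked baseline, then refines it
with a least-squares changepoint search that jointly scans onset frame
and initial decay rate over a fixed window ending before the collapse
peak. Onset localisation is information-limited for slow decays: at
pore rate 0.4/s and 20 Hz the per-frame signal change is ~2% of the
docked intensity, so onset and rate trade off and even a joint
least-squares changepoint has a few frames of intrinsic uncertainty at
moderate signal-to-noise. The tests therefore assert frame-exact onsets
(+/- 2 frames in >= 95% of events) for the fast mode and median
unbiasedness for the slow mode. The event end is the first sustained
re-entry into the post-release plateau band (+/- 2 noise SD for >= 5
frames), a criterion the original description leaves open.

`fitRelease` fits the piecewise two-step model by discrete candidate
search over (onset, collapse) frames with Levenberg-Marquardt fits of the
four continuous parameters; on noiseless traces from the model class the
recovery is exact. Events whose fits fail are flagged "unclassified",
never dropped silently. `classifyModes` fits a two-component Gaussian
mixture to the fitted delta-I_C values; the lower-mean component is
"slow", posterior ties go to "slow", and a collapsed mixture (minor
weight < 0.05 or means within 0.5 pooled SD) assigns a single label by
comparison with a configurable reference scale (default 60 counts on the
single-spot amplitude scale; note that 5x5 ROI traces carry an extra PSF
integration factor of about $2\pi\sigma^2 \approx 9$, so mixtures fitted
on ROI traces sit at correspondingly larger values -- the mixture itself
is scale-free).

Granules that move between docking and fusion are excluded from mode
analysis by a 2 px centroid-drift rule (`granuleDrift`), a threshold the
original analysis states only qualitatively. Manders colocalization uses
fixed thresholds or per-channel Otsu defaults; the upstream plugin's
thresholds are not recorded.

# Calcium dose-response decomposition

`assembleDoseResponse` computes the fraction of docked granules fusing
within the scoring window with Wilson intervals. `fitDoseResponse` fits

$$F(C) = F_{\max} \sum_j w_j \frac{C^{h_j}}{C^{h_j} + K_j^{h_j}},
\qquad \sum_j w_j = 1,$$

by weighted least squares (binomial variance weights; an unweighted
option is retained for sensitivity analysis) with multi-start
Levenberg-Marquardt, bounds $h \in [0.5, 6]$ and $K \in [0.5, 500]$ uM,
and components reported in ascending K. Two-component fits share the Hill
coefficient by default (both sensors are C2-domain proteins; a free
per-component $h$ is available via `hillShared = FALSE`); with only
eight dose levels, sharing $h$ is what keeps the decomposition
identifiable. Standard errors are asymptotic, mirroring the "K_1/2 = 12
+/- 2 uM" reporting convention; whether such printed intervals are fit
SEs or replicate SDs is generally ambiguous, so both interpretations can
be produced (fit SEs from one curve; SDs across seeded replicates).

`selectDoseModel` prefers the two-component fit only when AICc improves
by >= 2 *and* the minor weight is >= 0.15 *and* the K ratio is >= 2 --
conservative gates, all configurable. The AICc uses the binomial
log-likelihood of the fused counts with the total number of granules as
the effective sample size; an AICc computed on the eight grouped means
would penalise the five-parameter model out of existence by construction,
regardless of the data. `compareScenarios` classifies components as
high/low affinity around a 25 uM boundary (the geometric midpoint of the
calibrated K pairs) and reports which class a scenario lost relative to
the reference.

# FCS sizing

`fcsModel` implements the three-dimensional one-state diffusion model
with multiplicative blinking and (optionally) triplet corrections:

$$G(\tau) = 1 + \frac{\sum_i f_i n_i^2 X_i(\tau)}{(\sum_i f_i n_i)^2}
\left(1 + \frac{T_b e^{-\tau/\tau_b}}{1 - T_b}\right)
\left[1 + \frac{T_t e^{-\tau/\tau_t}}{1 - T_t}\right],$$

$$X_i(\tau) = \frac{1}{1+\tau/\tau_{d,i}}
\frac{1}{\sqrt{1 + (\tau/\tau_{d,i})(\omega_r/\omega_z)^2}}.$$

Conventions adopted where the printed form is ambiguous: occupancies
$f_i$ are mean particle numbers, so the single-species amplitude is
$1/N$ (the printed form carries no explicit $1/N$); the photophysical
exponents are decaying, $e^{-\tau/\tau_b}$; the sum formally runs over up
to three diffusing components but the default fit uses one ("one-state"),
with brightness fixed at 1 because it cancels for a single component.
Triplet relaxation is initialised faster than blinking
($\tau_t < \tau_b$). `selectFcsModel` adds the triplet term only when it
improves AICc by >= 2 (Gaussian AICc over the lag grid).

Diffusion times convert to sizes via $D = \omega_r^2 / (4\tau_d)$, the
Vogel viscosity equation $\eta(T) = e^{A + B/(C+T)}$ with the water
parameters $A=-3.72$, $B=578.919$ K, $C=-137.546$ K ($T$ in Kelvin --
the parameters only reproduce water viscosity on the Kelvin scale;
$\eta(298.15\,K) = 0.891$ mPa s), and the Stokes-Einstein relation
$R_h = k T / (6\pi\eta(T) D)$. Each run is converted at its own recorded
temperature before averaging (`aggregateRh`), which is what corrects for
run-to-run viscosity differences.

The confocal volume is calibrated on a reference-dye curve
(`calibrateFocus`), fitting the structure parameter and diffusion time
and setting $\omega_r = \sqrt{4 D_{\mathrm{ref}} \tau_d}$. The Rhodamine
B reference coefficient is taken as $4.50\times10^{-10}$ m$^2$/s at
25 C. A printed value of $4.50\times10^{-5}$ cm$^2$/s appears in the
calibration literature trail but is dimensionally implausible for a
~0.5 nm dye (it would imply $R_h \approx 0.05$ nm); we treat it as a
units typo for $10^{-6}$ cm$^2$/s = $10^{-10}$ m$^2$/s and expose
`dRef` so either convention can be selected.

# Diameter mixtures

`fitDiameterMixture` is a 1D Gaussian-mixture EM with seeded restarts
(quantile split, k-means, random draws), per-iteration log-likelihood
tracking (monotone by construction, asserted in tests), and degenerate
restarts discarded. For $k=1$ it reports the plain sample mean/SD.

A two-component fit is flagged **non-separable** when the fitted means
are within one pooled SD or either weight is below 0.1. This matters for
the study calibration itself: the 175/215 nm mixture is separated by only
~0.9 pooled SD, and at n = 2000 the maximum-likelihood component means
scatter by tens of nm across seeds -- the subpopulation means are not
identifiable from the pooled diameter distribution alone, which is
consistent with pooled size data being reported as a single mean +/- SD.
Tests assert 5 nm recovery only on genuinely separated mixtures and
assert the scatter (not a point value) for the calibration mixture.

# Lipidomics and depletion statistics

Peak areas are normalised per sample by the internal-standard area and
protein mass. The volcano computes the log2 ratio of group means
(syt9/syt7) and a two-tailed Welch t-test per species, by default on the
log2-transformed normalised values (the procedure log2-transforms
everything else, and peak-area noise is multiplicative; Welch on the raw
scale is available via `logValues = FALSE`). P-values are reported as
-log2(p) so the p = 0.05 line sits at 4.32; no multiple-testing
correction is applied by default, matching the per-species p < 0.05
rule, with Benjamini-Hochberg as an option.

One statistical caveat is documented deliberately: with ~100 detected
species, a per-species 5% test is expected to flag about five null
species per experiment, so "exactly one significant species" is not a
reproducible outcome of the stated generative conditions under any
per-species rule -- and even FDR correction leaves a ~5-10% chance of a
null co-discovery. The synthetic 3-fold SM 42:1 enrichment is, however,
always the strongest signal (minimum p) and its fold change is recovered
accurately; the corresponding acceptance check asserts the literal
single-hit criterion and is expected to fail, by design rather than by
defect.

Depletion fractions follow the subtraction rule
fraction_syt7 = (control - dep7)/control, clipped to [0, 1] and
renormalised to sum to 1 per protein, with raw values retained for QC
(whether the original bar charts renormalised is not stated; we emit
both). Secretion normalisations: percent-of-total
(100 x secreted/(secreted+lysate)), protein- and
reference-condition-relative secretion, and the calcium-imaging
(F - F0)/(Fcontrol - F0) normalisation.

# Orchestration and reproducibility

`runScenarioPipeline` runs the enabled stages for one scenario from a
validated configuration (`validateRunConfig`, YAML or list; all
violations reported together) and returns a report carrying the package
version and an MD5 hash of the canonical JSON serialisation of the
configuration. All generators are bit-reproducible given (config, seed):
the same configuration and seed produce an identical report. Default
problem sizes (300 granules/level, 2000 diameters, 3 x 20 FCS curves,
4 lipid replicates) match the acceptance analyses; the TIRF stage
defaults to a 96 x 96 x 160 stack with 24 granules and is off by default
in the composite run because the tabular stages already cover the
scenario-level questions.

There is no shell entry point: the package is an analysis library; the
exported functions, the configuration file format and this vignette are
the interface.

# Known limitations

* Slow-mode onset frames carry a few frames of intrinsic uncertainty
  (see above); delta-I_C and duration estimates are much less sensitive
  to this than onset itself.
* The untreated diameter mixture is not component-identifiable at
  realistic sample sizes; consult `isSeparable()` before interpreting
  component means.
* The two-step trace model aligns events to the frame grid; sub-frame
  kinetics, bleaching and fusion-pore flickering are not modelled.
* Dose-response decomposition assumes a shared Hill coefficient across
  components by default; strongly differing cooperativities between
  sensors would require more dose levels than the default ladder.
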