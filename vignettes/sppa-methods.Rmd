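---
title: "Classifying fossil bedding-plane communities as niche- or neutral-structured"
author: "sppa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fossil bedding-plane communities as niche- or neutral-structured}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sppa)
```

## The scientific question

Sessile Ediacaran macro-organisms are preserved on bedding planes as
near-complete census snapshots of living communities: every individual of a
buried generation is a point with a taxon label and planar coordinates in
metres. Because these organisms could not move, the spatial arrangement of
each taxon — and of each pair of taxa — is a record of the processes that
assembled the community. Spatial point process analysis (SPPA) turns that
record into a verdict:

* **Neutral processes.** Complete spatial randomness (CSR) means no
  detectable intrinsic or extrinsic structuring. Aggregation that follows a
  Thomas cluster process (TC), or a nested double cluster (DTC), is the
  signature of dispersal limitation — propagules settling near parents
  regardless of habitat — which is also neutral.
* **Niche processes.** Aggregation explained by a heterogeneous Poisson
  model (HP) indicates habitat association; a Thomas process thinned by a
  habitat surface (inhomogeneous Thomas, ITC) indicates dispersal limitation
  plus habitat filtering; spatial segregation indicates density-dependent
  competition. Non-independent bivariate (taxon-pair) structure —
  aggregation or segregation between taxa — likewise indicates niche
  processes (facilitation, shared habitat, or competition).

The package implements the full chain: summary-function estimation,
null-model simulation with Monte-Carlo envelopes, cluster-model fitting by
minimal contrast, bivariate independence testing by toroidal shift,
taphonomic bias screening and correction, the model-to-process mapping, and
a ground-truthed synthetic community generator that makes the whole chain
testable without access to the original fossil maps.

## Summary functions

The workhorse is the pair correlation function (PCF) `g(r)`: the density of
point pairs at separation `r`, normalised by intensity so that `g = 1` under
CSR, `g > 1` indicates aggregation and `g < 1` segregation. Estimation
conventions, all exposed through `distance_grid()`:

* **Bandwidth.** A box kernel of full width `h` on a grid of centres
  `(k - 1/2) h`. The default `h` = 0.1 m suits metre-scale surfaces; 0.01 m
  is appropriate for sub-square-metre surfaces. `g` is undefined below
  `h/2` and reported as missing there, never as 0.
* **Smoothing.** A centred moving average over `smoothing_span` grid steps
  (default 3; 5 for very small dense surfaces) applied to the PCF only.
* **Edge correction.** Translation correction (each pair weighted by
  `1/|W ∩ W_v|`) for `g` and Ripley's `K`; border (reduced-sample)
  correction for the nearest-neighbour distribution `D(r)`, which is made
  monotone with a running maximum. With the pair intensity estimated by
  `n(n-1)/|W|^2`, the CSR expectation of `g` is exactly 1 at every `r`.
* **Range.** Distances up to 2.5 m by default — beyond about a quarter of
  the window diameter the estimator warns, since census surfaces do not
  support larger-scale inference. The fitting ladder and the pipeline cap
  the analysed range at that quarter-diameter automatically, so
  sub-square-metre surfaces are analysed on a correspondingly short grid
  rather than on noise.

`estimate_L()` (variance-stabilised `K`, equal to `r` under CSR),
`estimate_oring()` (`O(r) = λ g(r)`) and `estimate_nn()` complete the set;
`estimate_pcf_bivariate()` is the symmetric cross-pair version. Axis-aligned
rectangular windows take an exact compiled fast path; convex polygon windows
(e.g. retrodeformed rectangles) use exact polygon-clipping geometry in R.
All estimators are checked against independent double-loop implementations
to 1e-10 in the test suite.

```{r pcf-example}
w <- owin_rect(c(0, 10), c(0, 10))
p <- simulate_thomas(thomas_params(sigma = 0.1, rho = 1, lambda_total = 10),
                     w, seed = 1)
g <- estimate_pcf(p, w, distance_grid(0.1, 2.5, 3))
plot(g)
```

## Null models, envelopes, goodness of fit

CSR is simulated conditionally on the observed count (uniform points); the
heterogeneous Poisson null uses an intensity surface, by default the
moving-window estimate of the same taxon's density: counts in a disc of
radius `R` divided by the disc area clipped to the window. Envelopes take
the rank-`k` smallest and largest of `n_sims` simulated curves at each
distance — 999 simulations with rank 50 marks off the 5% highest and lowest
simulations (tests and examples use a documented reduced-replicate mode,
199 simulations with rank 10).

Because the envelopes are pointwise, they are interpreted jointly with
Diggle's goodness-of-fit test (`diggle_gof()`): each curve's deviation
`u = Σ_r (curve(r) − leave-one-out mean)^2` is ranked among the simulated
deviations, giving `p_d = (#{u_sim ≥ u_obs} + 1)/(n_sims + 1)`; `p_d` near 1
is a good fit and the smallest attainable value is `1/(n_sims + 1)`. Under a
true null `p_d` is uniform, which the test suite verifies.

**Excursion length.** The moving average correlates runs of up to
`smoothing_span` adjacent grid bins, so a one-bin fluctuation appears as a
2-3 bin excursion by construction. An acceptable fit therefore tolerates
excursions up to `smoothing_span` grid steps (config-exposed as
`max_excursion_steps`); measured on CSR-true patterns (n = 300, 199
simulations) this rule accepts 90%, whereas tolerating only one grid step
accepts 58%, far below the test's nominal level. Narrower bivariate
associations are still caught by the goodness-of-fit clause (below).

## Cluster models and minimal contrast

The Thomas process (Poisson parents of density `ρ`, Poisson(`μ`) offspring
displaced by an isotropic Gaussian of sd `σ` per axis) has the closed form

&nbsp;&nbsp;`g(r) = 1 + exp(−r² / 4σ²) / (4π σ² ρ)`,

and the nested double-cluster variant adds a second exponential at the
combined scale `sqrt(σ₁² + σ₂²)`. `fit_minimal_contrast()` minimises the
summed squared discrepancy between observed and model curves over the
contiguous range where the observed PCF exceeds 1 (the aggregation signal,
not fluctuations around the CSR line), excluding distances below
`r_exclusion` = 0.02 m, which reflect finite specimen size rather than
ecology. Numerical choices:

* The PCF enters the contrast directly, with the model curve passed through
  the **same moving average** as the estimate — without this the fitted
  cluster radius is biased upward by ~25% at n ≈ 1000; with it the bias is
  within a few percent.
* The `L`-basis contrast uses the fourth-root transform of `K`
  (conventional variance stabilisation).
* With `fit_basis = "PCF+L"` both contrasts are summed with equal weight;
  the total intensity is fixed at the observed value so only `(σ, ρ)` (plus
  the nested scale for DTC) are free. Optimisation is Nelder-Mead on log
  parameters from several starts, inside a physical box (cluster radii
  between bandwidth/50 and four times the maximum analysed distance).
* Degenerate inputs: a PCF at or below 1 everywhere raises a typed
  "no aggregation" error; simulation guards refuse parameter combinations
  implying more than 5 million points.

Thinning invariance matters for the inhomogeneous variant: thinning a
Thomas process by a fixed surface leaves its PCF's cluster term unchanged
(it depends only on the parent density), so compensating the thinning loss
must inflate the offspring mean, never the parent density.

## The fitting ladder

`fit_protocol()` automates the published decision sequence:

1. **CSR** against the null envelope and `p_d` on both the PCF and
   nearest-neighbour bases. Patterns that only fall below the envelope are
   **segregated** (niche).
2. **HP** on the moving-window background of the same taxon. The radius is
   fixed at `R` = 0.5 m by default: selecting `R` by goodness of fit is
   degenerate, because a moving window at the analysis bandwidth reproduces
   any clustering and would absorb the very signal the ladder is trying to
   classify (a grid search over 0.1-1 m remains available via
   `hp_R = NULL`). The HP rung is gated by the PCF-basis `p_d` and the
   excursion rule only: the background is a plug-in estimate that
   re-absorbs sampling noise at scales below `R`, which makes the NN-basis
   test reject true heterogeneous-Poisson patterns at 3-8 times the nominal
   rate (the NN `p_d` is still computed and reported).
3. **TC** by minimal contrast, with the fit basis switching from PCF+L to
   PCF only to L only when the goodness of fit of the joint basis is poor
   (`refit_pd`, default 0.1) — a deterministic stand-in for the published
   visual-inspection step.
4. **DTC** when the single-cluster fit leaves a second aggregation scale:
   TC `p_d` below `dtc_residual_pd` (0.2) and a contiguous excursion above
   the TC envelope.
5. **ITC**: cluster parameters re-fitted to the background-adjusted PCF
   (observed `g` divided by the mean simulated PCF of the HP rung, which
   estimates the background factor — independent thinning multiplies the
   PCF), then simulated as a thinned Thomas process on the same background.
6. The first rung meeting the acceptance rule wins; if none does, the
   candidate with the best joint `p_d` is reported. Every candidate's
   `p_d` values are retained in a per-taxon table.

The ladder never reports a cluster model without an upward excursion from
the CSR envelope. Measured self-classification at the reduced simulation
budget (199 simulations, 10 × 10 m windows): CSR truth at n = 300 is
recovered ~94%, Thomas truth (σ = 0.1 m, μ = 10, n ≈ 1000) ~95%,
gradient heterogeneous-Poisson truth at n = 500 ~93%, inhomogeneous-cluster
truth ~87% — the acceptance suite re-runs these calibrations.

## Bivariate independence

`toroidal_shift_test()` fixes one pattern and translates the other in its
entirety with wrap-around on a rectangular sub-window (maps on non-
rectangular windows are first clipped with `extract_rect_subwindow()`; the
pipeline uses the largest inscribed rectangle found by grid search). The
wrap is measure-preserving, so each marginal's structure is exactly
retained — the test suite asserts that the multiset of toroidal pairwise
distances is invariant. Non-independence is declared when the rank
goodness-of-fit test rejects at 5% *and* the observed cross-PCF leaves the
pointwise envelope: the goodness-of-fit statistic carries the calibrated
significance, the excursions localize and sign the effect. (Either
component alone is a roughly 5% test and the two are nearly independent
under the null, so declaring on either would double the level; raw
pointwise excursions over 25 correlated bins would flag about half of all
truly independent pairs. The conjunction's measured false-positive rate on
independent pairs is 5-6%.)

Effect sizes follow the convention `density_change_pct = 100 × (extreme
observed g − 1)` over the significant ranges: a significant peak of
`g = 1.5` is a +50% density increase, a significant trough of `g = 0.61` a
−39% reduction. This reading of published percentage figures is a design
choice of this package; the underlying envelope and curve are always
available for alternative summaries.

## Taphonomic bias

Two forward distortions are modelled, and both have inverses or screens:

* **Tectonic strain.** Originally circular holdfast discs are preserved as
  ellipses. `estimate_strain()` takes the median long/short axis ratio and
  the ellipticity-weighted axial circular mean orientation;
  `retrodeform()` applies the inverse pure shear. The default is
  area-preserving (axes scaled by `sqrt(ratio)` and `1/sqrt(ratio)`), the
  structural-geology convention that leaves specimen densities unchanged; a
  uniaxial variant is available. `apply_tectonic_strain()` is the exact
  forward model, and the round trip is identity to 1e-9 m.
* **Differential erosion.** `fit_erosion_models()` fits inhomogeneous-
  Poisson models with log-linear intensity `exp(a + b·z)` for z = x (along
  strike), y (along dip) and distance to an anchor (e.g. nearest the modern
  shoreline), against a homogeneous baseline, by profile maximum likelihood
  (the covariate integrals are closed-form on rectangles, Gauss-Legendre
  quadrature otherwise). The log link guarantees positivity with two
  parameters per covariate. A heterogeneous model is adopted when it beats
  the homogeneous AIC by more than 2; the adopted surface becomes the null
  background for that surface's spatial analyses
  (`apply_bias_surface()`). The likelihood-ratio screen is calibrated: on
  CSR truth the gradient model's deviance is chi-squared(1) to good
  approximation.

## Synthetic communities

`generate_community()` draws each taxon from its named process, attaches
lognormal sizes (decorative for the point analyses, but they feed the
strain estimator), merges taxa into a `bed_map`, then applies strain and
erosion thinning in that order, recording every parameter and per-specimen
survival as ground truth. `scenario_bank()` ships five specifications
spanning the realistic census ranges — window areas from 0.81 to 115 m²,
total densities from ~3 to ~120 per m², per-taxon abundances from 18 to
over 1100, all five generating processes, one strained surface and two
eroded ones — so tests never invent geometry ad hoc. The same specifications
are shipped as YAML under `inst/extdata/scenarios/`.

What the generator does *not* emulate: specimen footprints (points can lie
arbitrarily close; real fronds exclude each other below ~2 cm — the
`r_exclusion` default exists precisely because of this), taphonomic
mis-identification, multi-generation succession, and anisotropic dispersal.
Passing calibration on synthetic data therefore demonstrates the
statistical machinery, not the palaeobiology; on real surfaces the
small-scale exclusion and the abundance filter do the corresponding work.

## Problem sizes and reproducibility

Production analyses use 999 simulations (rank 50). The test and acceptance
suites use the documented reduced-replicate mode — 199 simulations with
rank 10, windows of 10-20 m side, 25-100 replicates per calibration — which
keeps every calibration property estimable with modest Monte-Carlo error.
All stochastic entry points accept a `seed` and restore the caller's RNG
stream; `run_pipeline()` derives per-surface and per-taxon child seeds from
one master seed, so identical configurations produce byte-identical
reports.

## Known limitations

* First- versus second-order structure is not identifiable from one
  realization; the ladder resolves it by testing order and a fixed
  moving-window radius, as in the published protocol. Patterns whose
  clustering scale approaches the window size can be assigned HP rather
  than TC (or vice versa).
* Pointwise envelopes with a length rule are a calibrated heuristic, not a
  global test; global (studentised) envelope tests are deliberately out of
  scope, as they are not the published method.
* The nearest-neighbour basis is anticonservative for plug-in
  heterogeneous backgrounds (see the ladder section); its `p_d` is reported
  for completeness.
* `largest_inscribed_rect()` is a grid search (default resolution 0.1 m),
  adequate for gently-deformed census windows, not for pathological
  polygons.
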