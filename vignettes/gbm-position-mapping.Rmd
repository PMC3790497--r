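---
title: "Methods: axial position mapping of GBM epitopes from STORM localizations"
author: "gbmstorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axial position mapping of GBM epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `gbmstorm`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices that shape edge-case behaviour. It states no empirical result
beyond what the package's own tests and scripts compute.

## The measurement model

A two-channel STORM experiment on kidney sections yields a table of
single-molecule localizations: positions $(x, y)$ in nm with channel,
frame and photon metadata. The glomerular basement membrane (GBM) runs
as a thin band through these data, and each labeled epitope occupies one
or two layers at characteristic signed depths — the axial coordinate,
which this package fixes globally as *positive toward the podocyte
side*.

For an analysis window (a `gbm_region`: centre $c$, unit normal $n$
toward the podocyte side, width $w$ along the membrane, depth $d$ across
it) the axial coordinate of a localization $p$ is $a = (p - c) \cdot n$,
and the window keeps points with tangential coordinate in $[-w/2, w/2)$
and $a \in [-d/2, d/2)$. Half-open upper bounds make adjacent windows
disjoint, so projection plus accumulation can never count a localization
twice.

Per window and channel the axial positions are binned (default 10-nm
bins, bin *centres* at integer multiples of the width so that zero is
always a bin centre) and fitted by least squares with either

$$f_1(a) = A\,e^{-(a-\mu)^2/2\sigma^2} + b$$

for unimodal epitopes or

$$f_2(a) = A_1\,e^{-(a-\mu_1)^2/2\sigma_1^2} +
           A_2\,e^{-(a-\mu_2)^2/2\sigma_2^2} + b$$

for the two-layer (bimodal) case, components ordered $\mu_1 < \mu_2$.
The reference channel (agrinC in mouse, integrin β1 in human) is always
bimodal; its midpoint $(\mu_1+\mu_2)/2$ defines the zero of that
window's *reference frame*, and $\mu_2 - \mu_1$ is its *peak-to-peak
distance*. Target positions read off in this frame are pooled across
windows into the position estimate: mean, SD, and $\mathrm{SEM} =
\mathrm{SD}/\sqrt{n}$.

Binned unweighted least squares was chosen because the per-bin counts in
a usable window (hundreds of localizations over ~20 occupied bins) are
large enough that Poisson heteroscedasticity has negligible effect on
the fitted centres; results are required (and tested) to be stable
across 5–20 nm bins.

## Acceptance gates

Windows without a usable two-layer reference structure must be excluded,
and the exclusion must be mechanical. A double-Gaussian fit is accepted
only if all of the following hold (all thresholds are arguments of
`fit_double_gaussian1d()` and are logged per region):

* at least 40 localizations (20 for single fits), otherwise no fit;
* convergence of the Levenberg–Marquardt optimiser;
* separation $\mu_2 - \mu_1 \ge$ 40 nm;
* **resolvability**: $\mu_2 - \mu_1 \ge 1.5\,(\sigma_1 + \sigma_2)$.
  Least squares happily splits a single broad mode into two strongly
  overlapping components; for a pure Gaussian that degenerate split
  lands near $1.3\,(\sigma_1+\sigma_2)$, while genuine two-layer GBM
  profiles sit above $2$. The factor 1.5 separates the two regimes
  without touching any realistic two-layer geometry;
* amplitude balance: each component carries ≥ 10 % of the total
  component area $A_1\sigma_1 + A_2\sigma_2$.

Single-Gaussian fits are accepted when the fitted SD lies in
$[5, d/2]$ nm. Rejection is always a flag, never an error, so the
mapping loop can tally exclusions; a run in which *no* window passes is
an error naming the failing stage.

## The synthetic-data generator

`simulate_two_channel_dataset()` draws localization clouds on circular
capillary loops (default midline radius 2000 nm). For an epitope layer
at offset $o$ with in-layer spread $\sigma_\ell$ and localization error
$\sigma_e$, each point gets an angle uniform on its arc and a radius

$$r = r_{\mathrm{mid}} + o + \mathcal N(0, \sigma_\ell^2)
      + \mathcal N(0, \sigma_e^2),$$

with counts Poisson-distributed so that the expected number per layer
inside one 800-nm window equals the layer density. The podocyte side is
the *outside* of the loop. Defaults for recovery experiments:
$\sigma_\ell = 20$ nm, $\sigma_e = 15$ nm, 500 localizations per layer
per window. A loop of radius $r$ holds $\lfloor 2\pi r / w \rfloor$
disjoint windows (15 at the defaults), so datasets needing more windows
tile additional loops side by side — mirroring how real studies iterate
over many capillary loops and glomeruli.

The generator's epitope maps (`gbm_epitope_map()`) place layers at
published mouse and human GBM positions; these are the ground truths the
pipeline must recover. Blinking movies (`simulate_frame_stack()`) render
any molecule set as per-frame Bernoulli on-events with Poisson photons
and a pixel-integrated Gaussian PSF, which exercises the localizer end
to end.

What the generator deliberately does **not** emulate: dye photophysics
beyond per-frame Bernoulli blinking (duty-cycle distributions,
photobleaching), activator cross-talk between channels, mesangial
regions (simulated loops are clean circles, so region selection may use
the full circumference), sectioning artefacts, and the human
podocyte/endothelial labeling asymmetry. Passing recovery tests
therefore demonstrate that the *estimator* is unbiased and correctly
calibrated under the stated noise model — not that real tissue meets
that model.

## Geometry and the curvature choice

At the default loop radius the 800-nm window is strongly curved: the arc
sagitta is $\approx w^2/(8r) = 40$ nm, comparable to the layer spread. A
strictly flat projection $a = (p-c)\cdot n$ smears each layer toward the
loop centre and biases the mean recovered peak-to-peak distance upward
by just under 1 nm — small in absolute terms, but larger than the SEM at
hundreds of windows. `gbm_region` therefore carries an optional
`curvature` field: when the host loop geometry is known (always true for
simulated regions, where `select_regions()` fills it in), the axial
coordinate is measured radially from the loop circle and the tangential
coordinate as arc length, which removes the $O(w^2/r)$ distortion
exactly and reduces to the flat formulas as curvature goes to zero.
Manual regions default to the flat projection — the right choice when
the geometry is unknown, and a sub-nanometre effect at the gentler
curvatures of real capillaries; the test suite covers both paths,
including a flat-membrane variant of the pipeline.

## The localizer

`fit_elliptical_gaussian()` fits an axis-aligned elliptical Gaussian
$A\exp(-(x-x_0)^2/2\sigma_x^2 - (y-y_0)^2/2\sigma_y^2) + b$ to pixel
patches (≥ 7×7) by Levenberg–Marquardt with inverse-variance (Poisson)
weights $1/\max(z, 1)$. The weighting matters: unweighted least squares
inflates the localization SD by $\approx\sqrt{16/9}$ over the
shot-noise bound, and the test suite asserts the precision law
$\sigma_{x_0} \approx \sqrt{\sigma_{\mathrm{PSF}}^2 + a^2/12}\,/\sqrt{N}$
(pixel size $a$, photon count $N$) within 30 % across a decade of
photon counts. Width bounds are $[0.3, 4]$ px; non-convergence is a
flag, and photons are estimated by the analytic Gaussian integral
$2\pi A \sigma_x\sigma_y / (g\,a^2)$ at gain $g$. Peak candidates are
8-neighbour local maxima above an absolute threshold,
non-maximum-suppressed in order of decreasing brightness with ties
broken by (row, column) so that detection is fully deterministic.

## The Alport-style disruption mode

`apply_disruption()` replaces, on a randomly placed contiguous arc
covering a chosen fraction of a loop, all layered structure by a single
diffuse layer at the midline (default SD 60 nm, total density preserved)
— a deliberately minimal model of the segmental breakdown of the
two-layer pattern seen in collagen-IV-deficient GBM. The disruption is
exercised only through the bimodal acceptance gate: fully intact loops
pass in essentially every window, fully disrupted loops in none, and
partially disrupted loops in proportion to the intact arc, with windows
straddling a boundary falling either way. No quantitative "disruption
statistic" is defined beyond this gate behaviour.

## Numerical choices and edge cases

* **Histograms** anchor bin centres at multiples of the bin width, so a
  symmetric profile about zero stays symmetric after binning and spike
  data at exact positions (e.g. ±50 nm with 1-nm bins) fit back to those
  positions.
* **Initialisation**: single fits start from the histogram's weighted
  mean/SD; double fits split the positions at their median and start
  each component from its half's moments. Component SDs are bounded
  below by a quarter bin to keep spike fits finite, above by the window
  depth.
* **Convergence**: `nls.lm` with `ftol = ptol = 1e-10`, 200 iterations;
  the fit oracle tests compare the optimum against an independent
  brute-force grid search (means on a 1-nm grid, SDs on a 5-nm grid,
  amplitudes solved linearly).
* **Determinism**: the mapping pipeline contains no randomness; all
  randomness enters through simulation seeds, and every stage seed is
  derived from one master seed, so identical configurations reproduce
  outputs byte for byte.
* **Degenerate inputs**: empty windows yield flagged empty profiles;
  empty channel selections in rendering yield a flagged empty grid; an
  all-rejected reference stage raises an error naming the stage.

## Problem sizes

The recovery experiments use the region counts of the corresponding
published experiments (80 and 604 windows for the mouse agrinC
peak-to-peak, 60 windows per mapped epitope, 60 human windows at 1200 nm
depth) at the default densities — about $5\times10^5$ localizations for
the largest dataset, a few seconds per experiment. Property tests use
6–30 windows and 80–150 Monte-Carlo repetitions per photon level, sizes
at which the asserted tolerances (e.g. the 30 % precision-law band) are
comfortably resolved.

## Known limitations

* The axial model is 1-D per window; no 3-D (z) localization.
* Bimodal targets are fitted jointly; a split-at-zero alternative is a
  config point but the joint fit is the tested default.
* The simulator's per-window localization densities and in-layer spreads
  are calibrated to give realistic per-window fit scatter, not to match
  absolute counts of any particular instrument.
* Acceptance-gate thresholds (minimum separation, resolvability factor,
  amplitude balance) are package defaults chosen on simulated data;
  real-tissue profiles with strong baselines may need different gates,
  which is why every gate is an explicit argument and every exclusion is
  logged.
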