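---
title: "Staining kinetics for contrast-enhanced CT of ligaments and tendons"
author: "StainKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staining kinetics for contrast-enhanced CT of ligaments and tendons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StainKinetics)
```

## The problem

Ligaments and tendons attenuate X-rays weakly, so micro-CT of their
fascicle-scale structure needs a heavy-element contrast agent — typically
iodine potassium iodide (I2KI), phosphotungstic acid (PTA) or
phosphomolybdic acid (PMA). The agent diffuses in from the surface over
days. Under-staining leaves a dim core; over-staining shrinks and deforms
the tissue. The practical question this package answers is: *given a stain
and a sample radius, how long should the sample be immersed?*

The raw material is a time series of reconstructed transverse slices, one
scan per staining day, with a known pixel size (the geometry targeted here
is 7.5 µm/pixel and five daily scans, day 0 unstained). All quantitative
measurements are made on one-dimensional line profiles through the slice
centre; the samples are near-cylindrical, so a profile crosses
background–edge–core–edge–background.

## Models

Two qualitatively different staining behaviours are modelled.

**Bulk saturating staining (I2KI-like).** Intensity at a fixed depth rises
with staining time $t$ as

$$I(t) = I_0 + (I_{max} - I_0)\left(1 - e^{-kt}\right),$$

where $I_0$ is the unstained intensity, $I_{max}$ the asymptote and $k$
(1/days) reflects the local diffusion rate. `fitSaturation()` fits this
per depth increment. *Sign convention:* the exponent is $-kt$. A positive
exponent produces a divergent curve that cannot rise from $I_0$ to a
finite $I_{max}$; with the negative exponent the published constants for
this model reproduce their own reported "fraction of $I_{max}$ reached by
day 4" column (99/87/98% for I2KI/PTA/PMA), which is the consistency check
`test-acceptance.R` encodes.

Inverting the fit gives the time to reach a saturation level $f$
(interpreted as a fraction of the *absolute* maximum $f\,I_{max}$, not of
the span $I_{max}-I_0$):

$$t_{sat}(f) = -\tfrac{1}{k}\ln\!\Big(1 - \tfrac{f I_{max} - I_0}{I_{max} - I_0}\Big).$$

Collecting $t_{sat}$ across depths $x$ and fitting

$$t_{stain}(x) = A e^{c x}$$

(`fitStainingTimeModel()`, nonlinear least squares on the linear scale,
initialised from the log-linear regression) yields the staining-time
lookup used by `predictStainingTime()`. Fitting on the linear scale is a
deliberate choice — the published plots are semi-logarithmic, but the
measurement error lives on the time axis, not its log; the log-scale
variant is available by fitting `lm(log(t) ~ x)` directly.

**Sharp-front staining (PTA/PMA-like).** These stains advance as a steep
front whose depth saturates:

$$x(t) = C\left(1 - e^{-Kt}\right),$$

with $C$ (mm) the asymptotic penetration depth — an upper limit on the
sample radius that can ever be stained through — and $K$ (1/days) the
approach rate. `fitFrontModel()` fits this to per-day detected front
depths; `maxPenetrationDepth()` returns $C$.

## Detectors

All detectors operate on the cohort-normalised, Gaussian-filtered profile.

* **Normalisation** (`normaliseCohort()`): every profile in the study is
  divided by the single maximum recorded across *all* profiles (all
  samples, stains and days jointly — the alternative per-stain
  normalisation is a one-liner but is not the default, since cross-stain
  intensity comparisons are part of the analysis).
* **Smoothing** (`smoothProfile()`): discrete Gaussian, σ = 4 px, kernel
  truncated at 4σ and renormalised; boundary handling is edge replication
  (chosen so a constant profile is a fixed point; the data near profile
  ends is background, where replication is exact).
* **Edge detection** (`detectSampleEdges()`): the global maximum of the
  intensity gradient marks the climb into the sample; the edge is the next
  point toward the sample centre where $|$gradient$|$ < 0.01. The opposite
  edge mirrors this from the global minimum.
* **Front detection** (`detectStainFront()`): walking inward from a
  detected edge, the first point with gradient < −0.2 (along the inward
  direction) marks the descent behind the front; the next
  near-zero-gradient point is the front edge; its distance from the sample
  edge is the front depth. If no point passes the −0.2 drop the sample is
  bulk-stained (or unstained) and the result is flagged `found = FALSE` —
  recorded as *missing*, never as zero, so downstream fits skip it.

Two numerical choices deserve emphasis:

* **Threshold units.** The thresholds 0.01 and 0.2 are applied to the
  gradient of the normalised profile *per millimetre*. Read per pixel at
  7.5 µm spacing, a drop of −0.2/px would require the profile to fall by
  1.5 normalised units within 56 µm — impossible for values in [0, 1] once
  filtered, so the per-pixel reading would make the front criterion
  unreachable. Both tolerances are arguments, so other unit conventions
  are available.
* **"Approximately zero" on clean data.** On noise-free synthetic
  profiles the filtered gradient can step across the entire ±0.01 band
  between adjacent samples (it decays by ~e⁻¹ per pixel at 4σ from an
  edge). The walk therefore also accepts a *sign change* between
  consecutive samples as "approximately zero", taking the sample nearer
  zero. On noisy real-scale data the magnitude test fires first and the
  clause is inert.

Depth-resolved intensities (`toDepthSeries()`) are read at 0.1 mm
increments inward from each detected edge after 0.1 mm neighbourhood
averaging, and the two sides are averaged; depths beyond a day's
half-width are missing (the sample shrinks). Because the detected edge
sits slightly inside the true boundary (it is the *settled* point of the
gradient, a few σ inward), all depths share a small constant offset; this
scales $A$ but cannot bias the exponent $c$, which is the quantity the
pipeline is validated on.

## The synthetic phantom

No scan data ships with the package; every stage is validated against a
disc phantom (`PhantomSpec()`, `generatePhantomSlice()`) with closed-form
truth:

* a disc of radius $R(t) = R_0(1 - s(1 - e^{-\lambda t}))$ centred in the
  image — uniform radial shrinkage approaching a plateau, matching the
  observation that most shrinkage happens during the first day
  (default $\lambda = 2$/day puts 86% of the plateau shrinkage in day 1);
* *saturating mode*: $I(x,t)$ as above with depth-dependent rate
  $k(x) = k_0 e^{-c_k x}$ — by construction the time to any fixed
  saturation level scales as $e^{c_k x}$, which is exactly what makes the
  staining-time exponent recoverable end to end;
* *front mode*: intensity `IOut` outside the front depth
  $d(t) = C(1-e^{-Kt})$, `IIn` inside, joined by a linear ramp of width
  $w$ (the front shape is not constrained by any data; a ramp makes the
  detector tolerance stateable in units of $w$);
* additive Gaussian pixel noise (σ in normalised units, clipped to
  [0, 1]), reproducible from the spec seed.

Phantom defaults state the world the validation runs in: $R_0 = 3$ mm at
7.5 µm/px, five daily timepoints, background 0.02, noise σ = 0.01
(measured profiles are ~10-pixel averages of ~16-bit data, so per-pixel
noise of a few percent is realistic), saturating kinetics
$I_0 = 0.1, I_{max} = 0.6, k_0 = 1/\text{day}, c_k = 0.3/\text{mm}$, front
kinetics $C = 3$ mm, $K = 0.5$/day, $w = 0.3$ mm. The phantom emulates
*geometry and kinetics only*: no beam hardening, streaks, rings, partial
volume, texture, or inhomogeneous (bending) deformation. A green
recovery test therefore establishes that the detectors and fits are
mutually consistent and unbiased under the stated kinetics — not that
they are robust to reconstruction artefacts.

## What the validation suite establishes

* The shipped reference constants reproduce their published worked
  examples (staining times 1.6 d at 1.5 mm and 2.6 d at 3 mm for 90%
  saturation; day-4 saturation fractions 99/87/98%; penetration limits
  3.1 mm PTA and 2.1 mm PMA).
* End to end on noise-free phantoms, the pipeline recovers the
  staining-time exponent $c$ within 5% and the front parameters $C$
  within one ramp width and $K$ within 10%.
* Under Gaussian noise σ = 0.01 over 200 replicates, the median relative
  error of $k$ stays below 10% and the linearised 95% confidence
  intervals cover the truth at least 90% of the time.
* Smoothing, gradient, neighbourhood averaging, ANOVA sums of squares and
  Tukey studentized-range statistics match independent brute-force
  implementations to 1e−8.
* Measured normalised areas track $(R(t)/R_0)^2$ within 3% at σ ≤ 0.02,
  and the ANOVA holds its nominal 5% type-I error within [0.03, 0.07].

## Degenerate inputs and edge cases

* Flat profiles raise a *no-edge* error; crossed edges a
  *detection-failed* error.
* A front at or beyond the sample centre (fully stained) is flagged
  `found = FALSE` rather than given a capped depth.
* Saturation fits require ≥ 3 distinct timepoints and a non-constant
  series; a level already met at $t = 0$ returns time 0 with a warning,
  a level at or above $I_{max}$ errors as unreachable.
* Confidence intervals are linearised (from the numerical Jacobian at the
  optimum with $t$-quantiles); they are reported for transparency and
  property-tested for coverage, but they are not the profile-likelihood
  intervals a small-sample analysis might prefer.
* The two-way ANOVA fits the additive model when the design has one
  observation per cell (the interaction would exhaust the residual
  degrees of freedom) and includes the interaction when replicates exist.

## Known limitations

* Radial symmetry is assumed throughout; real samples bend and deform
  inhomogeneously, which only 3D analysis could capture.
* The stain-front ramp width is a free phantom parameter, not an estimate
  of any physical front shape; detector accuracy is stated relative to it.
* Slices are exchanged as 16-bit ASCII PGM (plus JSON manifests) — a
  deliberately dependency-free text format; converting TIFF stacks to PGM
  is left to external tooling.
* No mechanistic (Fickian) diffusion model is fitted; $k$, $c$, $C$, $K$
  are empirical constants of the saturation laws above.
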