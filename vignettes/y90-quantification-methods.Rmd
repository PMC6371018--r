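---
title: "Quantitative Y-90 bremsstrahlung SPECT/CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Y-90 bremsstrahlung SPECT/CT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y90quant)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Setting

In hepatic radiomicrosphere therapy, ⁹⁰Y-loaded microspheres are delivered
into the tumor vasculature. The pre-treatment plan is imaged with
⁹⁹ᵐTc-MAA SPECT/CT; the post-treatment distribution can only be imaged via
the bremsstrahlung x rays of the ⁹⁰Y beta decay. That spectrum is
continuous — there is no photopeak window — so ⁹⁰Y SPECT images are noisy
and low-contrast, which hampers (a) quantitative comparison with the MAA
plan via tumor-to-liver ratios and (b) voxel-level absorbed-dose
estimation. The pipeline here addresses both with post-reconstruction
processing only: reconstructed images are inputs; tomographic
reconstruction, scatter, attenuation and septal-penetration compensation
are out of scope.

## Image model and contrast recovery

The reconstructed image $A$ is modelled as the true distribution degraded
by an isotropic Gaussian collimator–detector response with full width at
half maximum $\mathrm{FWHM} = \sqrt{8\ln 2}\,\sigma$, plus noise.
Richardson–Lucy (RL) deconvolution — an expectation-maximization estimate
under Poisson noise — iterates

$$A'_i = \Big[\frac{A}{A'_{i-1}\otimes PSF}\otimes PSF\Big]\cdot A'_{i-1},
\qquad A'_0 = A,$$

with the PSF held fixed. RL preserves non-negativity and, away from image
boundaries, total counts. Numerical choices:

* **Discrete PSF**: separable Gaussian sampled at voxel centres, truncated
  at 4σ, renormalized to sum exactly to 1; `fwhm = 0` degenerates to a
  delta kernel so the update has an exact fixpoint.
* **Boundaries**: reflective (symmetric) padding for all convolutions —
  of the options tried this conserves counts best near edges; interior
  sources are conserved to well under 1%.
* **Division guard**: the denominator $A'\otimes PSF$ is floored at
  $10^{-12}$, the standard RL stabilization of 0/0 voxels.
* **PSF width default 12 mm**, representative of a medium-energy collimator
  at the ~90 keV bremsstrahlung window; it is a configuration parameter,
  not an estimated quantity (no blind deconvolution).

### Stopping rule

Deconvolution sharpens contrast first and amplifies noise later, so the
iteration count is a bias–variance dial. It is calibrated on a hot-sphere
phantom: per iteration we trace the contrast recovery coefficient of the
largest (34 mm) sphere,

$$Q_H = 100\cdot\frac{C_S/C_B - 1}{R - 1},$$

($C_S$, $C_B$ the sphere/background VOI means, $R$ the true concentration
ratio) and the RMSE between consecutive estimates. The selected iteration
is the global $Q_H$ maximum among iterations where the RMSE declined
relative to the previous one (ties to the smaller index; if no iteration
shows an RMSE decline, the plain argmax). Patient images carry no phantom
VOIs, so they use a fixed, phantom-calibrated iteration (default 6).

Two open points were decided as follows: RMSE is computed over the whole
image (a VOI-restricted variant would need an extra mask input and the
choice does not affect the rule's structure), and patient studies use one
fixed iteration rather than per-patient stopping (there is no per-patient
reference to stop on).

On the clean simulated phantom (blur + Poisson only) $Q_H$ keeps rising and
RMSE keeps falling through 15 iterations, so the rule selects the last one;
with the heavier, structured degradations of real bremsstrahlung data the
$Q_H$ curve peaks earlier. The rule is the deliverable; the selected index
is data-dependent.

## Calibration and activity quantification

The calibration factor (CF, cps/MBq) is the slope of an ordinary
least-squares regression of reconstructed count rate on administered
activity across patients — either whole-field-of-view counts (method 1) or
liver-VOI counts only (method 2, robust to artifacts outside the liver).
The intercept is left free and reported for diagnostics (a through-origin
switch exists); the CF is defined as the slope alone, and the slope's 95%
CI is the usual $t$-based interval. Voxel division by CF converts cps to
MBq; percent error is $(\mathrm{true}-\mathrm{estimated})/\mathrm{true}
\times 100$, with report tables rounded half-away-from-zero to integers.
Supporting statistics — Pearson $r$ with $t$-transform $p$, paired $t$ from
either a difference summary or raw samples, and a two-sided Grubbs
single-outlier test — are thin, tested wrappers over the standard
formulas; $p$ values are reported, never used for automated decisions.

## Registration selection by mutual information

Spatial normalization itself is delegated to external tools; the package
ranks already-resampled candidate pairs by mutual information
$I(A,B) = H(A)+H(B)-H(A,B)$, computed in bits from one shared joint
histogram so that $I(a,a) = H(a)$ holds exactly. Defaults that the source
problem leaves open and are therefore declared, not inferred: 64 bins per
image, per-image min–max linear binning (constant images fall back to a
single bin), and a "body" support restricted to voxels where either image
is positive — without it, the empty space around the patient dominates the
histogram and depresses the score's sensitivity, the same mechanism that
makes near-empty livers hard to register. A translation-only exhaustive MI
search (`translate_register`) is included purely as plumbing for
closed-loop synthetic tests.

## Tumor delineation and TLR

Tumor uptake is delineated inside the liver VOI with the two-phase
piecewise-constant Chan–Vese energy

$$E = \mu\,\mathrm{Per}(\Sigma) + \lambda_1\!\!\sum_{\mathrm{in}}(I-c_1)^2
    + \lambda_2\!\!\sum_{\mathrm{out}}(I-c_2)^2 .$$

No single threshold is involved, which matters because MAA and ⁹⁰Y count
scales differ by an order of magnitude; additionally, intensities are
min–max normalized inside the liver so one set of weights transfers across
agents. The energy is minimized by direct label-flipping descent: voxels
are visited on the eight 3-D checkerboard sublattices (no two neighbours
updated simultaneously), a flip is accepted only if it lowers the discrete
energy given the current region means, and means are refreshed every
sublattice sweep — so the recorded energy trace is non-increasing by
construction. The perimeter term counts 6-neighbour label disagreements
inside the liver. Defaults: $\mu = 0.25$ (normalized intensities),
$\lambda_1=\lambda_2=1$, at most 200 sweeps, tolerance $10^{-4}$ on the
region means. Checkerboard initialization starts with nearly equal means,
where the length term would immediately collapse one phase, so it gets a
data-term-only warm-up (a two-means relaxation) before the full energy is
switched on; the threshold-seeded initialization (default) does not need
it. The higher-mean phase is labelled tumor, all its connected components
are kept (multi-focal disease), the healthy liver is the set difference,
and a constant liver returns an empty tumor with `converged = FALSE`
rather than an arbitrary split. Necrotic cores receive no special logic:
a zero-uptake core simply lands in the low phase.

The TLR is the ratio of mean counts per voxel, tumor over healthy liver —
scale-free, so it is insensitive to the CF and to administered-activity
differences between the two agents.

## Voxel S-value dosimetry

Microspheres are a permanent implant: no biological clearance, so the
cumulated activity is $\tilde A = A_0\,T_{1/2}/\ln 2$ with
$T_{1/2} = 64.05$ h for ⁹⁰Y (configurable). Absorbed dose is the lattice
convolution $D(t)=\sum_s \tilde A(s)\,S(t-s)$ over a voxel S-value kernel.
Decisions and caveats:

* **Units.** Kernels are declared in mGy/(MBq·s) and convolved with
  cumulated activity in MBq·s; a kernel written "per MBq" with time
  absorbed into $\tilde A$ is the same quantity. The loader reads declared
  units and the engine checks them; kernel voxel size must match the grid
  spacing within 1%.
* **Voxel-size interpolation.** Published tables exist at 3 and 6 mm; the
  clinical 4.664 mm kernel is obtained by per-offset linear interpolation
  in voxel size, index-wise between the two lattices. This is a documented
  numerical convenience, not transport physics; a distance-wise resampling
  alternative was considered and rejected as equally heuristic but harder
  to validate.
* **Engines.** A direct shifted-sum engine and a zero-padded FFT engine
  implement the same linear convolution and agree to ~1e-12 relative;
  dose deposited beyond the grid boundary is discarded.
* **No published tables are shipped.** The repo carries synthetic,
  energy-conserving kernels (exponential fall-off with distance, scale
  2.5 mm ~ the ⁹⁰Y mean beta range, normalized so the kernel-weighted
  total equals the 0.9336 MeV mean emitted energy per decay deposited in
  water voxels). They exercise the machinery and its conservation
  properties; clinical use requires real tables via the documented CSV
  schema.

cDVHs report the fraction of a VOI at or above each dose level on a
uniform edge grid from 0 to the VOI maximum (512 bins by default; at that
resolution the curve's integral matches the mean VOI dose to <1%). Isodose
levels are percentages of the maximum dose and their masks are nested by
construction.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Digital Jaszczak phantom**: a ~5.8 L cylinder with eight spheres of
  diameter 2–34 mm on a 55 mm ring, concentrations 0.52 (spheres) and
  0.04 MBq/ml (background) — the 13:1 hot ratio. Concentrations are the
  primary ground truth; printed per-sphere activities are slightly
  inconsistent with concentration × volume for the large spheres, and the
  generator resolves that in favour of concentrations. Partial volume at
  region boundaries is handled by supersampled occupancy fractions (4³
  sub-voxels by default; total activity matches closed forms to <1%).
  Default grid 96×96×64 at 4.664 mm — the clinical voxel size — keeps the
  full QC run under ~10 s; a full 132³ grid is a constructor argument away.
* **Acquisition model**: reconstructed cps = CF × activity blurred by the
  Gaussian PSF; Poisson noise draws counts at an acquisition time of 35 s
  (the clinical per-azimuth dwell) and divides back to cps. Defaults
  CF = 9049 cps/MBq (phantom-regime value) and FWHM = 12 mm. All
  randomness flows from explicit integer seeds; identical seeds give
  bitwise-identical images.
* **Paired liver studies**: an ellipsoidal liver with ellipsoidal tumor
  blobs whose uptake multiplier *is* the true TLR, optional zero-uptake
  necrotic cores, and a rigid translation applied to the second study with
  the exact inverse recorded. "Core" truth masks eroded clear of
  rasterization boundaries let ground-truth ratios be read off exactly;
  the ordinary truth masks include boundary voxels and therefore carry
  realistic partial-volume dilution.

What the generator does **not** emulate — and what passing tests therefore
do not establish about clinical data: object scatter, septal penetration
and backscatter (the dominant bremsstrahlung degradations), attenuation,
reconstruction artifacts, anatomical variability, and CT-to-SPECT
misregistration beyond rigid translation. Concretely, the clean simulation
recovers small-sphere contrast better than real data does and postpones
the noise-amplification point of the RL trace; qualitative directions
(large spheres recover strongly, sub-resolution spheres do not; CNR rises;
liver-VOI calibration is unbiased) are the transferable conclusions.

## Problem sizes used in tests

The shipped tests run the full 96×96×64 phantom once, 40×40×30 liver
studies elsewhere, a 12-study cohort at 48×48×36, and 500-replicate
regression simulations; the complete suite finishes in about a minute on
one core. These sizes were chosen so that boundary effects and count
levels are representative while iteration remains fast; every size is a
constructor argument, not a constant.

## Known limitations

* Reconstructed images are trusted as given; no compensation for the
  physics the reconstruction did not model.
* The Gaussian-PSF assumption is isotropic and spatially invariant;
  distance-dependent collimator response is not modelled.
* Index-wise kernel interpolation across voxel sizes inherits the error of
  its linearity assumption.
* The discrete Chan–Vese solver finds a local minimum of a non-convex
  energy; initialization matters for pathological inputs (hence the
  degenerate-input guards and the warm-up described above).
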