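---
title: "Methods: analytical PET simulation and its evaluation stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytical PET simulation and its evaluation stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(petsim)
```

## Scope and model

`petsim` simulates PET acquisitions analytically: instead of tracking
individual annihilation photons, it composes the *expected* sinogram from
its physical components — geometric projection, attenuation, randoms,
single-scatter — and draws Poisson counts from that expectation. This gives
noise realizations with the correct first and second moments at a small
fraction of Monte Carlo cost, at the price of not modeling detector-level
physics (crystal geometry, dead time, depth of interaction, multiple
scatter), which is out of scope here.

The scanner is described entirely at the sinogram level. A geometry carries
the number of radial bins, mashed azimuthal views, span-compressed axial
planes and TOF bins, plus the physical transaxial/axial field of view and
bore radius. Lines of response are parameterized directly by sinogram
coordinates; no crystal-pair bookkeeping exists anywhere in the pipeline.
Two deliberate approximations follow from this description:

* **Uniform axial planes.** The reference preset has 815 span-19 axial
  planes. Reconstructing the true michelogram segment structure would
  require the ring count, which is not part of the sinogram description;
  the planes are therefore laid out uniformly over the axial FOV and each
  is treated as a direct (in-plane) projection at its axial position, with
  a per-plane axial position table that gives inverse single-slice
  rebinning well-defined targets. Axial obliqueness lost to span
  compression is absorbed into the pre-smoothing kernel.
* **Sinogram-space sampling.** Radial spacing is `fov_transaxial /
  n_projections`; views are uniform over `[0, π)`.

## The projector and its normalization

Joseph's method is used for line integrals: the ray is stepped along the
voxel planes of its dominant axis (ties broken toward x) with linear
interpolation transverse to it. The whole operator is materialized once per
(geometry, grid) pair as a sparse matrix and cached, with two consequences
that the test suite leans on:

* The back-projector is the literal transpose, so the adjoint identity
  `<Ax, y> = <x, A'y>` holds to machine precision. This is the oracle for
  OSEM correctness.
* Two normalizations of the same geometric weights coexist. The *physical*
  weights (path length in mm) feed the attenuation factors
  `exp(−∫μ dl)`. The *counts* weights are column-normalized so that every
  voxel's total contribution over all LORs and planes is exactly 1: each
  simulated decay is detected exactly once, allocated across LORs in
  proportion to the geometric weights. A single global scale factor cannot
  make total sinogram counts equal total image counts for *every* input;
  per-voxel normalization can, and it is what turns the sensitivity
  calibration into an exact identity (below). The axial slice-to-plane
  mixing matrix is column-normalized the same way; its row-normalized twin
  is used where interpolation semantics are wanted (attenuation, inverse
  SSRB).

With TOF enabled, each emission point's contribution is spread over TOF
bins by a Gaussian whose width derives from the timing resolution
(σ_l = c·σ_t/2), renormalized per emission point over the covered bins so
the TOF-summed sinogram equals the non-TOF one exactly. TOF bin width
(80 ps) and timing resolution (210 ps FWHM) are nominal preset values,
config-exposed because they are not part of the sinogram dimensioning.

## The acquisition chain and its calibration contract

For activity `a` (Bq/ml), acquisition time `T` (s) and sensitivity `S`
(cps/kBq), the decays image is `presmooth(a) · voxel_volume_ml · T` and the
trues sinogram is `(S/1000) · attn ⊙ A(decays)`. Because `A` preserves
counts, a non-attenuated source yields `Σtrues = S · T · A_kBq` *exactly* —
the package's sensitivity default S = 38 cps/kBq is reproduced to 1e−9 by
construction, and `calibrate_sensitivity()` inverts the relation in closed
form (counts are linear in S). Randoms are uniform in projection space with
`Σrandoms = r·Σtrues` (r = 0.20 default), held fixed across activity levels
— a known simplification of real randoms behavior. The random rate and
sensitivity defaults are the values a scanner calibration against a 10-min
image-quality phantom scan produces; the pre-smoothing default of 3 mm FWHM
is likewise the value selected by `calibrate_presmooth()`'s grid search
when reference recovery coefficients are available.

Scatter is a 2D single-scatter model per image slice: scatter points are
chosen deterministically (every k-th voxel with μ > 0.005 cm⁻¹, k set to
hit ~500 points/slice); for each point and detector pair the contribution
is the product of emission line integrals from each detector to the point,
attenuation along both legs (511 keV attenuation used for both legs — the
energy dependence of μ between 435 and 511 keV is neglected), the
Klein–Nishina differential cross-section at the scattering angle, the local
μ as electron-density surrogate, inverse-square solid-angle factors, and an
energy-window indicator on the scattered energy `E' = 511/(2 − cosθ)` keV
(window 435–585 keV by default). The raw estimate is smoothed radially
(4-bin FWHM) and expanded to the 3D plane set by inverse single-slice
rebinning (linear interpolation between the two nearest slice positions).
Absolute scaling of a single-scatter estimate requires detector-efficiency
data that a sinogram-level description does not have, so the estimate is
scaled globally to a configurable scatter fraction (default 0.30 of
prompts), with an `"absolute"` pass-through mode. When TOF is on, scatter
is distributed uniformly across TOF bins — the conservative choice that
sums correctly.

Noise: realization *i* seeds the generator with `seed + i`, draws prompts
`~ Poisson(trues + scatter + randoms)` element-wise and the delayed window
independently from the TOF-summed randoms, matching a physically acquired
delayed window rather than copying the prompt randoms. Realizations are
therefore mutually independent and individually reproducible.
Denormalization is the identity under the default uniform normalization
(component-based normalization is out of scope; a uniform norm cancels
between simulation and reconstruction), but a normalization sinogram can be
divided in and multiplied back.

## Reconstruction

OP-OSEM with view-interleaved subsets (view j in subset j mod n). Subsets
are balanced to within one view; exact divisibility of the view count by
the subset count is *not* required, because mashed view counts at reduced
geometry scales are rarely divisible (e.g. 12 views at scale 0.25 with the
standard 5 subsets) and the multiplicative update is valid for unequal
subsets. The update uses the subset sensitivity `sᵤ = Aᵀᵤ(attn)`,
initialization x₀ = 1 inside the sensitivity support, a division guard of
1e−10 × mean(prompts), masking (with a warning) of zero-sensitivity voxels,
an optional isotropic image-space Gaussian PSF inside `A` and `Aᵀ`
(spatially *invariant*; radially varying resolution is a known limitation),
and an optional Gaussian post-filter applied once. With one subset the
update is MLEM and the Poisson log-likelihood is non-decreasing; the test
suite verifies this and the recovery of a known phantom to < 5% NRMSE on a
noise-free instance. The reconstruction lives in the decay-counts domain of
the counts-preserving projector; `counts_to_activity()` divides by
`voxel_volume_ml · T · S/1000` to return Bq/ml.

## Phantoms: what they emulate and what they do not

`make_nema_iq()` reproduces the printed specification of the image-quality
phantom: six spheres (10/13/17/22/28/37 mm inner diameter, wall thickness
ignored) at 5.72 cm from the phantom axis on one transaxial plane, inside a
chamfered-cylinder ("D"-shaped) body of 180 mm interior length whose
cross-section is scaled analytically so the cavity volume is 9575 ml,
default concentrations 2930/27369 Bq/ml (ratio 9.34), uniform water
attenuation 0.096 cm⁻¹ inside and zero outside (no lung insert, matching
the simplified attenuation description). Sphere plane position and body
length follow the physical phantom standard and are overridable.
Rasterization is anti-aliased on a supersample³ sub-grid (default 3);
sub-voxel coverage blends sequentially, which is exact whenever a later
shape lies inside an earlier one (the only case the built-in phantoms use).

`make_synthetic_torso()` is a *synthetic* stand-in for clinical inputs: an
elliptic-cylinder body, two low-density lungs (μ = 0.03 cm⁻¹, 0.25×
background uptake), liver (2.2×) and spleen (1.6×) compartments, a spine
rod (μ = 0.15 cm⁻¹), spherical lesions with user-set uptake ratios over
their local background, and a seeded log-normal intra-organ texture
(σ = 0.1 log units, smoothed at 1.5 voxels). The organ values are package
defaults chosen to be physiologically plausible for an FDG-like tracer;
they are not fitted to any patient data. Consequently, tests passing on
these phantoms demonstrate the *pipeline's* correctness and internal
consistency — counts calibration, trend behavior, metric identities — not
agreement with any particular patient population, scanner's measured
resolution, or Monte Carlo ground truth, all of which require data this
package does not ship.

## Evaluation conventions

* **NEMA ROIs.** Sphere ROIs are exact spheres at the known centers; at
  very coarse grids an ROI that would contain no voxel center degenerates
  to the nearest voxel. The background ROI is an annulus about the phantom
  axis on the sphere plane ± 2 slices; its default radii (80–110 mm) start
  outside the largest sphere's radial reach (75.7 mm) and the annulus is
  clipped to the body cross-section eroded by 10 mm so it contains only
  warm background. An annulus that intersected a sphere ROI would raise an
  error rather than silently bias the COV.
* **RC and COV** use population moments; COV = SD/mean.
* **Peak** averages voxels whose centers fall in the 1 cm³ sphere (radius
  6.2035 mm) centered on the maximum voxel; ties break toward the lowest
  linear index. **Skewness** is the biased moment coefficient m₃/m₂^1.5,
  defined as 0 for constant input.
* **GLCM** features are built per transaxial slice for the four in-plane
  directions at distance 1, symmetric, counts pooled over slices per
  direction *before* normalization, features averaged over directions.
  Discretization is anchored at absolute zero with a fixed bin width in
  the image's intensity units (the bin width is an absolute intensity, not
  ROI-relative), so feature values are comparable across images.
* **Freedman–Diaconis** bin width 2·IQR·n^(−1/3) with type-7
  (linear-interpolation) quantiles; degenerate IQR falls back to one bin.
* **Overlap metrics**: MCC counts true negatives inside the union bounding
  box padded by 5 voxels by default (full-volume mode available), so TN
  does not swamp the statistic on large grids; DSC/TPR/precision/VS are
  TN-free. **VS** uses the |FP−FN| form.
* **STAPLE**: EM with a spatially uniform prior equal to the mean
  foreground fraction of the raters, initialization p = q = 0.99999, rates
  clipped to (1e−5, 1−1e−5) so empty/full raters stay well defined,
  convergence at max parameter change < 1e−6. Deterministic; invariant to
  rater order.
* **Shape features**: volume is voxel count × voxel volume; principal axis
  lengths are 2√(5λ) from the eigenvalues of the foreground coordinate
  covariance (a solid ellipsoid with semi-axis a has variance a²/5, so the
  estimator is exact in the continuum limit; a digitized 30 mm sphere
  measures 29.9 mm). Surface area integrates |∇| of the indicator smoothed
  at 1 voxel — by the coarea formula this averages isosurface areas across
  levels and lands within a few percent of the analytic sphere area
  without a triangulation dependency.
* **Lesion auto-thresholding** (40% of local peak inside a search sphere
  of twice the lesion diameter) substitutes for human analysts in the
  concordance experiment and is labeled as such in its manifest.

## Problem sizes and numerical choices

The package's own experiments default to geometry scale 0.25 (110×110×40
grid, 130×12×204 sinograms): large enough that all six spheres produce
distinct recovery coefficients, small enough that a full five-realization
NEMA analysis with OP-OSEM 8 it × 5 subsets completes in about a minute on
one CPU. The trend analyses in the test suite use scales 0.2–0.25 and two
realizations; the sphere-resolution-dependent monotonicity check (RC rising
with diameter) is run at scale 0.25 because at 8.25 mm voxels the two
smallest spheres degenerate to single-voxel ROIs. Noise-free components are
exactly linear in acquisition time, so multi-time experiments simulate once
at T = 1 and rescale.

Other numeric details: Gaussian kernels are truncated at 4σ and
renormalized; pre-smoothing renormalizes the global sum after convolution
so activity is conserved near grid edges; the rasterizer warns (not errors)
when the smallest sphere is under two voxels across; `scale_scatter`
achieves its target fraction to machine precision; Poisson sampling uses
R's `rpois` with one `set.seed` per realization.

## Known limitations

No detector-level physics (gaps, dead time, arc effects,
depth-of-interaction), no multiple scatter or out-of-FOV scatter, no
randoms-from-singles model (fixed randoms fraction), spatially invariant
PSF, uniform-plane axial approximation in place of the true michelogram,
uniform normalization (component-based normalization is a pass-through),
no decay during acquisition or continuous bed motion. These bound the
realism of absolute noise texture at the axial FOV edges and of resolution
far off-center; the package's validated claims are the calibration
identities, the trend behavior of RC/COV, and the internal consistency of
its evaluation metrics.
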