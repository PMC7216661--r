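---
title: "Segmenting root systems in X-ray CT volumes: models and methods"
author: "rootCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting root systems in X-ray CT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootCT)
```

## The problem

Root system architecture (RSA) — the 3-D arrangement of a plant's roots in
its growth medium — is a key drought-adaptation trait, but it is hidden in
soil. X-ray computed tomography can image a potted root system
non-destructively, yet root tissue differs only modestly in attenuation
from the surrounding substrate, and the reconstructed volumes must be
segmented before the architecture becomes visible. rootCT implements a
fully automatic segmentation chain for this setting, aimed at rice radicle
and crown roots (diameters roughly 0.2–1.2 mm) growing in a uniform
calcined-clay substrate, scanned at a 0.3 mm voxel pitch in pots around
20 cm diameter. Because roots absorb fewer X-rays than the fired-clay
granules, roots appear as dark, thin, tubular structures in a brighter,
granular matrix.

Everything in the package is testable without scanner data: a seeded
phantom generator renders synthetic 16-bit volumes with known root
geometry, and an evaluator scores the processed output against that
ground truth.

## The processing chain

`runPipeline()` applies, in order:

1. **Mode-anchored normalization** (`normalizeVolume`). The grayscale
   histogram of a soil-filled pot is bimodal: an air mode (pot
   surroundings) and a soil mode. A linear map sends air to 0 and
   soil to 1024, with negative values rounded up to zero. This removes
   scan-to-scan window-width/level differences; values above 1024 (pot
   wall, dense minerals) are deliberately preserved, since the later
   inversion clamps them anyway.
2. **3-D median filter** (`medianFilter3D`, kernel 7). A rank filter is
   the right denoiser here: photon/reconstruction speckle is spatially
   uncorrelated and is crushed by a 343-voxel median, while a root — a
   contiguous tube whose attenuation deficit the scanner's point-spread
   function (PSF) smears over a couple of voxels — shifts the ranks of
   the whole neighborhood and survives as a graded dip. Kernel 1 is the
   identity; kernel 9 visibly blurs structure, 7 is the default.
3. **Inversion** (`invertVolume`): `v -> max(0, 1024 - v)`. Roots become
   the bright foreground, soil falls to ~0.
4. **Per-slice edge detection** (`edgeDetectSlice`, box kernel 21):
   `max(0, slice - boxblur(slice))`. Subtracting a 21-px (6.3 mm) mean
   removes every structure smooth at that scale — residual shading,
   local soil-brightness differences the global normalization cannot fix —
   and keeps thin bright tubes. A box (not Gaussian) blur is used so
   that kernel size 1 is exactly the identity and the edge output is
   exactly zero there. Horizontal stratification (the soil surface)
   is invisible to a per-slice filter, which is also why this stage is
   applied in 2-D.
5. **Optional threshold + 3-D size opening** (`thresholdAndOpen`).
   Off by default: small voids and water gradients do remain visible in
   the output, but removing them risks erasing the fine root segments of
   young seedlings. When enabled, 26-connectivity is used so thin
   diagonal fragments are not split into pieces.
6. **Cylinder crop** (`cropCylinder`, default 180 mm diameter x 250 mm
   deep). Removes the pot wall and roots touching it; the default
   matches trimming an 18 cm cylinder out of a 20 cm pot.
7. **8-bit export** (`export8bit`). `clip` (default) truncates at 255 so
   absolute edge magnitudes stay comparable across the daily scans of a
   4-D series; `rescale` maps to the full display range. Values are
   rounded half-up.

Stage order follows the method's published description (median, then
inversion, then per-slice subtraction); the blur-subtraction acts on the
inverted volume.

### Numerical choices

* Median and blur borders use edge replication; replication adds no
  spurious edges at the volume boundary.
* The median is computed exactly (`nth_element` over the k^3 window) in
  C++; the box blur uses an integral image, so both are deterministic
  with no floating-point reordering across worker counts.
* The chain keeps real-valued intermediates; integers appear only at
  16-bit input and 8-bit export (rounding half-up).
* Parallelism (`workers`) splits the median stage into z-chunks with a
  halo of `(k-1)/2` slices and the edge stage per slice, so output is
  byte-identical for any worker count — a contract the tests enforce.

## Image-quality metrics

Root-to-soil contrast is summarized by the contrast-to-noise ratio

\[ \mathrm{CNR} = \frac{|S_1 - S_2|}{\sigma} \]

with \(S_1\) the mean intensity over root voxels, \(S_2\) the mean over
soil voxels and \(\sigma\) the *population* standard deviation of the
soil voxels (the formula does not specify the divisor; the population
form is fixed here so reported values are reproducible from masks).
`kernelSweep()` tabulates CNR against median kernel size;
`mip()` computes maximum-intensity projections (top-down and side
views) for visualization.

## The phantom generator

`generateRootSystem()` + `renderVolume()` emulate the statistical
structure the chain assumes, on a default 128^3 grid at 0.3 mm pitch
(a 38 mm pot in miniature — full-scale pots at this pitch would be
1024 x 1024 x 860 voxels; the miniature keeps the test suite's runtime
in seconds-to-minutes per volume while preserving every length scale
that matters: voxel pitch, kernel sizes, root diameters):

* **Geometry.** Roots grow from a crown point at the pot center at the
  soil surface, as piecewise-linear paths whose initial polar angle
  encodes the architecture archetype (deep ~5–25 degrees from vertical,
  shallow ~65–85, intermediate between), with small per-segment angular
  noise, a slight downward bias, and inward reflection at the wall and
  bottom. Roots keep one median-kernel width of clearance from the wall
  because the chain crops wall-touching roots by design. Slice 1 is the
  soil surface, as in real reconstructions of the potted column.
* **Partial volume.** Each root is rasterized as a capsule chain; a
  supersampler counts covered subvoxel centers (factor 3 per axis by
  default, i.e. fraction error up to ~1/6 near the tube surface; the
  convergence test runs the same code at factor 40 where it matches the
  analytic circle area within 2%). A root thinner than a voxel darkens
  it only fractionally — the mechanism behind the ~0.3 mm detection
  limit at 0.3 mm voxels.
* **PSF.** The combined attenuation deficit (roots, voids, cracks) is
  convolved with a Gaussian point-spread function (sigma 0.25 mm by
  default) before meeting the noise. Without it a sharp-edged sub-kernel
  tube would be *entirely* erased by a 7-voxel median (a rank filter
  removes any minority structure), which contradicts the observed
  behavior of the real chain; the PSF is what lets rank filtering keep
  thick roots while genuinely sub-voxel roots stay invisible.
* **Noise, two components.** A correlated Gaussian field (granularity
  0.6 mm, the substrate's granule scale) models soil texture, and white
  voxel-scale noise models photon/reconstruction speckle of rapid
  scanning. The white component is what the median visibly removes; the
  texture amplitude is kept low, emulating the uniform calcined-clay
  substrate that the protocol chose precisely so that an unthresholded
  chain yields a near-empty null volume.
* **Clutter and histogram.** Optional darker spherical voids, darker
  near-surface crack streaks, and a bright pot-wall annulus; air fills
  the region outside the pot, so the volume histogram is bimodal and
  the normalization's mode finder can be exercised end to end.
* **Determinism.** One seed drives everything through a locally scoped
  RNG (the caller's `.Random.seed` is untouched); identical seeds give
  bit-identical phantoms. `growTimeSeries()` renders nested growth
  stages with independent per-day scan noise.

### Calibration of the free parameters

No measured root/soil intensity contrast or substrate noise amplitude
is available for this scanner and substrate, so these are the
generator's free parameters,
calibrated once against the detection-limit properties the phantom must
exhibit (recovery of >= 0.6 mm roots, invisibility of <= 0.15 mm roots,
a near-empty processed null phantom, and a CNR gain from the kernel-7
median) and then frozen. These properties pull in opposite directions:
the correlated texture passes a median filter almost unchanged (it is
the denominator floor of the filtered CNR), white noise is crushed by
the median (it is what makes the CNR *improve*) but, too strong, it
dithers sub-voxel roots into visibility through rank shifts. The
shipped window — root contrast 0.5 (a water-like root in fired clay),
soil texture sd 1 and white scan noise sd 5 on a 14000-gray
air-to-soil separation, PSF sigma 0.25 mm — satisfies all four with
margin on multiple seeds.
What passing tests show is therefore that the *chain* behaves as
designed under the assumed image model; they do not certify performance
on substrates with coarser or stronger texture, where the edge stage
would pass granule clutter into the output exactly as it does in the
real method when run on sieved field soils.

## The detection evaluator

`scoreDetection()` replaces the human "detectable by eye" call with a
declared surrogate: a root counts as detected when at least half of its
centerline voxels have a nonzero processed voxel within a 1-voxel
(Chebyshev) tolerance. Both knobs are exposed. `diameterSummary()`
produces the five-number summaries a detectable-vs-undetectable box
plot draws (quantile type 7, linear interpolation between closest
ranks). `detectionReport()` keeps percentages exact:
`percentUndetected = 100 - percentDetected`, so the two always sum to
100.

## Scan-protocol arithmetic

`scanTimeS()` (projections x averaging / fps, floored to whole
seconds — so 600 projections without averaging at 18 fps report as
33 s), `physicalExtentMm()`, `magnification()` (source–detector over
source–axis distance), `doseBudget()` (permissible scans under a
cumulative limit, default 12.6 Gy — the dose shown not to affect rice
growth as 9 daily 1.4 Gy scans) and `cumulativeDose()`. The dose rate
itself is always an external input (e.g. a dose calculator); nothing is
derived from tube physics. `doseRateScanGy()` multiplies a supplied
Gy/h rate by the scan duration: the standard protocol's 0.55 Gy/h for
10 minutes gives 0.0917 Gy, an upper bound for the thicker copper
filter actually mounted (whose extra attenuation is not quantified).

## Known limitations

* The chain segments *contrast*, not roots: voids, cracks and water
  gradients of root-like scale remain in the output unless the optional
  size opening is enabled, exactly as in the real method.
* No skeletonization, diameter measurement or lateral-root detection;
  the output is a segmented volume for visualization and
  detection-limit analysis.
* The phantom's noise model is Gaussian (correlated + white); it does
  not simulate beam hardening, ring artifacts or scatter, and CT
  reconstruction itself is out of scope — volumes enter as reconstructed
  slice stacks.
* Mode detection assumes a genuinely bimodal histogram; degenerate
  substrates need manual modes (`bimodalModes()`), which every entry
  point accepts.
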