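# rootCT

Automatic segmentation and 4-D visualization of plant root system
architecture (RSA) in X-ray computed tomography volumes of soil-grown
plants — aimed at rice radicles and crown roots (0.2–1.2 mm diameter)
growing in calcined clay, scanned at 0.3 mm voxel pitch in ~20 cm pots.
Roots absorb fewer X-rays than the fired-clay substrate, so they appear
as thin dark tubes in a brighter granular matrix; the package turns a
stack of reconstructed 16-bit slices into an 8-bit volume in which the
roots are the only bright structures, with no training data and no
per-sample tuning.

## The method

For a reconstructed volume \(V\) with air and soil histogram modes
\(m_{air}, m_{soil}\):

1. normalize: \(V' = \max\!\big(0,\; 1024\,(V - m_{air})/(m_{soil} - m_{air})\big)\)
2. 3-D median filter, kernel 7 voxels (removes scan speckle, keeps tubes)
3. invert about the soil anchor: \(V'' = \max(0, 1024 - V')\)
4. per-slice edge detection, box kernel 21 px:
   \(E = \max(0, V'' - \mathrm{boxblur}_{21}(V''))\)
5. optional threshold + 3-D size opening (off by default)
6. crop to a centered cylinder (default 18 cm diameter x 25 cm deep)
7. export to 8 bits (clip mode preserves magnitudes across time points)

Root-to-soil contrast is quantified by the contrast-to-noise ratio
\(\mathrm{CNR} = |S_1 - S_2|/\sigma\) (mean root intensity, mean soil
intensity, soil standard deviation); visualization uses maximum
intensity projections. A seeded phantom generator renders synthetic CT
volumes of fibrous root systems (partial-volume attenuation, correlated
soil texture, white scan noise, point-spread blur, voids, cracks, pot
wall) with ground-truth centerlines, and an evaluator scores per-root
detection against them. A protocol module does the acquisition
arithmetic: scan time, field of view, geometric magnification and
X-ray dose budgets for repeated (4-D) scanning.

## Worked example

```r
library(rootCT)

# a synthetic scan: 128^3 voxels at 0.3 mm, ten 1.0 mm deep-type roots
cfg   <- phantomConfig(nRoots = 10, rootDiameters = 1.0,
                       archetype = "deep", includeVoids = FALSE,
                       includeCracks = FALSE, seed = 11)
truth <- generateRootSystem(cfg)
scan  <- renderVolume(truth, cfg)

# the standard chain, crop cylinder sized to this phantom's pot
chain <- pipelineConfig(cropDiameterMm = 34, cropHeightMm = 38.1)
out   <- runPipeline(scan$volume, chain)

report <- scoreDetection(out, scan$centerlines, truth)
report
#> DetectionReport: 10 roots, 10 detected (100.0%), 0 undetected (0.0%)

masks <- phantomMasks(scan, cfg)
kernelSweep(normalizeVolume(scan$volume), masks$root, masks$soil,
            kernels = c(1, 7))
#>   kernel      cnr
#> 1      1 1208.383
#> 2      7 1925.143
```

All ten 1.0 mm roots are recovered (every centerline voxel has segmented
output within one voxel), and the kernel-7 median filter raises the
root-to-soil CNR by about 60% relative to the unfiltered volume. Scan-protocol
arithmetic is one call each:

```r
scanTimeS(scanProtocol(1200, 2, 4.0))      # 600  (the 10-min scan)
scanTimeS(scanProtocol(600, 1, 18.0))      # 33   (the fast scan)
doseBudget(0.09)$scans_permissible         # 140 scans under 12.6 Gy
detectionCounts(detectionReport(68, 12))["percent_undetected"]  # 15
```

A command-line front end with `process`, `phantom`, `evaluate` and
`protocol` subcommands is installed at
`system.file("scripts", "rootct.R", package = "rootCT")`; every run
writes a `run_manifest.json` sufficient to reproduce it bit-exactly,
and processing is byte-identical for any `--jobs` value.

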