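test_that("root-system generation is deterministic and leaves no RNG trace", {
  cfg <- small_phantom_config()
  set.seed(123)
  before <- .Random.seed
  t1 <- generateRootSystem(cfg)
  expect_identical(.Random.seed, before)   # no global RNG state consumed
  t2 <- generateRootSystem(cfg)
  expect_identical(t1@roots, t2@roots)
  empty <- generateRootSystem(small_phantom_config(nRoots = 0L))
  expect_length(empty@roots, 0)
})

test_that("roots stay inside the pot and start at the crown point", {
  cfg <- phantomConfig(dim = c(64L, 64L, 64L), nRoots = 30L,
                       archetype = "shallow", seed = 3L)
  truth <- generateRootSystem(cfg)
  ext <- cfg@dim * cfg@pitch
  for (r in truth@roots) {
    rad <- sqrt((r$centerline[, 1] - ext[3] / 2)^2 +
                (r$centerline[, 2] - ext[2] / 2)^2)
    expect_lt(max(rad), truth@potRadiusMm)
    expect_gte(min(r$centerline[, 3]), truth@soilTopMm)
    expect_lt(max(r$centerline[, 3]), ext[1])
  }
  crowns <- t(vapply(truth@roots, function(r) r$centerline[1, ], numeric(3)))
  expect_lt(max(abs(crowns[, 1] - ext[3] / 2)), 1e-9)
})

test_that("deep archetypes end deeper than shallow ones", {
  depth_of <- function(arch, seed) {
    cfg <- phantomConfig(dim = c(64L, 64L, 64L), nRoots = 100L,
                         archetype = arch, seed = seed)
    truth <- generateRootSystem(cfg)
    mean(vapply(truth@roots, function(r) max(r$centerline[, 3]), numeric(1)))
  }
  expect_gt(mean(c(depth_of("deep", 1L), depth_of("deep", 2L))),
            mean(c(depth_of("shallow", 1L), depth_of("shallow", 2L))))
})

test_that("rendering is seed-reproducible, zero contrast hides the roots", {
  cfg <- small_phantom_config()
  truth <- generateRootSystem(cfg)
  r1 <- renderVolume(truth, cfg)
  r2 <- renderVolume(truth, cfg)
  expect_identical(ctData(r1$volume), ctData(r2$volume))

  # rootContrast 0: bit-identical to a rootless phantom of the same seed
  cfg0 <- small_phantom_config(rootContrast = 1e-12)
  r0 <- renderVolume(generateRootSystem(cfg0), cfg0)
  cfgE <- small_phantom_config(nRoots = 0L)
  rE <- renderVolume(generateRootSystem(cfgE), cfgE)
  expect_identical(ctData(r0$volume), ctData(rE$volume))
})

test_that("a fully covered tube voxel is darkened by the full contrast", {
  # straight axis-aligned tube of diameter 2 voxels, no noise
  cfg <- phantomConfig(dim = c(32L, 32L, 32L), soilSd = 0, nRoots = 0L,
                       includeVoids = FALSE, includeCracks = FALSE,
                       potWall = FALSE, rootContrast = 0.5, seed = 2L)
  # axis through voxel centers (voxel i spans [i-1, i) in 0-based units)
  segs <- matrix(c(15.5, 15.5, 8, 15.5, 15.5, 28, 1.0), 1)  # r = 1 voxel
  frac <- tubeVoxelFractions(segs, cfg@dim, ss = 3L)
  # interior voxels along the axis are fully covered
  expect_equal(frac[16, 16, 16], 1)
  expect_equal(frac[20, 16, 16], 1)
  expect_true(all(frac >= 0 & frac <= 1))
})

test_that("sub-voxel tubes get the analytic partial-volume fraction", {
  # axis-aligned tube of diameter 0.5 voxels centered on a voxel center:
  # the in-plane area fraction is pi * 0.25^2; a fine supersampling grid
  # must converge to it
  d <- c(9L, 9L, 9L)
  segs <- matrix(c(4.5, 4.5, 0, 4.5, 4.5, 9, 0.25), 1)
  frac <- tubeVoxelFractions(segs, d, ss = 40L)
  expect_lt(abs(max(frac) - pi * 0.25^2) / (pi * 0.25^2), 0.02)
})

test_that("phantom histograms are bimodal with recoverable air/soil modes", {
  cfg <- phantomConfig(dim = c(64L, 64L, 64L), nRoots = 6L, seed = 5L,
                       soilSd = 400)
  r <- renderVolume(generateRootSystem(cfg), cfg)
  modes <- findBimodalModes(computeHistogram(r$volume, binWidth = 16))
  expect_lt(abs(modes@mAir - cfg@airMean), 500)
  expect_lt(abs(modes@mSoil - cfg@soilMean), 500)
})

test_that("time series are nested, reproducible and grow monotonically", {
  cfg <- small_phantom_config(soilSd = 0, potWall = FALSE)
  truth <- generateRootSystem(cfg)
  days <- growTimeSeries(truth, cfg, nDays = 3)
  expect_length(days, 3)

  # day n equals the full render (same noise seed policy at t = 1 of 1)
  one <- growTimeSeries(truth, cfg, nDays = 1)
  full <- renderVolume(truth, cfg)
  expect_identical(ctData(one[[1]]$volume), ctData(full$volume))

  # same seed -> identical series
  again <- growTimeSeries(truth, cfg, nDays = 3)
  expect_identical(lapply(days, function(d) ctData(d$volume)),
                   lapply(again, function(d) ctData(d$volume)))

  # on noise-free renders the segmented voxel count never shrinks with age
  cfgP <- phantom_pipeline_config(cfg, kMed = 3L)
  counts <- vapply(days, function(dd) {
    out <- runPipeline(dd$volume, cfgP, modes = bimodalModes(cfg@airMean,
                                                             cfg@soilMean))
    sum(ctData(out) > 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
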