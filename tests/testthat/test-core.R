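test_that("median filter: kernel 1 is the identity, constants unchanged", {
  vol <- random_volume(c(6L, 6L, 6L), seed = 3)
  expect_identical(ctData(medianFilter3D(vol, 1L)), ctData(vol))
  const <- tiny_volume(c(5L, 5L, 5L), value = 777)
  for (k in c(3L, 5L)) {
    expect_true(all(ctData(medianFilter3D(const, k)) == 777))
  }
  expect_error(medianFilter3D(vol, 4L), "odd")
})

test_that("median filter equals a 27-neighbor sort oracle on random 9^3", {
  vol <- random_volume(c(9L, 9L, 9L), seed = 11, hi = 1000)
  got <- ctData(medianFilter3D(vol, 3L))
  v <- ctData(vol)
  for (z in 2:8) for (y in 2:8) for (x in 2:8) {
    nb <- v[(z - 1):(z + 1), (y - 1):(y + 1), (x - 1):(x + 1)]
    expect_identical(got[z, y, x], sort(as.vector(nb))[14],
                     label = sprintf("median at (%d,%d,%d)", z, y, x))
  }
})

test_that("median filter borders use edge replication", {
  # corner voxel of a 3^3 volume: its clamped 3x3x3 neighborhood repeats
  # edge values; compute the same expansion by hand
  vol <- random_volume(c(3L, 3L, 3L), seed = 5, hi = 100)
  v <- ctData(vol)
  got <- ctData(medianFilter3D(vol, 3L))[1, 1, 1]
  idx <- function(i) pmax(1, pmin(3, i))
  nb <- numeric(0)
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    nb <- c(nb, v[idx(dz), idx(dy), idx(dx)])
  }
  expect_identical(got, sort(nb)[14])
})

test_that("median commutes with global intensity shifts", {
  vol <- random_volume(c(7L, 7L, 7L), seed = 23, hi = 500)
  shifted <- CTVolume(ctData(vol) + 137, voxelPitch(vol))
  expect_equal(ctData(medianFilter3D(shifted, 3L)),
               ctData(medianFilter3D(vol, 3L)) + 137)
})

test_that("inversion maps the normalized anchors correctly", {
  vol <- CTVolume(array(c(1024, 0, 1500, 700, 512), c(5, 1, 1)))
  out <- ctData(invertVolume(vol))[, 1, 1]
  expect_equal(out, c(0, 1024, 0, 324, 512))
})

test_that("edge detection: kernel 1 and constant slices give all zeros", {
  set.seed(2)
  sl <- matrix(runif(30 * 30, 0, 1024), 30, 30)
  expect_true(all(edgeDetectSlice(sl, 1L) == 0))
  expect_true(all(edgeDetectSlice(matrix(5, 25, 25), 21L) == 0))
  expect_error(edgeDetectSlice(sl, 2L), "odd")
})

test_that("edge detection matches the closed-form box-blur response", {
  # single pixel of value V in a zero slice: center response V - V/441
  V <- 441
  sl <- matrix(0, 21, 21)
  sl[11, 11] <- V
  out <- edgeDetectSlice(sl, 21L)
  expect_equal(out[11, 11], V - V / 441)
  # every other pixel of the 21x21 slice sees the blurred pixel subtracted
  expect_true(all(out[-11, ] == 0 | out[-11, ] < V))
})

test_that("edge detection output is invariant to adding a constant", {
  set.seed(31)
  sl <- matrix(runif(40 * 40, 0, 200), 40, 40)
  expect_equal(edgeDetectSlice(sl + 123, 7L), edgeDetectSlice(sl, 7L))
})

test_that("size opening keeps only components of at least minSize voxels", {
  d <- c(12L, 12L, 12L)
  v <- array(0, d)
  v[2:3, 2:3, 2:3] <- 50           # 8 voxels
  v[6:9, 6:9, 6:9] <- 80           # 64 voxels
  vol <- CTVolume(v)
  out <- ctData(thresholdAndOpen(vol, threshold = 1, minSize = 10))
  expect_true(all(out[2:3, 2:3, 2:3] == 0))
  expect_true(all(out[6:9, 6:9, 6:9] == 80))
  # minSize = 1 is pure thresholding
  pure <- ctData(thresholdAndOpen(vol, threshold = 60, minSize = 1))
  expect_equal(pure > 0, v >= 60)
})

test_that("size opening equals a brute-force flood-fill oracle", {
  set.seed(77)
  d <- c(20L, 20L, 20L)
  v <- array(ifelse(runif(prod(d)) < 0.08, 100, 0), d)
  vol <- CTVolume(v)
  for (conn in c(6L, 26L)) {
    out <- ctData(thresholdAndOpen(vol, threshold = 50, minSize = 5,
                                   connectivity = conn)) > 0
    labels <- flood_fill_labels(v >= 50, conn)
    sizes <- tabulate(labels)
    keep <- array(labels > 0 & sizes[pmax(labels, 1L)] >= 5, d)
    expect_identical(out, keep, label = paste("connectivity", conn))
  }
})

test_that("size opening is anti-extensive and idempotent", {
  set.seed(78)
  d <- c(15L, 15L, 15L)
  v <- array(ifelse(runif(prod(d)) < 0.1, 100, 0), d)
  vol <- CTVolume(v)
  once <- thresholdAndOpen(vol, 50, minSize = 4)
  expect_true(all(ctData(once)[v < 50] == 0))           # mask shrinks only
  twice <- thresholdAndOpen(once, 50, minSize = 4)
  expect_identical(ctData(twice), ctData(once))
})

test_that("cylinder crop keeps exactly the in-circle pixel centers", {
  # one full-size slice at scanner geometry: 1024 x 1024 at 0.3 mm,
  # 180 mm crop diameter = radius 300 px
  vol <- CTVolume(array(1, c(1, 1024, 1024)), pitch = 0.3)
  out <- ctData(cropCylinder(vol, 180, 0.3))
  inside <- sum(out > 0)
  dx <- (seq_len(1024) - 0.5) - 512
  oracle <- sum(outer(dx^2, dx^2, "+") <= 300^2)
  expect_equal(inside, oracle)
  # center voxel retained, far-corner voxel zeroed
  expect_equal(out[1, 512, 512], 1)
  expect_equal(out[1, 1, 1], 0)
})

test_that("cylinder crop zeroes below the crop height and validates size", {
  vol <- CTVolume(array(1, c(10, 20, 20)), pitch = 1)
  out <- ctData(cropCylinder(vol, 10, 4))
  expect_true(all(out[5:10, , ] == 0))
  expect_true(any(out[1:4, , ] > 0))
  expect_error(cropCylinder(vol, 30, 4), "exceeds")
  expect_error(cropCylinder(vol, 10, 40), "exceeds")
})

test_that("8-bit export clips or rescales as configured", {
  vol <- CTVolume(array(c(0, 300, 256, 512), c(4, 1, 1)))
  expect_equal(ctData(export8bit(vol, "clip"))[, 1, 1], c(0, 255, 255, 255))
  expect_equal(ctData(export8bit(vol, "rescale"))[, 1, 1],
               c(0, 149, 128, 255))  # 300*255/512 = 149.4 -> 149
  zero <- tiny_volume(c(2L, 2L, 2L), 0)
  expect_true(all(ctData(export8bit(zero, "clip")) == 0))
  expect_true(all(ctData(export8bit(zero, "rescale")) == 0))
  expect_error(export8bit(CTVolume(array(-1, c(1, 1, 1)))), "nonnegative")
})

test_that("the full chain zeroes out when the blur kernel is 1", {
  cfg <- small_phantom_config()
  r <- renderVolume(generateRootSystem(cfg), cfg)
  out <- runPipeline(r$volume, phantom_pipeline_config(cfg, kBlur = 1L))
  expect_true(all(ctData(out) == 0))
})

test_that("pipeline errors are annotated with the failing stage", {
  vol <- random_volume(c(8L, 8L, 8L), seed = 1)
  # default 180 mm crop cannot fit an 8-voxel grid
  expect_error(runPipeline(vol, pipelineConfig(),
                           modes = bimodalModes(0, 1024)), "crop")
})
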