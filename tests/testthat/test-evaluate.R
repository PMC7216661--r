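test_that("detection bookkeeping reproduces the wired-basket contingency", {
  # 68 detected / 12 undetected roots -> 15% undetected
  rep <- detectionReport(68, 12)
  cnt <- detectionCounts(rep)
  expect_equal(unname(cnt["percent_undetected"]), 15)
  expect_equal(unname(cnt["percent_detected"]), 85)
  expect_equal(unname(cnt["n_detected"] + cnt["n_undetected"]), 80)
})

test_that("percentages always sum to exactly 100", {
  for (nd in c(0L, 1L, 7L, 82L)) for (nu in c(0L, 3L, 13L)) {
    if (nd + nu == 0L) next
    cnt <- detectionCounts(detectionReport(nd, nu))
    expect_identical(unname(cnt["percent_detected"] +
                            cnt["percent_undetected"]), 100)
  }
})

test_that("a perfect segmentation detects every root; an empty one none", {
  cfg <- small_phantom_config()
  truth <- generateRootSystem(cfg)
  r <- renderVolume(truth, cfg)
  perfect <- CTVolume(r$fractions, voxelPitch(r$volume))  # truth as image
  rep <- scoreDetection(perfect, r$centerlines, truth)
  expect_equal(rep@percentDetected, 100)
  expect_true(all(perRoot(rep)$coverage > 0.99))

  none <- CTVolume(array(0, dim(r$volume)), voxelPitch(r$volume))
  rep0 <- scoreDetection(none, r$centerlines, truth)
  expect_equal(rep0@nDetected, 0L)
  expect_equal(rep0@percentDetected, 0)
  expect_error(scoreDetection(none, list()), "empty")
})

test_that("detection is monotone in the processed volume", {
  cfg <- small_phantom_config()
  truth <- generateRootSystem(cfg)
  r <- renderVolume(truth, cfg)
  set.seed(4)
  partial <- r$fractions * (array(runif(prod(dim(r$fractions))),
                                  dim(r$fractions)) < 0.4)
  rep1 <- scoreDetection(CTVolume(partial, 0.3), r$centerlines, truth)
  more <- partial
  more[r$fractions > 0] <- 1     # add voxels, remove none
  rep2 <- scoreDetection(CTVolume(more, 0.3), r$centerlines, truth)
  expect_true(all(perRoot(rep2)$coverage >= perRoot(rep1)$coverage))
  expect_gte(rep2@nDetected, rep1@nDetected)
})

test_that("diameter summaries follow the stated quantile convention", {
  pr <- data.frame(id = 1:7, class = "crown",
                   diameter_mm = c(0.2, 0.4, 0.6, 0.8, 1.0, 0.3, 0.9),
                   coverage = c(1, 1, 1, 1, 1, 0, 0),
                   detected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  rep <- detectionReport(5, 2, pr)
  s <- diameterSummary(rep)
  det <- s[s$group == "detected", ]
  expect_equal(det$median, 0.6)
  expect_equal(det$min, 0.2)
  expect_equal(det$max, 1.0)
  expect_equal(det$q1, unname(quantile(c(0.2, 0.4, 0.6, 0.8, 1.0), 0.25)))

  # single-element group: all five numbers equal
  pr1 <- pr[c(1, 6), ]
  s1 <- diameterSummary(detectionReport(1, 1, pr1))
  und <- s1[s1$group == "undetected", ]
  expect_true(all(und[c("min", "q1", "median", "q3", "max")] == 0.3))
})

test_that("quartiles equal a sort-based oracle on a random set", {
  set.seed(99)
  x <- round(runif(100, 0.1, 1.5), 3)
  pr <- data.frame(id = seq_along(x), class = "crown", diameter_mm = x,
                   coverage = 1, detected = TRUE)
  s <- diameterSummary(detectionReport(length(x), 0, pr))
  det <- s[s$group == "detected", ]
  xs <- sort(x)
  # type-7: linear interpolation between closest ranks
  q <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(det$q1, q(0.25))
  expect_equal(det$median, q(0.5))
  expect_equal(det$q3, q(0.75))
  # empty complementary group is reported, not dropped
  expect_equal(s[s$group == "undetected", "n"], 0L)
})

test_that("kernel sweep: kernel 1 equals the unfiltered CNR, duplicates warn", {
  cfg <- small_phantom_config(soilSd = 500)
  r <- renderVolume(generateRootSystem(cfg), cfg)
  mk <- phantomMasks(r, cfg)
  sw <- kernelSweep(r$volume, mk$root, mk$soil, kernels = c(1L, 3L))
  expect_equal(sw$cnr[sw$kernel == 1], cnr(r$volume, mk$root, mk$soil))
  expect_warning(kernelSweep(r$volume, mk$root, mk$soil,
                             kernels = c(1L, 1L, 3L)), "duplicate")
})
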