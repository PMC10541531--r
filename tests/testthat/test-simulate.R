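test_that("scan pairs are deterministic under a fixed seed", {
  spec <- miniPhantomSpec(countScale = 20, seed = 77L)
  p1 <- simulateScanPair(spec)
  p2 <- simulateScanPair(spec)
  expect_identical(imgData(p1@volumeNoASC), imgData(p2@volumeNoASC))
  expect_identical(imgData(p1@volumeASC), imgData(p2@volumeASC))
  # the two arms draw independent noise (different sub-seeds)
  expect_false(identical(imgData(p1@volumeNoASC), imgData(p1@volumeASC)))
})

test_that("with the true contour and no scatter the ASC arm is the blurred activity", {
  spec <- miniPhantomSpec()     # noise-free
  spec@scatterFraction <- 0
  tc <- bodyContourFromMask(SpectASC:::brainMask(spec), spec@voxelSize)
  pair <- simulateScanPair(spec, contour = tc)
  blurred <- gaussianBlur(buildActivityMap(spec), spec@psfFWHM)
  interior <- ellipsoidMask(spec@gridShape, 2, c(0, 0, 0),
                            spec@brainSemiAxes - 8)
  rel <- abs(imgData(pair@volumeASC)[interior] - imgData(blurred)[interior]) /
    imgData(blurred)[interior]
  expect_lt(max(rel), 1e-6)
  # attenuation suppresses the center: putamen mean ordering
  m <- pair@masks$putamen_left
  expect_lt(mean(imgData(pair@volumeNoASC)[m]), mean(imgData(pair@volumeASC)[m]))
})

test_that("attenuation and scatter reduce putamen-to-reference contrast", {
  pair <- miniPair()    # noise-free, default scatter
  contrast <- function(v) {
    mean(imgData(v)[pair@masks$putamen_left]) /
      mean(imgData(v)[pair@masks$reference])
  }
  expect_lt(contrast(pair@volumeNoASC), contrast(pair@volumeASC))
})

test_that("the simulated reader applies threshold, bias and tie rules", {
  m <- ReaderModel(threshold = 0.9)
  expect_equal(simulateReader(c(0.89, 0.9, 0.91), m),
               c("reduced", "normal", "normal"))
  mb <- ReaderModel(threshold = 0.9, bias = 0.05)
  expect_equal(simulateReader(0.87, mb), "normal")
  # enormous perceptual noise: agreement with the noiseless reader ~ chance
  set.seed(15)
  sbr <- runif(1e4, 0.4, 1.4)
  noisy <- simulateReader(sbr, ReaderModel(threshold = 0.9, noiseSD = 100,
                                           seed = 8L))
  clean <- simulateReader(sbr, ReaderModel(threshold = 0.9))
  agree <- mean(noisy == clean)
  expect_gt(agree, 0.45); expect_lt(agree, 0.55)
})

test_that("cohort truth tables honor prevalence and class distributions", {
  co0 <- CohortSpec(nScans = 40L, prevalenceReduced = 0, seed = 3L)
  expect_true(all(simulateCohort(co0, volumes = FALSE)$truth$truth_class ==
                    "normal"))
  co <- CohortSpec(nScans = 2000L, seed = 19L)
  tt <- simulateCohort(co, volumes = FALSE)$truth
  worse <- pmin(tt$true_sbr_left, tt$true_sbr_right)
  for (cls in c("normal", "reduced")) {
    x <- worse[tt$truth_class == cls]
    mu <- if (cls == "normal") 1.577 else 0.579
    sd <- if (cls == "normal") 0.320 else 0.157
    expect_lt(abs(mean(x) - mu), 3 * sd / sqrt(length(x)))
  }
  # the better hemisphere is scaled by the asymmetry factor
  better <- pmax(tt$true_sbr_left, tt$true_sbr_right)
  expect_equal(better, worse * 1.3, tolerance = 1e-12)
  # fixed seed reproduces the truth table exactly
  expect_identical(tt, simulateCohort(co, volumes = FALSE)$truth)
})

test_that("cohort scan volumes validate and reproduce under the seed rule", {
  ph <- PhantomSpec(gridShape = c(48L, 52L, 40L), brainSemiAxes = c(42, 46, 34),
                    countScale = 20)
  co <- CohortSpec(nScans = 2L, phantom = ph, seed = 5L)
  s1 <- simulateCohort(co)
  expect_length(s1$scans, 2)
  for (p in s1$scans) expect_true(validObject(p))
  s2 <- simulateCohort(co)
  expect_identical(imgData(s1$scans[[2]]@volumeNoASC),
                   imgData(s2$scans[[2]]@volumeNoASC))
})
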