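test_that("survival factors have the closed form at a disc center", {
  d <- cachedDisc()
  A <- imgData(d$A)
  ctr <- c(32L, 32L, 32L)   # voxel at (-1, -1) mm: essentially the center
  # every ray from the center travels ~R; the moment-fit radius is within
  # a fraction of a voxel of the true R
  expect_equal(A[ctr[1], ctr[2], ctr[3]], exp(-0.146 * d$R / 10),
               tolerance = 2e-2)
  # bounds and monotonicity toward the center of a convex body
  expect_true(all(A > 0 & A <= 1))
  edgeVox <- which(d$co > 44 & d$co < 49)[1]
  expect_lt(A[ctr[1], ctr[2], 32], A[edgeVox, 32L, 32])
})

test_that("mu -> 0 gives survival factors -> 1", {
  d <- discPhantom(R = 20, gs = c(32L, 32L, 5L), kRange = 2:4)
  ct <- bodyContourFromMask(d$mask, 2)
  A <- attenuationFactors(ct, AttenuationModel(muPerCm = 1e-9))
  expect_equal(max(abs(imgData(A) - 1)), 0, tolerance = 1e-8)
})

test_that("angle-averaged factors agree with dense-angle and sampled-ray oracles", {
  d <- discPhantom(R = 24, gs = c(32L, 32L, 3L), kRange = 2L)
  ct <- bodyContourFromMask(d$mask, 2, minVoxels = 3L)
  A64 <- attenuationFactors(ct, AttenuationModel(nAngles = 64L))
  A4096 <- attenuationFactors(ct, AttenuationModel(nAngles = 4096L))
  inmask <- contourMask(ct)
  expect_lt(max(abs(imgData(A64)[inmask] - imgData(A4096)[inmask])), 1e-3)

  # independent fixed-step mask-walking tracer (1 mm steps)
  As <- SpectASC:::sampledAttenuationFactors(ct, AttenuationModel(nAngles = 32L))
  A32 <- attenuationFactors(ct, AttenuationModel(nAngles = 32L))
  expect_lt(max(abs(imgData(A32)[inmask] - imgData(As)[inmask])), 0.02)

  # convergence in the number of angles
  errs <- vapply(c(8L, 16L, 32L, 64L), function(m) {
    Am <- attenuationFactors(ct, AttenuationModel(nAngles = m))
    max(abs(imgData(Am)[inmask] - imgData(A4096)[inmask]))
  }, 1.0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("Chang correction inverts the forward factors exactly", {
  d <- cachedDisc()
  rec <- changCorrection(d$fwd, d$contour, AttenuationModel())
  expect_lt(max(abs(imgData(rec)[d$mask] - d$act[d$mask])), 1e-6)
  # uniform disc: corrected image is maximal at the center
  unif <- SpectVolume(d$mask * 1, 2)
  corr <- changCorrection(unif, d$contour, AttenuationModel())
  k <- 32L
  expect_equal(max(imgData(corr)[, , k]), imgData(corr)[32, 32, k])
})

test_that("the correction cap engages exactly where A < 1/cap", {
  d <- cachedDisc()
  cap <- 1.8
  corr <- changCorrection(d$fwd, d$contour, AttenuationModel(), cap = cap)
  A <- imgData(d$A)
  capped <- A < 1 / cap
  ratio <- imgData(corr) / pmax(imgData(d$fwd), 1e-12)
  expect_equal(ratio[capped & d$mask], rep(cap, sum(capped & d$mask)),
               tolerance = 1e-9)
  free <- !capped & d$mask
  expect_lt(max(abs(ratio[free] - 1 / A[free])), 1e-9)
})

test_that("delineation recovers the slice ellipses of a uniform ellipsoid", {
  gs <- c(70L, 86L, 60L); ba <- c(65, 80, 55)
  m <- ellipsoidMask(gs, 2, c(0, 0, 0), ba)
  v <- SpectVolume(m * 1, 2)
  dc <- delineateBodyContour(v)
  e <- contourEllipses(dc)
  z <- (e$slice - 1) * 2 - (gs[3] - 1)
  sel <- abs(z) < 0.3 * ba[3]   # equatorial band: slice geometry stable in z
  f <- sqrt(pmax(1 - (z[sel] / ba[3])^2, 0))
  expect_true(all(abs(e$a[sel] - ba[2] * f) <= 2))   # major axis within 1 voxel
  expect_true(all(abs(e$b[sel] - ba[1] * f) <= 2))   # minor axis within 1 voxel
  expect_true(all(abs(e$cx[sel]) < 1 & abs(e$cy[sel]) < 1))
})

test_that("delineation is equivariant under a 90-degree in-plane rotation", {
  gs <- c(64L, 64L, 20L)
  m <- ellipsoidMask(gs, 2, c(0, 0, 0), c(40, 55, 16))
  d1 <- delineateBodyContour(SpectVolume(m * 1, 2))
  d2 <- delineateBodyContour(SpectVolume(aperm(m, c(2, 1, 3)) * 1, 2))
  e1 <- contourEllipses(d1); e2 <- contourEllipses(d2)
  k <- 10L
  expect_equal(e2$a[e2$slice == k], e1$a[e1$slice == k], tolerance = 1e-2)
  expect_equal(e2$b[e2$slice == k], e1$b[e1$slice == k], tolerance = 1e-2)
})

test_that("slices without raw signal receive no ellipse", {
  a <- array(0, c(32L, 32L, 16L))
  a[10:22, 10:22, 8] <- 1
  dc <- delineateBodyContour(SpectVolume(a, 2))
  expect_equal(unique(contourEllipses(dc)$slice), 8L)
  expect_true(all(contourMask(dc)[, , -8] == FALSE))
  expect_error(delineateBodyContour(SpectVolume(array(0, c(4L, 4L, 4L)), 2)),
               "all-zero")
})
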