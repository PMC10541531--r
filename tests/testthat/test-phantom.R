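test_that("activity map is piecewise constant with the declared levels", {
  # degenerate spec: no structures
  spec <- PhantomSpec(gridShape = c(40L, 40L, 40L), brainSemiAxes = c(30, 32, 28),
                      backgroundActivity = 1.5)
  act <- buildActivityMap(spec)
  brain <- ellipsoidMask(spec@gridShape, 2, c(0, 0, 0), spec@brainSemiAxes)
  expect_true(all(imgData(act)[brain] == 1.5))
  expect_true(all(imgData(act)[!brain] == 0))

  # one putamen with true SBR 2 -> max voxel = 3 x background
  spec2 <- PhantomSpec(gridShape = c(40L, 40L, 40L), brainSemiAxes = c(30, 32, 28),
    structures = list(StriatalStructure("putamen", "left", c(-12, 0, 0),
                                        c(6, 9, 6), trueSBR = 2)))
  act2 <- buildActivityMap(spec2)
  expect_equal(max(imgData(act2)), 3 * spec2@backgroundActivity)
})

test_that("total activity equals the voxel-counting oracle", {
  structures <- list(
    StriatalStructure("putamen", "left", c(-12, 0, 0), c(6, 9, 6), 2),
    StriatalStructure("putamen", "right", c(12, 0, 0), c(6, 9, 6), 1.2),
    StriatalStructure("caudate", "left", c(-6, 10, 5), c(4, 6, 5), 0.8))
  spec <- PhantomSpec(gridShape = c(40L, 40L, 40L), brainSemiAxes = c(30, 32, 28),
                      structures = structures, backgroundActivity = 2)
  act <- buildActivityMap(spec)
  # independent count: background everywhere in brain plus sbr excess per
  # structure (structures are disjoint here)
  brain <- ellipsoidMask(spec@gridShape, 2, c(0, 0, 0), spec@brainSemiAxes)
  expected <- 2 * sum(brain)
  for (s in structures)
    expected <- expected +
      2 * s@trueSBR * sum(ellipsoidMask(spec@gridShape, 2, s@center, s@semiAxes))
  expect_equal(sum(imgData(act)), expected)
})

test_that("structures protruding from the brain are rejected by name", {
  expect_error(
    PhantomSpec(gridShape = c(40L, 40L, 40L), brainSemiAxes = c(30, 32, 28),
                structures = list(StriatalStructure("putamen", "right",
                                                    c(28, 0, 0), c(6, 9, 6), 1))),
    "right putamen")
})

test_that("reference mask shrinks monotonically with the margin", {
  spec <- PhantomSpec(structures = defaultStructures(putamenSBR = c(1, 1)))
  brain <- ellipsoidMask(spec@gridShape, 2, c(0, 0, 0), spec@brainSemiAxes)
  # margin 0, no structures -> reference is the whole brain
  bare <- PhantomSpec()
  expect_equal(makeReferenceMask(bare, margin = 0), brain)

  sizes <- vapply(c(0, 2, 4, 8), function(m) sum(makeReferenceMask(spec, m)),
                  1.0)
  expect_true(all(diff(sizes) < 0))

  # a 4 mm margin excludes a 2-voxel shell: the dilated structure is gone
  ref4 <- makeReferenceMask(spec, 4)
  s <- spec@structures[[1]]
  shell <- ellipsoidMask(spec@gridShape, 2, s@center, s@semiAxes + 4)
  expect_false(any(ref4 & shell))
})

test_that("putamen masks are oversized, unilateral, and avoid the caudate", {
  spec <- PhantomSpec(structures = defaultStructures(putamenSBR = c(1, 1)))
  pm <- makePutamenMasks(spec)
  vml <- 0.008
  expect_gt(sum(pm$left) * vml, 10)    # bigger than the 10 ml analysis volume
  expect_gt(sum(pm$right) * vml, 10)
  for (s in spec@structures[c(3, 4)]) {
    cm <- ellipsoidMask(spec@gridShape, 2, s@center, s@semiAxes)
    expect_false(any(pm$left & cm))
    expect_false(any(pm$right & cm))
  }
  # each mask fully contains its own putamen
  put <- spec@structures[[1]]
  putMask <- ellipsoidMask(spec@gridShape, 2, put@center, put@semiAxes)
  expect_true(all(pm$left[putMask]))
})
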