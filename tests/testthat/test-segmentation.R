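test_that("a noiseless two-level stack segments exactly to the ground truth", {
  ph <- straightTubePhantom(R = 0.1, L = 0.5, spacing_um = 12)
  seg <- segmentLumen(ph$stack, closeIter = 0)
  expect_identical(seg@voxels, ph$mask@voxels)
  # idempotence: re-segmenting the binary rendering returns the same mask
  bin <- new("ImageStack", voxels = array(as.numeric(seg@voxels),
                                          dim(seg@voxels)),
             spacing = seg@spacing, mask = logical(0), provenance = list())
  seg2 <- segmentLumen(bin, closeIter = 0)
  expect_identical(seg2@voxels, seg@voxels)
})

test_that("filtered noisy stacks segment with high Dice against ground truth", {
  tr <- vesselTree(list(straightSegment("descending_aorta",
                                        c(0.25, 0.25, 0.05),
                                        c(0.25, 0.25, 0.85), 0.12)))
  stk <- rasterizeStack(tr, spacing = 12, noiseSD = 0.2, seed = 11L)
  fl <- speckleFilter(stk, iterations = 10, conductance = 0.25)
  seg <- segmentLumen(fl)
  expect_gte(diceOverlap(seg@voxels, groundTruthMask(stk)), 0.95)
})

test_that("degenerate histograms fail explicitly instead of returning empty masks", {
  const <- new("ImageStack", voxels = array(0.5, c(10, 10, 10)),
               spacing = c(8, 8, 8), mask = logical(0), provenance = list())
  expect_error(segmentLumen(const), "single-mode")
  rng <- fetoflow:::setLocalSeed(1L)
  noise <- new("ImageStack",
               voxels = array(rnorm(1000, 0.5, 0.001), c(10, 10, 10)),
               spacing = c(8, 8, 8), mask = logical(0), provenance = list())
  fetoflow:::restoreSeed(rng)
  expect_error(segmentLumen(noise), "single-mode")
})

test_that("largest-component selection drops detached specks", {
  ph <- straightTubePhantom(R = 0.1, L = 0.5, spacing_um = 12)
  v <- ph$stack@voxels
  v[2, 2, 2] <- max(v)   # a detached bright voxel
  spk <- new("ImageStack", voxels = v, spacing = ph$stack@spacing,
             mask = logical(0), provenance = list())
  seg <- segmentLumen(spk, closeIter = 0)
  expect_false(seg@voxels[2, 2, 2])
  expect_equal(max(seg@labels), 1L)
})
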