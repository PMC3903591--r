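test_that("diffusion fixed points: constant images and zero iterations", {
  const <- new("ImageStack", voxels = array(0.4, c(8, 8, 8)),
               spacing = c(5, 5, 5), mask = logical(0), provenance = list())
  out <- speckleFilter(const, iterations = 15)
  expect_equal(out@voxels, const@voxels)
  tr <- vesselTree(list(straightSegment("arch", c(0.1, 0.1, 0.02),
                                        c(0.1, 0.1, 0.3), 0.05)))
  stk <- rasterizeStack(tr, spacing = 10, noiseSD = 0.2, seed = 2L)
  expect_identical(speckleFilter(stk, iterations = 0)@voxels, stk@voxels)
})

test_that("filtering reduces within-region variance while keeping edges in place", {
  tr <- vesselTree(list(straightSegment("descending_aorta",
                                        c(0.25, 0.25, 0.05),
                                        c(0.25, 0.25, 0.75), 0.12)))
  stk <- rasterizeStack(tr, spacing = 12, noiseSD = 0.2, seed = 3L)
  gt <- groundTruthMask(stk)
  fl <- speckleFilter(stk, iterations = 12, conductance = 0.25)
  core <- fetoflow:::erode6(gt, 2L)          # away from the edge
  bgCore <- fetoflow:::erode6(!gt, 2L)
  vr <- function(v) c(var(v[core]), var(v[bgCore]))
  v0 <- vr(stk@voxels); v1 <- vr(fl@voxels)
  expect_lt(v1[1], 0.5 * v0[1])
  expect_lt(v1[2], 0.5 * v0[2])
  # the 50%-level edge surface stays within one voxel of the true edge:
  # every post-filter above-midlevel voxel is within the 1-voxel dilated
  # true lumen, and the eroded true lumen stays above midlevel
  mid <- (mean(fl@voxels[gt]) + mean(fl@voxels[!gt])) / 2
  seg <- fl@voxels > mid
  expect_true(all(!seg[!fetoflow:::dilate6(gt, 1L)]))
  expect_true(all(seg[fetoflow:::erode6(gt, 1L)]))
})

test_that("diffusion preserves the intensity range and conserves total intensity", {
  tr <- vesselTree(list(straightSegment("arch", c(0.15, 0.15, 0.03),
                                        c(0.15, 0.15, 0.4), 0.06)))
  stk <- rasterizeStack(tr, spacing = 12, noiseSD = 0.25, seed = 6L)
  fl <- speckleFilter(stk, iterations = 20, conductance = 0.3)
  expect_gte(min(fl@voxels), min(stk@voxels) - 1e-12)
  expect_lte(max(fl@voxels), max(stk@voxels) + 1e-12)
  expect_lt(abs(sum(fl@voxels) - sum(stk@voxels)) / sum(stk@voxels), 1e-3)
})

test_that("invalid inputs are rejected", {
  bad <- new("ImageStack", voxels = array(0.5, c(4, 4, 4)),
             spacing = c(5, 5, 5), mask = logical(0), provenance = list())
  bad@voxels[1] <- NaN
  expect_error(speckleFilter(bad), "non-finite")
  ok <- new("ImageStack", voxels = array(0.5, c(4, 4, 4)),
            spacing = c(5, 5, 5), mask = logical(0), provenance = list())
  expect_error(speckleFilter(ok, step = 0.5), "stability")
  expect_error(speckleFilter(ok, iterations = -1), "iterations")
})
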