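test_that("trees are deterministic for a fixed seed and anchored at the DAo", {
  cfg <- makeStageConfig(18.5, seed = 42L)
  t1 <- generateVesselTree(cfg)
  t2 <- generateVesselTree(cfg)
  expect_identical(t1@segments, t2@segments)
  expect_identical(t1@junctions, t2@junctions)
  # descending-aorta diameter equals the configured anchor exactly
  expect_equal(2 * max(t1@segments$descending_aorta$radius), 0.573)
  t3 <- generateVesselTree(makeStageConfig(18.5, seed = 43L))
  expect_false(identical(t1@segments, t3@segments))
})

test_that("mean cross-sectional areas grow strictly with gestational age", {
  ages <- c(14.5, 15.5, 16.5, 17.5, 18.5)
  trees <- lapply(ages, function(a) generateVesselTree(makeStageConfig(a, seed = 7L)))
  for (role in names(trees[[1]]@segments)) {
    areas <- vapply(trees, meanSegmentArea, numeric(1), role = role)
    expect_true(all(diff(areas) > 0), info = role)
  }
})

test_that("tree invariants hold: positive radii, ellipticity in (0,1], angles in (0,180]", {
  tr <- generateVesselTree(makeStageConfig(16.5, seed = 3L))
  for (s in tr@segments) {
    expect_true(all(s$radius > 0))
    expect_true(all(s$ellipticity > 0 & s$ellipticity <= 1))
  }
  expect_true(all(tr@junctions$angleDeg > 0 & tr@junctions$angleDeg <= 180))
  expect_true(validObject(tr))
})

test_that("ductus insertion angle moves toward parallel with age and branch zones flatten", {
  ages <- c(14.5, 15.5, 16.5, 17.5, 18.5)
  angs <- vapply(ages, function(a) {
    tr <- generateVesselTree(makeStageConfig(a, seed = 5L))
    tr@junctions$angleDeg[tr@junctions$child == "ductus"]
  }, numeric(1))
  expect_true(all(diff(angs) > 0))
  expect_gt(angs[1], 90); expect_lte(angs[5], 180)
  # ellipticity dips below the baseline proximal to arch branch ostia,
  # with the elongation axis along the branch direction (+z)
  tr <- generateVesselTree(makeStageConfig(16.5, seed = 5L))
  arch <- tr@segments$arch
  expect_lt(min(arch$ellipticity), 0.75)
  iDip <- which.min(arch$ellipticity)
  expect_gt(abs(arch$elongAxis[iDip, 3]), 0.9)
})

test_that("overlapping-segment configurations are rejected", {
  a <- straightSegment("descending_aorta", c(0, 0, 0), c(0, 0, 1), 0.2)
  b <- straightSegment("pulmonary_trunk", c(0.05, 0, 0), c(0.05, 0, 1), 0.2)
  tr <- vesselTree(list(a, b))
  expect_error(fetoflow:::checkNoOverlap(tr), "overlap")
})
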