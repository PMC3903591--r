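test_that("circular tubes give the circle area and near-unit aspect ratio", {
  h <- 0.010
  ph <- straightTubePhantom(R = 0.14, L = 0.9, spacing_um = h * 1000)
  org <- ph$origin
  cl <- extractCenterline(ph$mask, list(c(0.3, 0.3, 0.07) - org,
                                        c(0.3, 0.3, 0.93) - org))
  sm <- sectionMetrics(cl, ph$mask, stations = seq(0.2, 0.6, by = 0.1))
  expect_true(all(abs(sm$area_mm2 / (pi * 0.14^2) - 1) < 0.03))
  expect_true(all(sm$aspect_ratio > 0.95))
  expect_true(all(sm$area_mm2 <= pi / 4 * sm$d_max_mm^2))
  expect_false(any(sm$flagged))
})

test_that("elliptical tubes recover the imposed aspect ratio and elongation axis", {
  h <- 0.010
  ph <- straightTubePhantom(R = 0.14, L = 0.9, spacing_um = h * 1000,
                            ellipticity = 0.7, elongAxis = c(1, 0, 0))
  org <- ph$origin
  cl <- extractCenterline(ph$mask, list(c(0.3, 0.3, 0.07) - org,
                                        c(0.3, 0.3, 0.93) - org))
  sm <- sectionMetrics(cl, ph$mask, stations = seq(0.2, 0.6, by = 0.1))
  expect_true(all(abs(sm$aspect_ratio - 0.7) < 0.02))
  angle <- acos(pmin(abs(sm$elong_x), 1)) * 180 / pi
  expect_true(all(angle < 15))
})

test_that("aspect ratio is invariant under rigid rotation of the volume", {
  h <- 0.010
  # same elliptical tube, elongation axis rotated 90 degrees in-plane
  phA <- straightTubePhantom(R = 0.12, L = 0.7, spacing_um = h * 1000,
                             ellipticity = 0.75, elongAxis = c(1, 0, 0))
  phB <- straightTubePhantom(R = 0.12, L = 0.7, spacing_um = h * 1000,
                             ellipticity = 0.75, elongAxis = c(0, 1, 0))
  aspect <- function(ph) {
    org <- ph$origin
    cl <- extractCenterline(ph$mask, list(c(0.3, 0.3, 0.07) - org,
                                          c(0.3, 0.3, 0.73) - org))
    mean(sectionMetrics(cl, ph$mask,
                        stations = c(0.25, 0.35, 0.45))$aspect_ratio)
  }
  expect_equal(aspect(phA), aspect(phB), tolerance = 0.03)
})

test_that("stations outside the arclength range are rejected", {
  pts <- cbind(0, 0, seq(0, 1, length.out = 20))
  cl <- pointsCenterline(pts)
  m <- array(TRUE, c(5, 5, 5))
  msk <- new("SegmentationMask", voxels = m, spacing = c(10, 10, 10),
             labels = array(1L, c(5, 5, 5)))
  expect_error(sectionMetrics(cl, msk, stations = 2), "outside")
})

test_that("branch-zone ellipticity and elongation direction are recovered from the generator", {
  h <- 0.012
  cfg <- makeStageConfig(16.5, seed = 8L)
  tr <- generateVesselTree(cfg, jitterCV = 0)
  # rasterize the arch alone and measure sections near the carotid ostium
  arch <- tr@segments$arch
  ph <- phantomMask(vesselTree(list(arch)), h * 1000)
  org <- ph$origin
  cl <- extractCenterline(ph$mask,
                          list(arch$points[3, ] - org,
                               arch$points[nrow(arch$points) - 2, ] - org))
  lcc <- tr@landmarks[tr@landmarks$name == "left_common_carotid_ostium", ]
  sts <- seq(max(0.05, lcc$arclength - 0.15), lcc$arclength + 0.15,
             by = 0.03)
  sm <- sectionMetrics(cl, ph$mask, stations = sts)
  expect_lt(abs(min(sm$aspect_ratio) - 0.70), 0.05)
  # elongation at the flattest section points along the branch direction
  # (+z projected into the section plane)
  iMin <- which.min(sm$aspect_ratio)
  s0 <- sm$location[iMin]
  at <- function(s) vapply(1:3, function(c3)
    approx(cl@arclength, cl@points[, c3], s)$y, numeric(1))
  tg <- at(s0 + 0.05) - at(s0 - 0.05); tg <- tg / sqrt(sum(tg^2))
  ez <- c(0, 0, 1)
  proj <- ez - sum(ez * tg) * tg; proj <- proj / sqrt(sum(proj^2))
  rec <- c(sm$elong_x[iMin], sm$elong_y[iMin], sm$elong_z[iMin])
  expect_lt(acos(pmin(abs(sum(rec * proj)), 1)) * 180 / pi, 15)
})
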