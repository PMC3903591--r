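test_that("a straight cylinder's centerline tracks the true axis within half a voxel", {
  h <- 0.012
  ph <- straightTubePhantom(R = 0.14, L = 1.1, spacing_um = h * 1000)
  org <- ph$origin
  cl <- extractCenterline(ph$mask, list(c(0.3, 0.3, 0.07) - org,
                                        c(0.3, 0.3, 1.13) - org))
  ax <- c(0.3, 0.3) - org[1:2]
  dev <- sqrt((cl@points[, 1] - ax[1])^2 + (cl@points[, 2] - ax[2])^2)
  expect_lt(max(dev), 0.5 * h)
  # mid-vessel inscribed-sphere radius near the true radius
  mid <- cl@arclength > 0.3 & cl@arclength < 0.7
  expect_equal(mean(cl@radius[mid]), 0.14, tolerance = 0.1)
  expect_true(all(diff(cl@arclength) > 0))
})

test_that("a torus-segment tube recovers the bend radius within 2 percent", {
  h <- 0.012; Rb <- 0.45
  arc <- arcSegment("arch", center = c(0.6, 0.6, 0.1), radius = Rb,
                    axisU = c(1, 0, 0), axisV = c(0, 0, 1),
                    phi0 = pi, phi1 = pi / 2, r0 = 0.12, n = 61)
  ph <- phantomMask(vesselTree(list(arc)), h * 1000)
  org <- ph$origin
  cl <- extractCenterline(ph$mask, list(arc$points[2, ] - org,
                                        arc$points[60, ] - org))
  # distances from the known bend center (analytic arc oracle)
  ctr <- c(0.6, 0.6, 0.1) - org
  rad <- sqrt((cl@points[5:95, 1] - ctr[1])^2 +
                (cl@points[5:95, 3] - ctr[3])^2)
  expect_lt(abs(mean(rad) / Rb - 1), 0.02)
  expect_lt(max(abs(cl@points[, 2] - ctr[2])), h)
})

test_that("a Y-junction yields exactly one detected bifurcation", {
  h <- 0.012
  stem <- straightSegment("descending_aorta", c(0.4, 0.3, 0.05),
                          c(0.4, 0.3, 0.55), 0.1)
  b1 <- straightSegment("innominate", c(0.4, 0.3, 0.55),
                        c(0.15, 0.3, 0.95), 0.07)
  b2 <- straightSegment("left_common_carotid", c(0.4, 0.3, 0.55),
                        c(0.65, 0.3, 0.95), 0.07)
  ph <- phantomMask(vesselTree(list(stem, b1, b2)), h * 1000)
  org <- ph$origin
  res <- extractCenterline(ph$mask, list(c(0.4, 0.3, 0.07) - org,
                                         c(0.16, 0.3, 0.93) - org,
                                         c(0.64, 0.3, 0.93) - org))
  expect_equal(nrow(res$bifurcations), 1L)
  # the bifurcation lies on the stem axis near the geometric junction
  bif <- res$bifurcations[1, ] + org
  expect_lt(sqrt(sum((bif[1:2] - c(0.4, 0.3))^2)), 0.03)
  expect_lt(abs(bif[3] - 0.55), 0.12)
})

test_that("disconnected lumens are rejected", {
  m <- array(FALSE, c(20, 20, 20))
  m[4:6, 4:6, 4:6] <- TRUE
  m[14:16, 14:16, 14:16] <- TRUE
  msk <- new("SegmentationMask", voxels = m, spacing = c(10, 10, 10),
             labels = fetoflow:::label6(m))
  expect_error(extractCenterline(msk, list(c(0.04, 0.04, 0.04),
                                           c(0.14, 0.14, 0.14))),
               "disconnected")
})
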