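# Shared phantom builders for the test suite. All fixtures are generated
# in code; nothing is read from disk.

# Ground-truth SegmentationMask from a rasterized tree (noiseless render).
phantomMask <- function(tree, spacing_um, margin = 0.06) {
  stk <- rasterizeStack(tree, spacing = spacing_um, noiseSD = 0, seed = 1,
                        margin = margin)
  gt <- groundTruthMask(stk)
  list(mask = new("SegmentationMask", voxels = gt, spacing = stk@spacing,
                  labels = array(as.integer(gt), dim(gt))),
       origin = stk@provenance$origin, stack = stk)
}

# Straight circular tube phantom along z.
straightTubePhantom <- function(R = 0.14, L = 0.9, spacing_um = 10,
                                ellipticity = 1, elongAxis = NULL) {
  seg <- straightSegment("descending_aorta", c(0.3, 0.3, 0.05),
                         c(0.3, 0.3, 0.05 + L), R, R,
                         ellipticity = ellipticity, elongAxis = elongAxis)
  c(phantomMask(vesselTree(list(seg)), spacing_um), list(seg = seg))
}

# Geometric circle fit: mean distance to the best-fit center (planar).
fitCircleRadius <- function(xy) {
  obj <- function(ctr) {
    d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    stats::var(d)
  }
  fit <- stats::optim(colMeans(xy), obj)
  mean(sqrt((xy[, 1] - fit$par[1])^2 + (xy[, 2] - fit$par[2])^2))
}

# Analytic centerline as a Centerline object from raw points.
pointsCenterline <- function(pts, radius = 0.1) {
  sl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  sl <- sl + seq_along(sl) * max(sl, 1) * 1e-12
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[3:nrow(pts), ] - pts[1:(nrow(pts) - 2), ],
              pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  new("Centerline", points = pts, tangents = tg, arclength = sl,
      radius = rep(radius, length.out = nrow(pts)),
      branchIds = rep(0L, nrow(pts)))
}

# Reference blood properties used across solver tests.
testProps <- function() viscosityFromHct(0.35)
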