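# Voxelization of a vessel tree into an episcopic-like grayscale stack:
# lumen and tissue intensity classes plus multiplicative speckle noise, with
# the exact generating mask retained as ground truth.

#' Rasterize a vessel tree into an image stack
#'
#' Renders the swept-ellipse tube tree on a regular voxel grid. Lumen voxels
#' take the lumen mean intensity and tissue (background) voxels the tissue
#' mean, separated by \code{contrast}; multiplicative lognormal speckle of
#' coefficient of variation \code{noiseSD} (mean 1) is applied on top. The
#' analytic interior mask is retained in the result.
#'
#' @param tree a \linkS4class{VesselTree} (or a single-segment tree from the
#'   segment constructors wrapped with \code{\link{vesselTree}}).
#' @param spacing voxel size, micrometres; scalar or length-3
#'   (slice, row, col). The recommended range is 2--10 um for full
#'   episcopic realism; coarser spacings are useful desk-scale.
#' @param contrast intensity difference between lumen and tissue means.
#' @param noiseSD coefficient of variation of the multiplicative speckle.
#' @param seed RNG seed for the speckle.
#' @param margin padding around the tree bounding box, mm.
#' @param dims optional fixed grid dimensions; if the tree (plus margin)
#'   does not fit, rasterization is rejected.
#' @param tissueMean tissue (background) mean intensity.
#' @return an \linkS4class{ImageStack}; \code{provenance} records the grid
#'   origin (mm), noise parameters and generating seed.
#' @export
rasterizeStack <- function(tree, spacing = 8, contrast = 0.5, noiseSD = 0.1,
                           seed = 1L, margin = 0.08, dims = NULL,
                           tissueMean = 0.3) {
  spacing <- rep(spacing, length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  h <- spacing / 1000   # mm
  segs <- tree@segments
  allPts <- do.call(rbind, lapply(segs, `[[`, "points"))
  maxR <- max(vapply(segs, function(s) max(s$radius / sqrt(s$ellipticity)),
                     numeric(1)))
  lo <- apply(allPts, 2, min) - maxR - margin
  hi <- apply(allPts, 2, max) + maxR + margin
  need <- ceiling((hi - lo) / h) + 1
  if (is.null(dims)) {
    d <- as.integer(need)
  } else {
    d <- as.integer(rep(dims, length.out = 3))
    if (any(need > d))
      stop("tree (with margin) larger than requested grid: needs ",
           paste(need, collapse = "x"), ", given ", paste(d, collapse = "x"))
  }
  origin <- lo
  mask <- array(FALSE, d)

  for (s in segs) {
    pts <- s$points
    sl <- segArclength(s)
    ds <- min(h) / 2
    nS <- max(2L, ceiling(max(sl) / ds) + 1L)
    su <- seq(0, max(sl), length.out = nS)
    ds <- su[2] - su[1]
    P <- apply(pts, 2, function(col) approx(sl, col, su)$y)
    R <- approx(sl, s$radius, su)$y
    E <- approx(sl, s$ellipticity, su)$y
    EA <- apply(s$elongAxis, 2, function(col) approx(sl, col, su)$y)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    tg <- segTangents(P)
    for (k in seq_len(nS)) {
      c0 <- P[k, ]; tk <- tg[k, ]
      a <- R[k] / sqrt(E[k]); b <- R[k] * sqrt(E[k])
      ek <- EA[k, ]
      if (sqrt(sum(ek^2)) < 1e-6) {
        ek <- if (abs(tk[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      }
      e1 <- ek - sum(ek * tk) * tk
      if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(tk[2], -tk[1], 0)
      e1 <- unitize(e1)
      e2 <- c(tk[2] * e1[3] - tk[3] * e1[2],
              tk[3] * e1[1] - tk[1] * e1[3],
              tk[1] * e1[2] - tk[2] * e1[1])
      w <- a + max(h)
      rng <- lapply(1:3, function(ax) {
        i0 <- max(1L, floor((c0[ax] - w - origin[ax]) / h[ax]) + 1L)
        i1 <- min(d[ax], ceiling((c0[ax] + w - origin[ax]) / h[ax]) + 1L)
        if (i0 > i1) integer(0) else i0:i1
      })
      if (any(lengths(rng) == 0)) next
      xs <- origin[1] + (rng[[1]] - 1) * h[1] - c0[1]
      ys <- origin[2] + (rng[[2]] - 1) * h[2] - c0[2]
      zs <- origin[3] + (rng[[3]] - 1) * h[3] - c0[3]
      axial <- outer(outer(xs * tk[1], ys * tk[2], "+"), zs * tk[3], "+")
      d1 <- outer(outer(xs * e1[1], ys * e1[2], "+"), zs * e1[3], "+")
      d2 <- outer(outer(xs * e2[1], ys * e2[2], "+"), zs * e2[3], "+")
      inside <- (abs(axial) <= 0.75 * ds) & ((d1 / a)^2 + (d2 / b)^2 <= 1)
      if (any(inside)) {
        sub <- mask[rng[[1]], rng[[2]], rng[[3]]]
        mask[rng[[1]], rng[[2]], rng[[3]]] <- sub | inside
      }
    }
  }

  vox <- array(tissueMean, d)
  vox[mask] <- tissueMean + contrast
  if (noiseSD > 0) {
    rng0 <- setLocalSeed(seed)
    on.exit(restoreSeed(rng0), add = TRUE)
    sig <- sqrt(log(1 + noiseSD^2))
    vox <- vox * array(rlnorm(length(vox), -sig^2 / 2, sig), d)
  }
  new("ImageStack", voxels = vox, spacing = spacing,
      mask = as.logical(mask),
      provenance = list(origin = origin, seed = as.integer(seed),
                        noiseSD = noiseSD, contrast = contrast,
                        tissueMean = tissueMean,
                        treeAge = tree@ageDays, treeSeed = tree@seed))
}
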