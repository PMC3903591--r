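# Centerline extraction from segmented lumens: interior Euclidean distance
# transform, ridge-weighted shortest path between declared endpoints
# (maximal-inscribed-sphere centers), smoothing and resampling.

# Map physical mm coordinates to nearest in-mask voxel index.
.snapToMask <- function(mask, spacing, origin, p) {
  d <- dim(mask)
  h <- spacing / 1000
  ijk <- round((p - origin) / h) + 1
  ijk <- pmin(pmax(ijk, 1), d)
  if (mask[ijk[1], ijk[2], ijk[3]]) return(ijk)
  idx <- which(mask)
  pos <- arrayInd(idx, d)
  # coordinates of voxel centers are origin + (pos - 1) * h
  pc <- cbind((pos[, 1] - 1) * h[1] + origin[1],
              (pos[, 2] - 1) * h[2] + origin[2],
              (pos[, 3] - 1) * h[3] + origin[3])
  pos[which.min(colSums((t(pc) - p)^2)), ]
}

#' Extract a vessel centerline between declared endpoints
#'
#' Computes the interior Euclidean distance transform of the lumen, then
#' follows the distance ridge between the endpoints via a shortest path on
#' the 26-connected voxel graph with edge weights penalizing departure
#' from the ridge; the path is smoothed and resampled, and the
#' maximal-inscribed-sphere radius is recorded per point.
#'
#' When more than two endpoints are given (a root plus several leaves), a
#' path is traced from the root to each leaf and the result is a list with
#' per-leaf \code{centerlines} and detected \code{bifurcations} (points
#' where paths diverge).
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param endpoints list of 3D points, mm (root first). The lumen must be
#'   connected between them.
#' @param origin grid origin, mm (default 0; use the stack provenance
#'   origin when the mask comes from a rasterized tree).
#' @param nSample number of resampled centerline points.
#' @param smoothIter smoothing passes applied to the raw voxel path.
#' @return a \linkS4class{Centerline}, or a list for > 2 endpoints.
#' @export
extractCenterline <- function(mask, endpoints, origin = c(0, 0, 0),
                              nSample = 100L, smoothIter = 10L) {
  if (length(endpoints) < 2) stop("need at least a root and one leaf endpoint")
  vox <- mask@voxels
  d <- dim(vox)
  h <- mask@spacing / 1000
  lab <- label6(vox)
  snaps <- lapply(endpoints, function(p) .snapToMask(vox, mask@spacing,
                                                     origin, p))
  comp <- vapply(snaps, function(s) lab[s[1], s[2], s[3]], integer(1))
  if (length(unique(comp)) != 1)
    stop("disconnected lumen: endpoints lie in different components")

  dt <- edt3d(vox, h)
  dtMax <- max(dt)
  idx <- which(vox)
  id <- array(0L, d); id[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  # 26-neighborhood edges (13 unique offsets)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[1:(nrow(offs) / 2), ]
  el <- list(); wl <- list()
  for (q in seq_len(nrow(offs))) {
    o <- offs[q, ]
    p2 <- sweep(pos, 2, o, `+`)
    ok <- p2[, 1] >= 1 & p2[, 1] <= d[1] & p2[, 2] >= 1 & p2[, 2] <= d[2] &
      p2[, 3] >= 1 & p2[, 3] <= d[3]
    j <- id[p2[ok, , drop = FALSE]]
    keep <- j > 0L
    a <- which(ok)[keep]; bIdx <- j[keep]
    len <- sqrt(sum((o * h)^2))
    dmid <- (dt[idx[a]] + dt[idx[bIdx]]) / 2
    el[[q]] <- cbind(a, bIdx)
    wl[[q]] <- len * (dtMax / pmax(dmid, 1e-9))^4
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  igraph::E(g)$weight <- unlist(wl)
  nv <- length(idx)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))

  vid <- function(s) id[s[1], s[2], s[3]]
  rootV <- vid(snaps[[1]])
  paths <- lapply(snaps[-1], function(s)
    as.integer(igraph::shortest_paths(g, rootV, vid(s))$vpath[[1]]))

  buildCl <- function(pv) {
    pp <- pos[pv, , drop = FALSE]
    xyz <- cbind((pp[, 1] - 1) * h[1] + origin[1],
                 (pp[, 2] - 1) * h[2] + origin[2],
                 (pp[, 3] - 1) * h[3] + origin[3])
    rad <- dt[idx[pv]]
    # laplacian smoothing with fixed ends
    n <- nrow(xyz)
    if (n >= 3 && smoothIter > 0) for (it in seq_len(smoothIter)) {
      xyz[2:(n - 1), ] <- 0.5 * xyz[2:(n - 1), ] +
        0.25 * (xyz[1:(n - 2), , drop = FALSE] +
                  xyz[3:n, , drop = FALSE])
      rad[2:(n - 1)] <- 0.5 * rad[2:(n - 1)] +
        0.25 * (rad[1:(n - 2)] + rad[3:n])
    }
    sl <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
    keepU <- !duplicated(sl)
    sl <- sl[keepU]; xyz <- xyz[keepU, , drop = FALSE]; rad <- rad[keepU]
    su <- seq(0, max(sl), length.out = nSample)
    ptsS <- apply(xyz, 2, function(col) approx(sl, col, su)$y)
    radS <- approx(sl, rad, su)$y
    slS <- c(0, cumsum(sqrt(rowSums(diff(ptsS)^2))))
    # enforce strict monotonicity after resampling
    eps <- max(slS) * 1e-9
    slS <- slS + seq_along(slS) * eps
    new("Centerline", points = ptsS, tangents = segTangents(ptsS),
        arclength = slS, radius = pmax(radS, 1e-9),
        branchIds = rep(0L, nrow(ptsS)))
  }

  if (length(paths) == 1) return(buildCl(paths[[1]]))

  # multiple leaves: find bifurcation points where paths diverge
  bifs <- list()
  for (a in seq_along(paths)) for (b in seq_len(a - 1)) {
    pa <- paths[[a]]; pb <- paths[[b]]
    shared <- intersect(pa, pb)
    # last common voxel along path a
    inB <- pa %in% shared
    lastCommon <- if (any(inB)) pa[max(which(inB))] else NA_integer_
    if (!is.na(lastCommon)) {
      pp <- pos[lastCommon, ]
      bifs[[length(bifs) + 1L]] <- c((pp[1] - 1) * h[1] + origin[1],
                                     (pp[2] - 1) * h[2] + origin[2],
                                     (pp[3] - 1) * h[3] + origin[3])
    }
  }
  bm <- if (length(bifs)) do.call(rbind, bifs) else matrix(numeric(0), 0, 3)
  # merge bifurcation points closer than 2 voxels
  if (nrow(bm) > 1) {
    keep <- rep(TRUE, nrow(bm))
    for (a in 2:nrow(bm)) for (b in 1:(a - 1)) {
      if (keep[b] && sqrt(sum((bm[a, ] - bm[b, ])^2)) < 2 * max(h))
        keep[a] <- FALSE
    }
    bm <- bm[keep, , drop = FALSE]
  }
  list(centerlines = lapply(paths, buildCl), bifurcations = bm)
}
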