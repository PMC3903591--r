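# Cross-section morphometry: per-station lumen area, Feret diameters,
# aspect ratio and elongation axis on planes orthogonal to the centerline.

# Trilinear interpolation of a 3D array at physical points (mm).
interp3 <- function(field, spacing, origin, pts) {
  d <- dim(field)
  h <- spacing / 1000
  gx <- (pts[, 1] - origin[1]) / h[1] + 1
  gy <- (pts[, 2] - origin[2]) / h[2] + 1
  gz <- (pts[, 3] - origin[3]) / h[3] + 1
  out <- rep(NA_real_, nrow(pts))
  ok <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2] & gz >= 1 & gz <= d[3]
  gx <- pmin(pmax(gx, 1), d[1] - 1e-9)
  gy <- pmin(pmax(gy, 1), d[2] - 1e-9)
  gz <- pmin(pmax(gz, 1), d[3] - 1e-9)
  x0 <- pmin(floor(gx), d[1] - 1); y0 <- pmin(floor(gy), d[2] - 1)
  z0 <- pmin(floor(gz), d[3] - 1)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    v <- v + w * field[cbind(x0 + dx, y0 + dy, z0 + dz)]
  }
  out[ok] <- v[ok]
  out
}

# One-step 4-neighborhood dilation of a 2D logical matrix.
dilate2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-n1, ]
  out[-n1, ] <- out[-n1, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -n2]
  out[, -n2] <- out[, -n2] | m[, -1]
  out
}

# Rotation-minimizing frames transported along a centerline.
.transportFrames <- function(points, tangents) {
  n <- nrow(points)
  u <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u[1, ] <- unitize(ref - sum(ref * t1) * t1)
  if (n > 1) for (i in 2:n) {
    ti <- tangents[i, ]
    ui <- u[i - 1, ] - sum(u[i - 1, ] * ti) * ti
    nu <- sqrt(sum(ui^2))
    u[i, ] <- if (nu < 1e-9) u[i - 1, ] else ui / nu
  }
  v <- cbind(tangents[, 2] * u[, 3] - tangents[, 3] * u[, 2],
             tangents[, 3] * u[, 1] - tangents[, 1] * u[, 3],
             tangents[, 1] * u[, 2] - tangents[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Cross-section metrics along a centerline
#'
#' For each requested station arclength, intersects the lumen with the
#' plane orthogonal to the centerline tangent and computes lumen area,
#' minimum and maximum Feret diameters, aspect ratio (d_min/d_max) and the
#' in-plane elongation (max-Feret) axis. Sections whose sampling window
#' leaves the grid are flagged rather than dropped.
#'
#' @param centerline a \linkS4class{Centerline}.
#' @param mask a \linkS4class{SegmentationMask}.
#' @param stations arclength positions, mm (default: every local radius).
#' @param origin grid origin, mm.
#' @param smoothSigma Gaussian smoothing (voxels) applied to the occupancy
#'   field before in-plane sampling.
#' @param windowFactor half-width of the in-plane sampling window in local
#'   radii.
#' @return data.frame: location, area_mm2, d_min_mm, d_max_mm,
#'   aspect_ratio, elong_x/y/z (3D elongation axis), flagged.
#' @export
sectionMetrics <- function(centerline, mask, stations = NULL,
                           origin = c(0, 0, 0), smoothSigma = 0.7,
                           windowFactor = 1.8) {
  sl <- centerline@arclength
  if (is.null(stations)) {
    stations <- numeric(0)
    s <- sl[1]
    while (s <= max(sl)) {
      stations <- c(stations, s)
      s <- s + approx(sl, centerline@radius, s, rule = 2)$y
    }
  }
  if (any(stations < sl[1] - 1e-9 | stations > max(sl) + 1e-9))
    stop("stations outside the centerline arclength range")
  vox <- mask@voxels
  h <- mask@spacing / 1000
  F <- gauss3d(array(as.numeric(vox), dim(vox)), smoothSigma)
  g <- min(h) / 1.6
  # station tangents by symmetric differences over +/- half a local radius:
  # voxel-scale wobble in the extracted path must not tilt section planes
  interpPt <- function(s) vapply(1:3, function(c3)
    approx(sl, centerline@points[, c3], pmin(pmax(s, sl[1]), max(sl)))$y,
    numeric(1))
  stTangents <- t(vapply(stations, function(s0) {
    w <- max(approx(sl, centerline@radius, s0, rule = 2)$y / 2,
             2 * max(sl) / length(sl))
    unitize(interpPt(s0 + w) - interpPt(s0 - w))
  }, numeric(3)))
  frames <- .transportFrames(
    t(vapply(stations, interpPt, numeric(3))), stTangents)
  out <- vector("list", length(stations))
  for (si in seq_along(stations)) {
    s0 <- stations[si]
    ctr <- interpPt(s0)
    uu <- frames$u[si, ]; vv <- frames$v[si, ]
    rad <- approx(sl, centerline@radius, s0)$y
    w <- windowFactor * rad
    gs <- seq(-w, w, by = g)
    gp <- expand.grid(a = gs, b = gs)
    pts <- cbind(ctr[1] + gp$a * uu[1] + gp$b * vv[1],
                 ctr[2] + gp$a * uu[2] + gp$b * vv[2],
                 ctr[3] + gp$a * uu[3] + gp$b * vv[3])
    val <- interp3(F, mask@spacing, origin, pts)
    inside <- !is.na(val) & val >= 0.5
    if (!any(inside)) {
      out[[si]] <- data.frame(location = s0, area_mm2 = 0, d_min_mm = 0,
                              d_max_mm = 0, aspect_ratio = NA_real_,
                              elong_x = NA_real_, elong_y = NA_real_,
                              elong_z = NA_real_, flagged = TRUE)
      next
    }
    # keep the connected in-plane region containing the centerline point
    ng <- length(gs)
    insM <- matrix(FALSE, ng, ng)
    insM[cbind(match(gp$a[inside], gs), match(gp$b[inside], gs))] <- TRUE
    labsM <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(insM * 1)))
    i0 <- which.min(abs(gs))
    ctrLab <- labsM[i0, i0]
    if (ctrLab == 0) ctrLab <- which.max(tabulate(labsM[labsM > 0]))
    insM <- labsM == ctrLab
    # flag truncated sections: the lumen region touches the sampling
    # window border or abuts samples outside the grid
    naM <- matrix(is.na(val), ng, ng)
    flagged <- any(insM[1, ]) || any(insM[ng, ]) || any(insM[, 1]) ||
      any(insM[, ng]) || any(dilate2(insM) & naM)
    area <- sum(insM) * g^2
    # sub-pixel boundary: linear 0.5-crossings of the sampled field along
    # grid rows and columns, restricted to the selected component
    V <- matrix(ifelse(is.na(val), 0, val), ng, ng)
    near <- dilate2(insM)
    bpts <- list()
    dh <- (V[-1, ] - 0.5) * (V[-ng, ] - 0.5) < 0 &
      (near[-1, ] | near[-ng, ])
    if (any(dh)) {
      ij <- which(dh, arr.ind = TRUE)
      tfrac <- (0.5 - V[ij]) / (V[cbind(ij[, 1] + 1, ij[, 2])] - V[ij])
      bpts[[1]] <- cbind(gs[ij[, 1]] + tfrac * g, gs[ij[, 2]])
    }
    dv <- (V[, -1] - 0.5) * (V[, -ng] - 0.5) < 0 &
      (near[, -1] | near[, -ng])
    if (any(dv)) {
      ij <- which(dv, arr.ind = TRUE)
      tfrac <- (0.5 - V[ij]) / (V[cbind(ij[, 1], ij[, 2] + 1)] - V[ij])
      bpts[[2]] <- cbind(gs[ij[, 1]], gs[ij[, 2]] + tfrac * g)
    }
    pp <- do.call(rbind, bpts)
    if (is.null(pp) || nrow(pp) < 3)
      pp <- cbind(gs[row(insM)[insM]], gs[col(insM)[insM]])
    hull <- pp[grDevices::chull(pp), , drop = FALSE]
    angs <- seq(0, pi, length.out = 181)[-181]
    widths <- vapply(angs, function(aa) {
      pr <- hull %*% c(cos(aa), sin(aa))
      max(pr) - min(pr)
    }, numeric(1))
    dmax <- max(widths)
    dmin <- min(widths)
    # elongation axis: principal axis of the filled region (second moments)
    rpts <- cbind(gs[row(insM)[insM]], gs[col(insM)[insM]])
    rc <- sweep(rpts, 2, colMeans(rpts))
    ev <- eigen(crossprod(rc) / nrow(rc), symmetric = TRUE)
    elong2d <- ev$vectors[, 1]
    elong3d <- elong2d[1] * uu + elong2d[2] * vv
    out[[si]] <- data.frame(location = s0, area_mm2 = area,
                            d_min_mm = dmin, d_max_mm = dmax,
                            aspect_ratio = dmin / dmax,
                            elong_x = elong3d[1], elong_y = elong3d[2],
                            elong_z = elong3d[3], flagged = flagged)
  }
  do.call(rbind, out)
}
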