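# Isosurface extraction from segmentation masks (marching tetrahedra on a
# lightly smoothed field) and branch clipping with hole capping.

# Cube corner offsets in binary order (index = 1 + x + 2y + 4z).
.cubeOffsets <- cbind(x = c(0, 1, 0, 1, 0, 1, 0, 1),
                      y = c(0, 0, 1, 1, 0, 0, 1, 1),
                      z = c(0, 0, 0, 0, 1, 1, 1, 1))

# Kuhn 6-tetrahedra decomposition of the unit cube: one tet per axis
# permutation, all sharing the (0,0,0)-(1,1,1) diagonal. Face diagonals are
# translation-invariant, so adjacent cubes tile compatibly (watertight).
.cubeTets <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(apply(perms, 1, function(p) {
    v <- matrix(0, 4, 3)
    for (s in 1:3) { v[s + 1, ] <- v[s, ]; v[s + 1, p[s]] <- 1 }
    1 + v[, 1] + 2 * v[, 2] + 4 * v[, 3]
  }))
})

# Per-case triangulation of one tetrahedron: for each inside-corner bitmask,
# a list of triangles given as 3 x 2 matrices of local corner-id pairs
# (each row = the tet edge the triangle vertex sits on), plus the inside
# corner ids used to orient the triangle outward.
.tetCases <- local({
  tbl <- vector("list", 16)
  for (m in 1:14) {
    ins <- which(bitwAnd(m, c(1, 2, 4, 8)) > 0)
    out <- setdiff(1:4, ins)
    tris <- list()
    if (length(ins) == 1) {
      tris <- list(rbind(c(ins, out[1]), c(ins, out[2]), c(ins, out[3])))
    } else if (length(ins) == 3) {
      tris <- list(rbind(c(ins[1], out), c(ins[2], out), c(ins[3], out)))
    } else if (length(ins) == 2) {
      v1 <- ins[1]; v2 <- ins[2]; o1 <- out[1]; o2 <- out[2]
      tris <- list(rbind(c(v1, o1), c(v2, o1), c(v2, o2)),
                   rbind(c(v1, o1), c(v2, o2), c(v1, o2)))
    }
    tbl[[m + 1]] <- list(tris = tris, inside = ins)
  }
  tbl
})

#' Extract a triangulated lumen surface from a mask
#'
#' Marching-tetrahedra isosurfacing at the 0.5 level of the (lightly
#' Gaussian-smoothed) binary mask, in physical mm coordinates with voxel
#' centers at 0-based index times spacing. The smoothing recovers sub-voxel
#' surface positions for smooth shapes; the mask is padded so the surface is
#' always closed.
#'
#' @param mask a \linkS4class{SegmentationMask} or a logical 3D array.
#' @param spacing voxel spacing in micrometres (required when \code{mask}
#'   is a bare array).
#' @param smoothSigma Gaussian pre-smoothing sigma in voxels (0 disables).
#' @param iso iso-level in the smoothed field.
#' @return a \linkS4class{SurfaceMesh} (closed; no open boundaries).
#' @export
extractSurface <- function(mask, spacing = NULL, smoothSigma = 0.9,
                           iso = 0.5) {
  if (is(mask, "SegmentationMask")) { spacing <- mask@spacing; mask <- mask@voxels }
  if (is.null(spacing)) stop("spacing required for bare-array masks")
  spacing <- rep(spacing, length.out = 3)
  if (!any(mask)) stop("empty mask")
  d0 <- dim(mask)
  h <- spacing / 1000
  pad <- max(2L, ceiling(3 * smoothSigma))
  d <- d0 + 2L * pad
  mp <- array(0, d)
  mp[pad + (1:d0[1]), pad + (1:d0[2]), pad + (1:d0[3])] <- as.numeric(mask)
  F <- if (smoothSigma > 0) gauss3d(mp, smoothSigma) else mp
  # tiny masks can smooth entirely below the iso level; fall back to the
  # raw occupancy field
  if (max(F) < iso) F <- mp
  F[abs(F - iso) < 1e-9] <- iso + 1e-8
  ins <- F >= iso

  # active cells: cube corners straddle the iso level
  d1 <- d[1]; d2 <- d[2]; d3 <- d[3]
  cnt <- array(0L, d - 1L)
  for (ci in 1:8) {
    o <- .cubeOffsets[ci, ]
    cnt <- cnt + ins[o[1] + 1:(d1 - 1), o[2] + 1:(d2 - 1), o[3] + 1:(d3 - 1)]
  }
  act <- which(cnt > 0L & cnt < 8L)
  if (!length(act)) stop("no iso-crossings found")
  pos <- arrayInd(act, d - 1L)
  ci <- pos[, 1]; cj <- pos[, 2]; ck <- pos[, 3]

  cornerLin <- function(o) (ci + o[1]) + (cj + o[2] - 1) * d1 +
    (ck + o[3] - 1) * d1 * d2
  cornerCoord <- function(o)
    cbind((ci + o[1] - 1 - pad) * h[1], (cj + o[2] - 1 - pad) * h[2],
          (ck + o[3] - 1 - pad) * h[3])

  fvals <- lapply(1:8, function(k) F[cornerLin(.cubeOffsets[k, ])])
  coords <- lapply(1:8, function(k) cornerCoord(.cubeOffsets[k, ]))

  triA <- triB <- triC <- list(); nt <- 0L
  for (tt in seq_len(nrow(.cubeTets))) {
    tv <- .cubeTets[tt, ]
    fb <- matrix(unlist(lapply(1:4, function(s) fvals[[tv[s]]] >= iso)),
                 ncol = 4)
    caseId <- 1L + fb[, 1] + 2L * fb[, 2] + 4L * fb[, 3] + 8L * fb[, 4]
    for (cs in 2:15) {
      sel <- which(caseId == cs)
      if (!length(sel)) next
      info <- .tetCases[[cs]]
      pin <- Reduce(`+`, lapply(info$inside,
               function(s) coords[[tv[s]]][sel, , drop = FALSE])) /
             length(info$inside)
      for (tr in info$tris) {
        vp <- vector("list", 3)
        for (r in 1:3) {
          p <- tv[tr[r, 1]]; q <- tv[tr[r, 2]]
          fp <- fvals[[p]][sel]; fq <- fvals[[q]][sel]
          t01 <- (iso - fp) / (fq - fp)
          vp[[r]] <- coords[[p]][sel, , drop = FALSE] +
            t01 * (coords[[q]][sel, , drop = FALSE] -
                   coords[[p]][sel, , drop = FALSE])
        }
        # orient outward: normal away from the inside corners
        e1 <- vp[[2]] - vp[[1]]; e2 <- vp[[3]] - vp[[1]]
        nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                     e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                     e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        w <- vp[[1]] - pin
        flip <- rowSums(nrm * w) < 0
        b <- vp[[2]]; c3 <- vp[[3]]
        b[flip, ] <- vp[[3]][flip, ]; c3[flip, ] <- vp[[2]][flip, ]
        nt <- nt + 1L
        triA[[nt]] <- vp[[1]]; triB[[nt]] <- b; triC[[nt]] <- c3
      }
    }
  }
  A <- do.call(rbind, triA); B <- do.call(rbind, triB); C <- do.call(rbind, triC)
  allv <- rbind(A, B, C)
  tol <- 1e-7
  key <- paste(round(allv[, 1] / tol), round(allv[, 2] / tol),
               round(allv[, 3] / tol))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- allv[uk, , drop = FALSE]
  m <- nrow(A)
  faces <- cbind(vid[1:m], vid[m + 1:m], vid[2 * m + 1:m])
  # drop degenerate triangles
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  new("SurfaceMesh", vertices = verts, faces = faces,
      openBoundaries = list())
}

#' Surface area of a mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return total triangle area, mm^2.
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (positive for outward-oriented
#' closed surfaces).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return enclosed volume, mm^3.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Check that a mesh is watertight
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return TRUE if every undirected edge is shared by exactly two faces
#'   with opposite orientation.
#' @export
meshIsClosed <- function(mesh) {
  f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keyU <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(keyU)
  if (any(cnt != 2)) return(FALSE)
  keyD <- paste(ed[, 1], ed[, 2])
  all(!duplicated(keyD))
}

# Directed boundary edges of a face set (edges used exactly once).
.boundaryEdges <- function(faces) {
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  keyU <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(keyU)
  ed[keyU %in% names(cnt)[cnt == 1], , drop = FALSE]
}

#' Clip branch stubs off a surface and cap the holes
#'
#' Removes the portion of the surface lying past each ostial plane (within
#' the branch cylinder) and fills each resulting hole with a centroid-fan
#' cap, leaving the trunk watertight.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param landmarks list of clip specifications, each a list with
#'   \code{point} (3D ostium position, mm), \code{normal} (unit branch
#'   direction pointing away from the trunk), and \code{radius} (branch
#'   clip radius, mm).
#' @param offset distance past the ostial plane at which clipping starts,
#'   mm (default 0: clip at the plane).
#' @param tol maximum allowed distance from a landmark point to the surface
#'   (rejected beyond this), mm; default 5x the median edge length.
#' @return clipped and capped \linkS4class{SurfaceMesh}.
#' @export
clipBranches <- function(mesh, landmarks, offset = 0, tol = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  if (is.null(tol)) {
    e <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    tol <- 5 * stats::median(sqrt(rowSums(e^2)))
  }
  removeV <- rep(FALSE, nrow(v))
  for (lm in landmarks) {
    p <- lm$point; nrm <- unitize(lm$normal); rad <- lm$radius
    dmin <- min(sqrt(rowSums((v - matrix(p, nrow(v), 3, byrow = TRUE))^2)))
    tolEff <- max(tol, rad)   # an ostium landmark sits within the branch bore
    if (dmin > tolEff)
      stop("landmark at (", paste(sprintf("%.3f", p), collapse = ", "),
           ") not on surface (distance ", sprintf("%.3f", dmin),
           " mm exceeds ", sprintf("%.3f", tolEff), ")")
    w <- v - matrix(p, nrow(v), 3, byrow = TRUE)
    ax <- as.numeric(w %*% nrm)
    rd <- sqrt(pmax(rowSums(w^2) - ax^2, 0))
    removeV <- removeV | (ax > offset & rd < rad)
  }
  if (!any(removeV)) return(mesh)
  keepF <- !(removeV[f[, 1]] | removeV[f[, 2]] | removeV[f[, 3]])
  f2 <- f[keepF, , drop = FALSE]
  be <- .boundaryEdges(f2)
  caps <- list()
  if (nrow(be)) {
    # group directed boundary edges into loops by walking head -> tail
    used <- rep(FALSE, nrow(be))
    startOf <- be[, 1]
    while (any(!used)) {
      i <- which(!used)[1]
      loop <- integer(0)
      cur <- i
      repeat {
        used[cur] <- TRUE
        loop <- c(loop, cur)
        nxt <- which(!used & startOf == be[cur, 2])
        if (!length(nxt)) break
        cur <- nxt[1]
      }
      caps[[length(caps) + 1L]] <- be[loop, , drop = FALSE]
    }
  }
  newV <- v; newF <- f2
  for (loopE in caps) {
    ctr <- colMeans(v[unique(as.vector(loopE)), , drop = FALSE])
    newV <- rbind(newV, ctr)
    cid <- nrow(newV)
    # cap triangles traverse each boundary edge opposite to the kept face
    capF <- cbind(loopE[, 2], loopE[, 1], cid)
    newF <- rbind(newF, capF)
  }
  new("SurfaceMesh", vertices = newV, faces = newF, openBoundaries = list())
}
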