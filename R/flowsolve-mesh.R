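# Structured tube-fitted meshes for the steady solvers.

#' Structured mesh for a straight tube
#'
#' @param radius tube radius, mm.
#' @param length tube length, mm (including any extensions).
#' @param level refinement level; each level doubles the cell count in
#'   every direction.
#' @param nr radial cells at level 0.
#' @param nz axial cells at level 0.
#' @param ntheta azimuthal sectors at level 0 (used for 3D expansion).
#' @param extensions named numeric, per-patch extension lengths in
#'   diameters (bookkeeping; included in \code{length}).
#' @return a \linkS4class{FlowMesh} with patches inlet, outlet, wall.
#' @export
tubeMesh <- function(radius, length, level = 0, nr = 16L, nz = 64L,
                     ntheta = 16L, extensions = c(inlet = 1, outlet = 9)) {
  f <- 2^level
  dims <- c(ns = as.integer(nz * f), nr = as.integer(nr * f),
            ntheta = as.integer(ntheta * f))
  zc <- (seq_len(dims[["ns"]]) - 0.5) * length / dims[["ns"]]
  rc <- (seq_len(dims[["nr"]]) - 0.5) * radius / dims[["nr"]]
  th <- (seq_len(dims[["ntheta"]]) - 1) * 2 * pi / dims[["ntheta"]]
  g <- expand.grid(r = rc, th = th, z = zc)
  nodes <- cbind(g$r * cos(g$th), g$r * sin(g$th), g$z)
  new("FlowMesh", type = "straight_tube", dims = dims,
      geom = list(radius = radius, length = length),
      nodes = nodes, patches = c("inlet", "outlet", "wall"),
      extensions = extensions, level = as.numeric(level))
}

#' Structured mesh for a constant-curvature (curved) tube
#'
#' @param radius tube (cross-section) radius, mm.
#' @param bendRadius centerline bend radius, mm.
#' @param bendAngle swept bend angle, radians.
#' @param level refinement level.
#' @param nr radial node shells at level 0.
#' @param ntheta azimuthal sectors at level 0.
#' @param ns axial stations at level 0.
#' @return a \linkS4class{FlowMesh} with patches inlet, outlet, wall.
#' @export
curvedTubeMesh <- function(radius, bendRadius, bendAngle = pi / 2,
                           level = 0, nr = 20L, ntheta = 32L, ns = 17L) {
  f <- 2^level
  dims <- c(ns = as.integer(ns * f), nr = as.integer(nr * f),
            ntheta = as.integer(ntheta * f))
  phi <- seq(0, bendAngle, length.out = dims[["ns"]])
  rr <- seq_len(dims[["nr"]]) * radius / dims[["nr"]]
  th <- (seq_len(dims[["ntheta"]]) - 1) * 2 * pi / dims[["ntheta"]]
  nodes <- NULL
  g <- expand.grid(r = rr, th = th)
  blocks <- lapply(phi, function(p) {
    ex <- c(cos(p), 0, sin(p))      # outward in the curvature plane
    ey <- c(0, 1, 0)
    ctr <- bendRadius * ex
    xc <- g$r * cos(g$th); yc <- g$r * sin(g$th)
    cbind(ctr[1] + xc * ex[1] + yc * ey[1],
          ctr[2] + xc * ex[2] + yc * ey[2],
          ctr[3] + xc * ex[3] + yc * ey[3])
  })
  nodes <- do.call(rbind, blocks)
  new("FlowMesh", type = "curved_tube", dims = dims,
      geom = list(radius = radius, bendRadius = bendRadius,
                  bendAngle = bendAngle),
      nodes = nodes, patches = c("inlet", "outlet", "wall"),
      extensions = c(inlet = 0, outlet = 0), level = as.numeric(level))
}

#' Mesh a vessel tree into structured tube blocks
#'
#' Builds a multi-block tube-fitted mesh over the whole tree, one
#' structured block per segment, with named inlet/outlet/wall patches.
#' Terminal outlets are extended along the end tangent by 9 diameters and
#' root inlets by 1 diameter (defaults), emulating boundary extensions;
#' self-intersecting extensions are rejected.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param resolution radial cells per block at level 0.
#' @param extensions named numeric: extension length in diameters for
#'   \code{outlet} and \code{root} patches.
#' @param level refinement level (each level doubles every direction).
#' @param ntheta azimuthal sectors.
#' @return a \linkS4class{FlowMesh} of type \code{tube_network}; block
#'   bookkeeping is kept in \code{geom$blocks}.
#' @export
meshTree <- function(tree, resolution = 6L, extensions = c(outlet = 9, root = 1),
                     level = 0, ntheta = 12L) {
  f <- 2^level
  nr <- as.integer(resolution * f); nth <- as.integer(ntheta * f)
  segs <- tree@segments
  isRoot <- names(segs) %in% .inletRoles
  isOutlet <- names(segs) %in% .outletRoles
  blocks <- list(); nodes <- list(); patches <- "wall"
  for (role in names(segs)) {
    s <- segs[[role]]
    sl <- segArclength(s)
    R <- mean(s$radius)
    ds <- R / 2 / f
    pts <- s$points; tg <- segTangents(pts)
    extLo <- if (isRoot[[match(role, names(segs))]])
      extensions[["root"]] * 2 * R else 0
    extHi <- if (isOutlet[[match(role, names(segs))]])
      extensions[["outlet"]] * 2 * R else 0
    # extend end points along end tangents
    p0 <- pts[1, ] - tg[1, ] * extLo
    p1 <- pts[nrow(pts), ] + tg[nrow(pts), ] * extHi
    if (extLo > 0) pts <- rbind(p0, pts)
    if (extHi > 0) pts <- rbind(pts, p1)
    totLen <- max(sl) + extLo + extHi
    nsB <- max(2L, ceiling(totLen / ds))
    # intersection guard for the extension tips
    for (other in names(segs)) {
      if (other == role) next
      so <- segs[[other]]
      for (tip in list(if (extHi > 0) p1 else NULL,
                       if (extLo > 0) p0 else NULL)) {
        if (is.null(tip)) next
        dmin <- min(sqrt(colSums((t(so$points) - tip)^2)))
        if (dmin < max(so$radius) + R)
          stop("self-intersecting boundary extension: '", role,
               "' extension runs into '", other, "'")
      }
    }
    blocks[[role]] <- list(role = role, ns = nsB, nr = nr, ntheta = nth,
                           radius = R, length = totLen,
                           cells = nsB * nr * nth)
    if (isRoot[[match(role, names(segs))]])
      patches <- c(patches, paste0("inlet_", role))
    if (isOutlet[[match(role, names(segs))]])
      patches <- c(patches, paste0("outlet_", role))
    # coarse node lattice along the (extended) centerline
    su <- seq(0, 1, length.out = min(nsB, 64L))
    slx <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    ppts <- apply(pts, 2, function(col) approx(slx, col, su * max(slx))$y)
    nodes[[role]] <- ppts
  }
  dims <- c(ns = sum(vapply(blocks, `[[`, numeric(1), "ns")),
            nr = nr, ntheta = nth)
  new("FlowMesh", type = "tube_network", dims = as.integer(dims),
      geom = list(blocks = blocks),
      nodes = do.call(rbind, nodes), patches = unique(patches),
      extensions = extensions, level = as.numeric(level))
}

#' Total cell count of a flow mesh
#'
#' @param mesh a \linkS4class{FlowMesh}.
#' @return number of cells.
#' @export
meshCellCount <- function(mesh) {
  if (mesh@type == "tube_network")
    sum(vapply(mesh@geom$blocks, `[[`, numeric(1), "cells"))
  else prod(mesh@dims)
}
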