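# Parametric great-artery tree generator. The tree reproduces the topology
# of the fetal mouse great arteries: ascending aorta -> arch (giving off the
# innominate, left common carotid and left subclavian) -> descending aorta,
# and pulmonary trunk -> ductus arteriosus inserting into the descending
# aorta, with small left/right pulmonary-artery branches. Segments are
# swept-ellipse tubes along sampled space curves; the arch and the
# pulmonary-trunk bend are circular arcs, the ductus is a cubic Hermite
# curve whose end tangent realizes the stage-dependent insertion angle.

# Reference diameters relative to the near-term descending aorta (0.573 mm).
.refDiamRatio <- c(
  ascending_aorta = 1.05, arch = 0.88, descending_aorta = 1.00,
  pulmonary_trunk = 0.95, ductus = 0.75, innominate = 0.45,
  left_common_carotid = 0.32, left_subclavian = 0.35,
  left_pulmonary_artery = 0.30, right_pulmonary_artery = 0.30)

#' Build a straight tube segment
#'
#' @param role anatomical role label.
#' @param p0,p1 3D start/end points, mm.
#' @param r0,r1 start/end radius, mm (linear taper).
#' @param n number of centerline samples.
#' @param ellipticity per-sample minor/major ratio (recycled), in (0, 1].
#' @param elongAxis single 3D vector giving the in-plane elongation
#'   direction for non-circular sections, or NULL.
#' @return a segment list usable in \code{\link{vesselTree}}.
#' @export
straightSegment <- function(role, p0, p1, r0, r1 = r0, n = 31,
                            ellipticity = 1, elongAxis = NULL) {
  u <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + u * (p1[1] - p0[1]),
               p0[2] + u * (p1[2] - p0[2]),
               p0[3] + u * (p1[3] - p0[3]))
  makeSegment(role, pts, r0 + u * (r1 - r0), ellipticity, elongAxis)
}

#' Build a circular-arc tube segment
#'
#' @param role anatomical role label.
#' @param center arc center, mm.
#' @param radius bend radius, mm.
#' @param axisU,axisV orthonormal in-plane axes of the arc plane.
#' @param phi0,phi1 start/end arc angle, radians (sampled linearly).
#' @param r0,r1 tube radius at start/end, mm.
#' @param n number of samples.
#' @param ellipticity per-sample minor/major ratio (recycled).
#' @param elongAxis elongation direction vector or NULL.
#' @return a segment list.
#' @export
arcSegment <- function(role, center, radius, axisU, axisV, phi0, phi1,
                       r0, r1 = r0, n = 41, ellipticity = 1,
                       elongAxis = NULL) {
  phi <- seq(phi0, phi1, length.out = n)
  u <- seq(0, 1, length.out = n)
  pts <- t(vapply(phi, function(p)
    center + radius * (cos(p) * axisU + sin(p) * axisV), numeric(3)))
  makeSegment(role, pts, r0 + u * (r1 - r0), ellipticity, elongAxis)
}

#' Build a cubic-Hermite tube segment
#'
#' @param role anatomical role label.
#' @param p0,p1 endpoints, mm.
#' @param t0,t1 unit tangents at the endpoints.
#' @param r0,r1 tube radius at start/end, mm.
#' @param n number of samples.
#' @param tension tangent magnitude as a multiple of the chord length.
#' @return a segment list.
#' @export
hermiteSegment <- function(role, p0, p1, t0, t1, r0, r1 = r0, n = 41,
                           tension = 1) {
  chord <- sqrt(sum((p1 - p0)^2))
  m0 <- unitize(t0) * chord * tension
  m1 <- unitize(t1) * chord * tension
  u <- seq(0, 1, length.out = n)
  h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
  pts <- outer(h00, p0) + outer(h10, m0) + outer(h01, p1) + outer(h11, m1)
  makeSegment(role, pts, r0 + u * (r1 - r0), 1, NULL)
}

makeSegment <- function(role, pts, radius, ellipticity = 1, elongAxis = NULL) {
  n <- nrow(pts)
  ell <- rep(ellipticity, length.out = n)
  ea <- if (is.null(elongAxis)) matrix(0, n, 3)
        else matrix(rep(unitize(elongAxis), each = n), n, 3)
  list(role = role, points = pts, radius = rep(radius, length.out = n),
       ellipticity = ell, elongAxis = ea)
}

segArclength <- function(seg) {
  d <- sqrt(rowSums(diff(seg$points)^2))
  c(0, cumsum(d))
}

segTangents <- function(pts) {
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[3:n, ] - pts[1:(n - 2), ],
              pts[n, ] - pts[n - 1, ])
  rowUnitize(tg)
}

# Gaussian ellipticity dip toward `depth` centered at arclengths s0 (width w).
applyEllipticityDip <- function(seg, s0, depth = 0.70, width = NULL,
                                elongAxis = NULL, base = NULL) {
  s <- segArclength(seg)
  if (is.null(base)) base <- seg$ellipticity
  ell <- base
  for (k in seq_along(s0)) {
    w <- if (is.null(width)) stats::approx(s, seg$radius, s0[k], rule = 2)$y
         else width
    dip <- exp(-((s - s0[k]) / w)^2)
    ell <- pmin(ell, base - (base - depth) * dip)
    if (!is.null(elongAxis)) {
      ax <- matrix(rep(unitize(elongAxis[[k]]), each = nrow(seg$points)),
                   ncol = 3)
      sel <- dip > 0.1
      seg$elongAxis[sel, ] <- ax[sel, ]
    }
  }
  seg$ellipticity <- ell
  seg
}

#' Assemble a vessel tree from segments
#'
#' @param segments list of segment lists (from the segment constructors);
#'   names default to segment roles.
#' @param junctions data.frame (parent, child, x, y, z, angleDeg) or NULL.
#' @param landmarks data.frame (name, segment, arclength, x, y, z) or NULL.
#' @param ageDays gestational age attached to the tree.
#' @param seed generating seed attached to the tree.
#' @return a \linkS4class{VesselTree}.
#' @export
vesselTree <- function(segments, junctions = NULL, landmarks = NULL,
                       ageDays = NA_real_, seed = 0L) {
  names(segments) <- vapply(segments, `[[`, character(1), "role")
  if (is.null(junctions))
    junctions <- data.frame(parent = character(), child = character(),
                            x = numeric(), y = numeric(), z = numeric(),
                            angleDeg = numeric(), stringsAsFactors = FALSE)
  if (is.null(landmarks))
    landmarks <- data.frame(name = character(), segment = character(),
                            arclength = numeric(), x = numeric(),
                            y = numeric(), z = numeric(),
                            stringsAsFactors = FALSE)
  new("VesselTree", segments = segments, junctions = junctions,
      landmarks = landmarks, ageDays = as.numeric(ageDays),
      seed = as.integer(seed))
}

# Stage-dependent ductus insertion angle (degrees; 180 = parallel merge).
# Near-perpendicular early, approaching parallel near term.
ductusAngleAtAge <- function(ageDays) 100 + 50 * (ageDays - 14.5) / 4

#' Generate a synthetic great-artery tree
#'
#' Builds the stage-scaled parametric tree for the configured gestational
#' age. Deterministic for a fixed config seed. The descending-aorta diameter
#' equals \code{config@daoDiameter}; other vessel diameters follow fixed
#' anatomical ratios with a small per-subject lognormal jitter; the ductus
#' insertion angle moves from near 90 degrees at E14.5 toward parallel
#' (180 degrees) near term; cross-section ellipticity dips below 1 proximal
#' to each branch ostium with the elongation axis oriented toward the
#' branch.
#'
#' @param config a \linkS4class{StageConfig}.
#' @param jitterCV per-subject lognormal coefficient of variation applied to
#'   non-anchored vessel radii (0 disables jitter).
#' @param branchEllipticity minimum minor/major ratio imposed in branch
#'   zones.
#' @param n samples per unit-length of segment (controls sampling density).
#' @return a \linkS4class{VesselTree}.
#' @export
generateVesselTree <- function(config, jitterCV = 0.03,
                               branchEllipticity = 0.70, n = 31) {
  sc <- config@daoDiameter / 0.573   # stage scale relative to near-term
  age <- config@ageDays
  rng <- setLocalSeed(config@seed + 1000L)
  on.exit(restoreSeed(rng), add = TRUE)

  rad <- 0.573 / 2 * .refDiamRatio   # near-term radii
  jit <- exp(rnorm(length(rad), -0.5 * log(1 + jitterCV^2),
                   sqrt(log(1 + jitterCV^2))))
  names(jit) <- names(rad)
  jit["descending_aorta"] <- 1       # anchored exactly
  r <- rad * jit * sc

  # --- systemic side -------------------------------------------------------
  zArch <- 0.60 * sc; xArch <- 0.45 * sc
  aao <- straightSegment("ascending_aorta", c(0, 0, 0), c(0, 0, zArch),
                         r[["ascending_aorta"]], r[["arch"]],
                         n = n, ellipticity = 0.85)
  archPhi <- c(pi, 0)
  arch <- arcSegment("arch", center = c(xArch, 0, zArch), radius = xArch,
                     axisU = c(1, 0, 0), axisV = c(0, 0, 1),
                     phi0 = pi, phi1 = 0,
                     r0 = r[["arch"]], r1 = r[["descending_aorta"]],
                     n = 2 * n - 1, ellipticity = 0.85)
  dao <- straightSegment("descending_aorta", c(2 * xArch, 0, zArch),
                         c(2 * xArch, 0, zArch - 1.6 * sc),
                         r[["descending_aorta"]], r[["descending_aorta"]],
                         n = 2 * n - 1, ellipticity = 1)

  # head-and-neck branches leave the arch top, directed cranially (+z)
  branchPhi <- c(innominate = 0.80 * pi, left_common_carotid = 0.55 * pi,
                 left_subclavian = 0.38 * pi)
  archS <- segArclength(arch)
  phiGrid <- seq(pi, 0, length.out = nrow(arch$points))
  heads <- list(); headS <- numeric(0)
  for (b in names(branchPhi)) {
    i0 <- which.min(abs(phiGrid - branchPhi[[b]]))
    p0 <- arch$points[i0, ]
    heads[[b]] <- straightSegment(b, p0, p0 + c(0, 0, 0.45 * sc),
                                  r[[b]], r[[b]], n = n, ellipticity = 1)
    headS[b] <- archS[i0]
  }
  arch <- applyEllipticityDip(arch, headS, depth = branchEllipticity,
                              elongAxis = rep(list(c(0, 0, 1)),
                                              length(headS)))

  # --- pulmonary side ------------------------------------------------------
  # The pulmonary course runs in a plane offset anteriorly (y = -yP) so the
  # two lumens never fuse; only the ductus approaches the descending aorta,
  # at its insertion point.
  yP <- 0.65 * sc
  bendR <- 0.50 * sc
  pt <- arcSegment("pulmonary_trunk",
                   center = c(bendR, -yP, 0), radius = bendR,
                   axisU = c(-1, 0, 0), axisV = c(0, 0, 1),
                   phi0 = 0, phi1 = pi / 2,
                   r0 = r[["pulmonary_trunk"]], r1 = r[["ductus"]],
                   n = n, ellipticity = 0.85)
  ptEnd <- pt$points[nrow(pt$points), ]
  ptEndTan <- segTangents(pt$points)[nrow(pt$points), ]

  # pulmonary arteries branch near the distal pulmonary trunk
  iPA <- nrow(pt$points) - 3L
  paOrigin <- pt$points[iPA, ]
  lpa <- straightSegment("left_pulmonary_artery", paOrigin,
                         paOrigin + 0.35 * sc * unitize(c(-0.3, -0.9, -0.2)),
                         r[["left_pulmonary_artery"]], n = n)
  rpa <- straightSegment("right_pulmonary_artery", paOrigin,
                         paOrigin + 0.35 * sc * unitize(c(0.5, -0.8, -0.2)),
                         r[["right_pulmonary_artery"]], n = n)
  ptS <- segArclength(pt)
  pt <- applyEllipticityDip(pt, ptS[iPA], depth = branchEllipticity,
                            elongAxis = list(c(0, -1, 0)))

  # ductus: Hermite curve into a straight terminal run along the insertion
  # direction, so the insertion angle is a sustained approach course (as in
  # the anatomy), not just an endpoint tangent
  angle <- ductusAngleAtAge(age)
  alpha <- (180 - angle) * pi / 180
  zIns <- zArch - 0.55 * sc
  pIns <- c(2 * xArch, 0, zIns)
  happ <- unitize(c(pIns[1] - ptEnd[1], pIns[2] - ptEnd[2], 0))
  tIns <- sin(alpha) * happ + cos(alpha) * c(0, 0, -1)
  lStr <- 0.35 * sc
  p2 <- pIns - lStr * tIns
  ducCurve <- hermiteSegment("ductus", ptEnd, p2, ptEndTan, tIns,
                             r[["ductus"]], r[["ductus"]], n = n)
  nStr <- max(5L, ceiling(n / 2))
  uS <- seq(0, 1, length.out = nStr)[-1]
  strPts <- outer(rep(1, nStr - 1), p2) + outer(uS, lStr * tIns)
  duc <- makeSegment("ductus", rbind(ducCurve$points, strPts),
                     r[["ductus"]])

  sIns <- zArch - zIns   # arclength of insertion point along the DAo

  segments <- c(list(aao, arch, dao, pt, duc), heads, list(lpa, rpa))
  junctions <- data.frame(
    parent = c("arch", "arch", "arch", "descending_aorta",
               "pulmonary_trunk", "pulmonary_trunk"),
    child = c(names(branchPhi), "ductus",
              "left_pulmonary_artery", "right_pulmonary_artery"),
    x = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 1],
                 numeric(1)), pIns[1], paOrigin[1], paOrigin[1]),
    y = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 2],
                 numeric(1)), pIns[2], paOrigin[2], paOrigin[2]),
    z = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 3],
                 numeric(1)), pIns[3], paOrigin[3], paOrigin[3]),
    angleDeg = c(rep(90, length(branchPhi)), angle, 75, 75),
    stringsAsFactors = FALSE)
  landmarks <- data.frame(
    name = c(paste0(names(branchPhi), "_ostium"), "ductus_insertion",
             "pa_ostium"),
    segment = c(rep("arch", length(branchPhi)), "descending_aorta",
                "pulmonary_trunk"),
    arclength = c(unname(headS), sIns, ptS[iPA]),
    x = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 1],
                 numeric(1)), pIns[1], paOrigin[1]),
    y = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 2],
                 numeric(1)), pIns[2], paOrigin[2]),
    z = c(vapply(names(branchPhi), function(b) heads[[b]]$points[1, 3],
                 numeric(1)), pIns[3], paOrigin[3]),
    stringsAsFactors = FALSE)

  tree <- vesselTree(segments, junctions, landmarks, ageDays = age,
                     seed = config@seed)
  checkNoOverlap(tree)
  tree
}

# Adjacent segment pairs share a junction; all other pairs must keep their
# centerlines farther apart than the sum of local radii.
checkNoOverlap <- function(tree) {
  segs <- tree@segments
  nm <- names(segs)
  adjacent <- rbind(
    c("ascending_aorta", "arch"), c("arch", "descending_aorta"),
    c("arch", "innominate"), c("arch", "left_common_carotid"),
    c("arch", "left_subclavian"), c("pulmonary_trunk", "ductus"),
    c("pulmonary_trunk", "left_pulmonary_artery"),
    c("pulmonary_trunk", "right_pulmonary_artery"),
    c("ductus", "descending_aorta"),
    # siblings that share a junction region, and the isthmus neighborhood
    c("ductus", "left_pulmonary_artery"), c("ductus", "right_pulmonary_artery"),
    c("left_pulmonary_artery", "right_pulmonary_artery"),
    c("ductus", "arch"))
  isAdj <- function(a, b)
    any((adjacent[, 1] == a & adjacent[, 2] == b) |
        (adjacent[, 1] == b & adjacent[, 2] == a))
  # a pair overlaps when one centerline penetrates the core of the other
  # tube (closer than 60% of the larger local radius) away from any shared
  # junction
  for (i in seq_along(segs)) for (j in seq_len(i - 1L)) {
    a <- segs[[i]]; b <- segs[[j]]
    if (isAdj(nm[i], nm[j])) next
    dmin <- Inf
    for (k in seq_len(nrow(a$points)))
      dmin <- min(dmin, sqrt(min(colSums((t(b$points) - a$points[k, ])^2))))
    if (dmin < 0.6 * max(max(a$radius), max(b$radius)))
      stop("non-physical tree: segments '", nm[i], "' and '", nm[j],
           "' overlap")
  }
  invisible(TRUE)
}

#' Ground-truth centerline of a tree segment
#'
#' Converts a generator segment into a \linkS4class{Centerline} (the
#' analytic ground truth retained for recovery tests).
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param role segment role name.
#' @return a \linkS4class{Centerline}.
#' @export
segmentCenterline <- function(tree, role) {
  s <- tree@segments[[role]]
  if (is.null(s)) stop("no segment with role '", role, "'")
  sl <- segArclength(s)
  sl <- sl + seq_along(sl) * max(sl) * 1e-12
  new("Centerline", points = s$points, tangents = segTangents(s$points),
      arclength = sl, radius = s$radius,
      branchIds = rep(0L, nrow(s$points)))
}

#' Mean cross-sectional area of a tree segment
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param role segment role name.
#' @return mean of pi * radius^2 along the segment, mm^2.
#' @export
meanSegmentArea <- function(tree, role) {
  s <- tree@segments[[role]]
  if (is.null(s)) stop("no segment with role '", role, "'")
  mean(pi * s$radius^2)
}

# Seed scoping helpers: generators are pure functions of (parameters, seed);
# the caller's RNG stream is left untouched.
setLocalSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  old
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
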