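# Landmark-scaled profile alignment across subjects and junction insertion
# angles.

#' Align profiles across subjects by landmark rescaling
#'
#' Each subject's arclength coordinate is normalized to [0, 1] and warped
#' piecewise-linearly so that every named landmark lands at the
#' cross-subject mean normalized position; values are resampled on a
#' common grid and the cross-subject mean and dispersion are computed.
#'
#' @param profiles list of subjects, each a list with \code{x} (arclength,
#'   mm or normalized), \code{values} (same length), and \code{landmarks}
#'   (named numeric positions on \code{x}, in increasing order).
#' @param landmarkNames landmark names required of every subject, in order.
#' @param nGrid size of the common resampling grid.
#' @return list with \code{x} (common grid), \code{aligned} (subject x
#'   grid matrix), \code{mean}, \code{sd}, \code{landmarks} (pinned
#'   positions), \code{subjects}.
#' @export
alignProfiles <- function(profiles, landmarkNames, nGrid = 101L) {
  if (!length(profiles)) stop("no profiles supplied")
  normed <- lapply(profiles, function(p) {
    if (is.null(p$x) || is.null(p$values)) stop("profiles need x and values")
    if (!all(landmarkNames %in% names(p$landmarks)))
      stop("missing landmark(s): ",
           paste(setdiff(landmarkNames, names(p$landmarks)), collapse = ", "))
    lm <- p$landmarks[landmarkNames]
    if (any(diff(lm) <= 0)) stop("landmarks out of order for a subject")
    rng <- range(p$x)
    list(x = (p$x - rng[1]) / diff(rng), values = p$values,
         lm = (lm - rng[1]) / diff(rng))
  })
  lmMat <- do.call(rbind, lapply(normed, `[[`, "lm"))
  pinned <- colMeans(lmMat)
  xg <- seq(0, 1, length.out = nGrid)
  aligned <- t(vapply(normed, function(p) {
    knots0 <- c(0, p$lm, 1); knots1 <- c(0, pinned, 1)
    warped <- approx(knots0, knots1, p$x, rule = 2)$y
    approx(warped, p$values, xg, rule = 2)$y
  }, numeric(nGrid)))
  mu <- colMeans(aligned)
  sdv <- if (nrow(aligned) > 1) apply(aligned, 2, sd) else rep(0, nGrid)
  list(x = xg, aligned = aligned, mean = mu, sd = sdv,
       landmarks = stats::setNames(pinned, landmarkNames),
       subjects = seq_along(profiles))
}

#' Insertion angle between a branch and its parent vessel
#'
#' Angle between the branch direction pointing back out of the junction
#' (upstream along the branch) and the parent downstream tangent, reported
#' in (0, 180] degrees: 90 means perpendicular insertion, 180 a parallel
#' flow merge.
#'
#' @param parent a \linkS4class{Centerline}, ordered with flow.
#' @param branch a \linkS4class{Centerline}, ordered with flow into the
#'   junction (its last point is at or near the insertion).
#' @param junction 3D junction point, mm.
#' @param tol maximum distance of either centerline from the junction, mm.
#' @param standoff chord window, in units of the local vessel radius, over
#'   which each direction is measured away from the junction (the merged
#'   lumen bends centerline paths inside the junction itself).
#' @return angle in degrees.
#' @export
insertionAngle <- function(parent, branch, junction, tol = 0.15,
                           standoff = c(0.5, 1.6)) {
  pp <- parent@points; bp <- branch@points
  dPar <- sqrt(rowSums((pp - matrix(junction, nrow(pp), 3,
                                    byrow = TRUE))^2))
  dBr <- sqrt(rowSums((bp - matrix(junction, nrow(bp), 3,
                                   byrow = TRUE))^2))
  if (min(dPar) > tol || min(dBr) > tol)
    stop("junction mismatch: centerline(s) farther than ", tol,
         " mm from the junction point")
  chordDir <- function(cl, sFrom, sTo) {
    at <- function(s) vapply(1:3, function(c3)
      approx(cl@arclength, cl@points[, c3],
             pmin(pmax(s, cl@arclength[1]), max(cl@arclength)))$y,
      numeric(1))
    unitize(at(sTo) - at(sFrom))
  }
  iP <- which.min(dPar)
  sJ <- parent@arclength[iP]
  rP <- parent@radius[iP]
  tDown <- chordDir(parent, sJ + standoff[1] * rP, sJ + standoff[2] * rP)
  nB <- nrow(bp)
  iB <- which.min(dBr)
  sB <- branch@arclength[iB]
  rB <- branch@radius[max(1L, iB - 5L)]
  tIn <- chordDir(branch, sB - standoff[2] * rB, sB - standoff[1] * rB)
  cosA <- sum(-tIn * tDown)
  acos(pmin(pmax(cosA, -1), 1)) * 180 / pi
}
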