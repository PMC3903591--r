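# Wall shear stress/rate, centerline Reynolds/Womersley numbers and
# normalized helicity from solved flow fields.

#' Wall shear field from a solved flow
#'
#' Wall shear rate is the normal gradient of the tangential velocity at
#' the wall (one-sided second-order difference consistent with the solver
#' grid); wall shear stress is mu times shear rate. Samples are laid out
#' on the structured wall grid (arclength x azimuth).
#'
#' @param field a \linkS4class{FlowField} from \code{\link{solveSteady3D}}.
#' @param mesh the mesh solved on (defaults to \code{field@mesh}).
#' @param props a \linkS4class{BloodProperties}.
#' @return a \linkS4class{WallShearField} (tau in mPa, gamma in 1/s).
#' @export
wallShear <- function(field, mesh = NULL, props) {
  if (is.null(mesh)) mesh <- field@mesh
  st <- field@structured
  mu <- props@mu
  if (st$type == "straight") {
    R <- st$R
    th <- st$theta
    zc <- st$zc
    gw <- st$gammaWall            # per axial cell, theta-uniform
    g <- as.vector(outer(gw, rep(1, length(th))))
    s <- as.vector(outer(zc, rep(1, length(th))))
    thv <- as.vector(outer(rep(1, length(zc)), th))
    posx <- R * cos(thv); posy <- R * sin(thv)
    positions <- cbind(posx, posy, s)
  } else if (st$type == "curved") {
    a <- st$a; Rb <- st$Rb
    phi <- seq(0, st$phiMax, length.out = st$Ns)
    th <- st$th
    gw <- st$gammaWall            # per azimuth, station-uniform
    g <- as.vector(outer(rep(1, length(phi)), gw))
    s <- as.vector(outer(phi * Rb, rep(1, length(th))))
    thv <- as.vector(outer(rep(1, length(phi)), th))
    phv <- as.vector(outer(phi, rep(1, length(th))))
    ex1 <- cos(phv); ex3 <- sin(phv)
    xc <- a * cos(thv); yc <- a * sin(thv)
    positions <- cbind((Rb + xc) * ex1, yc, (Rb + xc) * ex3)
  } else stop("wall patch information absent from field")
  new("WallShearField", positions = positions, s = s,
      theta = (thv * 180 / pi) %% 360, gamma = g, tau = mu * g, mu = mu)
}

#' Centerline hemodynamics: velocity, Reynolds and Womersley numbers
#'
#' Samples the velocity magnitude at the centerline points of a solved 3D
#' field (or takes reduced-order centerline velocities directly) and
#' evaluates, per station, the Reynolds number Re = V_c a / nu and the
#' Womersley number alpha = a sqrt(omega/nu), with a the station radius
#' (average of the maximum and minimum cross-sectional radius), nu the
#' kinematic viscosity and omega the heart-rate angular frequency.
#'
#' @param field a \linkS4class{FlowField}, or a numeric vector of
#'   centerline velocities (mm/s) per station.
#' @param centerline a \linkS4class{Centerline}.
#' @param props a \linkS4class{BloodProperties}.
#' @param config a \linkS4class{StageConfig}.
#' @return data.frame: s_mm, radius_mm, Vc_mm_s, Re, alpha, flagged.
#' @export
centerlineHemodynamics <- function(field, centerline, props, config) {
  nu <- props@nu; omega <- config@omega
  a <- centerline@radius
  if (is.numeric(field)) {
    vc <- field
    flagged <- rep(FALSE, length(vc))
  } else {
    st <- field@structured
    pts <- centerline@points
    if (st$type == "straight") {
      # sample axial velocity on the (z, r) grid
      r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
      z <- pts[, 3]
      flagged <- z < 0 | z > st$L | r > st$R
      iz <- pmin(pmax(round(z / (st$dz * st$R) + 0.5), 1), nrow(st$uc))
      jr <- pmin(pmax(round(r / (st$dr * st$R) + 0.5), 1), ncol(st$uc))
      vc <- sqrt(st$uc[cbind(iz, jr)]^2 + st$vc[cbind(iz, jr)]^2)
    } else if (st$type == "curved") {
      Rb <- st$Rb
      phiQ <- atan2(pts[, 3], pts[, 1])
      rho <- sqrt(pts[, 1]^2 + pts[, 3]^2)
      xc <- rho - Rb; yc <- pts[, 2]
      rq <- sqrt(xc^2 + yc^2) / st$a
      tq <- atan2(yc, xc)
      flagged <- rq > 1 | phiQ < -1e-9 | phiQ > st$phiMax + 1e-9
      w <- .polarInterp(st$w, st$wC, st$rr, st$th, pmin(rq, 0.999), tq)
      vc <- abs(w) * st$velScale
    } else stop("unsupported field type for centerline sampling")
    if (any(flagged))
      warning(sum(flagged), " centerline station(s) outside the flow domain")
  }
  data.frame(s_mm = centerline@arclength, radius_mm = a, Vc_mm_s = vc,
             Re = vc * a / nu, alpha = a * sqrt(omega / nu),
             flagged = flagged)
}

#' Normalized helicity of a flow field
#'
#' Hn = (V . w) / (|V| |w|), the cosine of the angle between velocity and
#' vorticity, in [-1, 1]; defined as 0 where either magnitude is below the
#' degeneracy floor.
#'
#' @param field a \linkS4class{FlowField}.
#' @param floor magnitude floor (working units) below which Hn = 0.
#' @return a \linkS4class{HelicityField}.
#' @export
normalizedHelicity <- function(field, floor = 1e-9) {
  V <- field@velocity; W <- field@vorticity
  nv <- sqrt(rowSums(V^2)); nw <- sqrt(rowSums(W^2))
  hn <- ifelse(nv > floor & nw > floor,
               rowSums(V * W) / (nv * nw), 0)
  hn <- pmin(pmax(hn, -1), 1)
  new("HelicityField", nodes = field@mesh@nodes, hn = hn, floor = floor)
}

#' Signed helicity volume balance
#'
#' Volume integrals of positive and negative normalized helicity; in
#' mirror-symmetric curved-tube flow the two agree closely (balanced
#' right- and left-handed structures).
#'
#' @param hel a \linkS4class{HelicityField}.
#' @return list with \code{positive}, \code{negative} (absolute values)
#'   and \code{imbalance} = |pos - neg| / max(pos, neg).
#' @export
helicityBalance <- function(hel) {
  pos <- sum(hel@hn[hel@hn > 0])
  neg <- -sum(hel@hn[hel@hn < 0])
  list(positive = pos, negative = neg,
       imbalance = if (max(pos, neg) > 0) abs(pos - neg) / max(pos, neg)
                   else 0)
}
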