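# User-facing steady-solver API: dispatch over tube-fitted mesh types,
# grid-independence reporting, and passive-tracer streamline diagnostics.

#' Solve steady incompressible Newtonian flow on a tube-fitted mesh
#'
#' Steady laminar (low-Reynolds) solution with plug inlet, no-slip rigid
#' walls and zero-gradient outflow. Straight tubes are solved with the
#' axisymmetric staggered finite-volume scheme (developing flow); curved
#' tubes with the fully developed Dean vorticity-streamfunction scheme.
#' Both return full 3D fields on the mesh nodes. Multi-block tree meshes
#' are handled by the reduced-order network solver
#' (\code{\link{solvePoiseuilleNetwork}}), not here.
#'
#' @param mesh a \linkS4class{FlowMesh} of type \code{straight_tube} or
#'   \code{curved_tube}.
#' @param bc a \linkS4class{FlowBoundarySet}, or a list with element
#'   \code{inletVelocity} (plug / mean axial velocity, mm/s).
#' @param props a \linkS4class{BloodProperties}.
#' @param tol relative residual tolerance.
#' @return a \linkS4class{FlowField}.
#' @export
solveSteady3D <- function(mesh, bc, props, tol = 1e-6) {
  Vin <- if (is(bc, "FlowBoundarySet")) bc@inlets$velocity_mm_s[1]
         else bc$inletVelocity
  if (is.null(Vin) || !is.finite(Vin) || Vin <= 0)
    stop("boundary set must supply a positive inlet velocity")
  ReEst <- props@density * Vin * mesh@geom$radius / props@mu
  if (ReEst > 100)
    stop("configuration Reynolds number ", sprintf("%.1f", ReEst),
         " outside the laminar steady regime (<= 100)")
  switch(mesh@type,
         straight_tube = solveStraightTube(mesh, Vin, props, tol = tol),
         curved_tube = solveCurvedTube(mesh, Vin, props, tol = tol),
         stop("mesh type '", mesh@type, "' is solved with ",
              "solvePoiseuilleNetwork(), not the 3D solver"))
}

#' Grid-independence check between two refinement levels
#'
#' @param coarse,fine \linkS4class{FlowField}s solved on meshes of the same
#'   geometry at different refinement levels.
#' @param metric one of \code{"mean_wss"} (area-mean wall shear stress),
#'   \code{"pressure_drop"}, \code{"peak_velocity"}.
#' @return relative difference |coarse - fine| / |fine|.
#' @export
gridIndependence <- function(coarse, fine,
                             metric = c("mean_wss", "pressure_drop",
                                        "peak_velocity")) {
  metric <- match.arg(metric)
  gc0 <- coarse@mesh@geom; gf <- fine@mesh@geom
  if (coarse@mesh@type != fine@mesh@type ||
      abs(gc0$radius - gf$radius) > 1e-12 ||
      abs((gc0$length %||% gc0$bendRadius) -
            (gf$length %||% gf$bendRadius)) > 1e-12)
    stop("fields solved on different geometries")
  val <- function(fld) {
    st <- fld@structured
    switch(metric,
           mean_wss = mean(st$gammaWall) * st$mu,
           pressure_drop = if (st$type == "straight")
             mean(st$P[1, ]) * st$mu * st$Vin / st$R / 1000
           else abs(fld@pressure[length(fld@pressure)] - fld@pressure[1]),
           peak_velocity = max(sqrt(rowSums(fld@velocity^2))))
  }
  a <- val(coarse); bv <- val(fine)
  abs(a - bv) / abs(bv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear interpolation of a (r, theta) polar field at arbitrary points.
.polarInterp <- function(M, centerVal, rr, th, r, theta) {
  Nr <- length(rr); Nth <- length(th)
  dth <- th[2] - th[1]
  theta <- theta %% (2 * pi)
  k0 <- floor(theta / dth) + 1
  k1 <- ifelse(k0 >= Nth, 1, k0 + 1)
  wk <- (theta - (k0 - 1) * dth) / dth
  dr <- rr[1]
  j0 <- floor(r / dr)                 # 0 means center
  j0 <- pmin(j0, Nr - 1)
  wj <- r / dr - j0
  j1 <- j0 + 1
  get <- function(j, k) ifelse(j == 0, centerVal, M[cbind(pmax(j, 1), k)])
  (1 - wj) * ((1 - wk) * get(j0, k0) + wk * get(j0, k1)) +
    wj * ((1 - wk) * get(j1, k0) + wk * get(j1, k1))
}

#' Passive-tracer mixing fraction through a solved field
#'
#' Releases tracers on the inlet cross-section in the two mirror halves of
#' the tube (the two contributing streams of a confluence, in the
#' reduced-geometry sense), integrates streamlines (RK4) through the steady
#' field, and reports the fraction of tracers whose half (cross-section
#' sector) at the outlet differs from the one they were released in. In
#' orderly low-Reynolds flow this fraction is small: the streams remain in
#' disjoint sectors.
#'
#' @param field a \linkS4class{FlowField} from \code{\link{solveSteady3D}}.
#' @param n number of tracers (split across halves).
#' @param seed RNG seed for seeding positions.
#' @param nStep RK4 steps along the tube.
#' @return list with \code{mixingFraction} and per-tracer start/end halves.
#' @export
tracerMixing <- function(field, n = 200L, seed = 1L, nStep = 200L) {
  st <- field@structured
  rngSave <- setLocalSeed(seed)
  on.exit(restoreSeed(rngSave), add = TRUE)
  rad <- sqrt(runif(n)) * 0.92
  thv <- runif(n, 0, pi)
  half <- rep(c(1, -1), length.out = n)      # +1: upper (y>0), -1: lower
  theta <- ifelse(half > 0, thv, -thv)
  if (st$type == "straight") {
    # axisymmetric: transverse velocity has no azimuthal component, so
    # theta is invariant; integrate (z, r) only
    z <- rep(0, n); r <- rad * st$R
    dzStep <- st$L / nStep
    for (i in seq_len(nStep)) {
      # dr/dz = v/u sampled at cell centers
      sampleVU <- function(zq, rq) {
        iz <- pmin(pmax(round(zq / (st$dz * st$R) + 0.5), 1),
                   nrow(st$uc))
        jr <- pmin(pmax(round(rq / (st$dr * st$R) + 0.5), 1),
                   ncol(st$uc))
        cbind(st$vc[cbind(iz, jr)], st$uc[cbind(iz, jr)])
      }
      k1 <- sampleVU(z, r)
      slope <- ifelse(abs(k1[, 2]) > 1e-12, k1[, 1] / k1[, 2], 0)
      r <- pmin(pmax(r + slope * dzStep, 0), st$R * 0.999)
      z <- z + dzStep
    }
    endHalf <- ifelse(sin(theta) >= 0, 1, -1)  # unchanged by construction
  } else {
    # curved tube: secondary flow advects the cross-section position as
    # the tracer progresses along the bend
    r <- rad; thc <- theta    # dimensionless r in [0,1)
    sTot <- st$Rb / st$a * st$phiMax   # axial length in units of a
    ds <- sTot / nStep
    vel <- function(rq, tq) {
      w <- .polarInterp(st$w, st$wC, st$rr, st$th, rq, tq)
      ur <- .polarInterp(st$ur, 0, st$rr, st$th, rq, tq)
      ut <- .polarInterp(st$ut, 0, st$rr, st$th, rq, tq)
      list(w = pmax(w, 1e-9), ur = ur, ut = ut)
    }
    deriv <- function(rq, tq) {
      v <- vel(rq, tq)
      list(dr = v$ur / v$w, dt = ifelse(rq > 1e-6, v$ut / (rq * v$w), 0))
    }
    for (i in seq_len(nStep)) {
      k1 <- deriv(r, thc)
      k2 <- deriv(pmin(pmax(r + ds / 2 * k1$dr, 0), 0.999),
                  thc + ds / 2 * k1$dt)
      k3 <- deriv(pmin(pmax(r + ds / 2 * k2$dr, 0), 0.999),
                  thc + ds / 2 * k2$dt)
      k4 <- deriv(pmin(pmax(r + ds * k3$dr, 0), 0.999), thc + ds * k3$dt)
      r <- pmin(pmax(r + ds / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr),
                     0), 0.999)
      thc <- thc + ds / 6 * (k1$dt + 2 * k2$dt + 2 * k3$dt + k4$dt)
    }
    endHalf <- ifelse(sin(thc %% (2 * pi)) >= 0, 1, -1)
  }
  list(mixingFraction = mean(endHalf != half), startHalf = half,
       endHalf = endHalf)
}

#' Count secondary-flow cells in a curved-tube solution
#'
#' Labels the sign regions of the secondary-flow streamfunction on the
#' cross-section (theta-periodic 4-connectivity); Dean flow has exactly two
#' counter-rotating cells.
#'
#' @param field a curved-tube \linkS4class{FlowField}.
#' @param frac magnitude threshold as a fraction of max |psi|.
#' @return number of connected same-sign cells.
#' @export
countSecondaryCells <- function(field, frac = 0.05) {
  st <- field@structured
  if (st$type != "curved") stop("secondary cells defined for curved tubes")
  psi <- st$psi
  Nr <- nrow(psi); Nth <- ncol(psi)
  thr <- frac * max(abs(psi))
  sgn <- matrix(0L, Nr, Nth)
  sgn[psi > thr] <- 1L; sgn[psi < -thr] <- -1L
  idx <- which(sgn != 0L)
  if (!length(idx)) return(0L)
  id <- matrix(0L, Nr, Nth); id[idx] <- seq_along(idx)
  edges <- list()
  pos <- arrayInd(idx, c(Nr, Nth))
  # radial neighbors
  ok <- pos[, 1] < Nr
  nb <- id[cbind(pos[ok, 1] + 1L, pos[ok, 2])]
  same <- nb > 0L & sgn[idx[ok]] == sgn[cbind(pos[ok, 1] + 1L, pos[ok, 2])]
  edges[[1]] <- cbind(which(ok)[same], nb[same])
  # azimuthal neighbors (periodic)
  k2 <- ifelse(pos[, 2] == Nth, 1L, pos[, 2] + 1L)
  nb <- id[cbind(pos[, 1], k2)]
  same <- nb > 0L & sgn[idx] == sgn[cbind(pos[, 1], k2)]
  edges[[2]] <- cbind(which(same), nb[same])
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}
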