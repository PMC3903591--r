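# Steady fully developed flow in a constant-curvature tube (Dean flow):
# axial momentum plus a coupled vorticity-streamfunction system for the
# centrifugally driven secondary flow on the cross-section, solved on a
# polar node grid with a center auxiliary node and Thom wall vorticity.
# Valid in the low-Dean-number regime of the fetal great arteries; the
# solution is swept along the bend to the full 3D grid.

solveCurvedTube <- function(mesh, Vmean, props, tol = 1e-6, maxOuter = 12L) {
  a <- mesh@geom$radius; Rb <- mesh@geom$bendRadius
  phiMax <- mesh@geom$bendAngle
  Nr <- mesh@dims[["nr"]]; Nth <- mesh@dims[["ntheta"]]
  Ns <- mesh@dims[["ns"]]
  mu <- props@mu; rho <- props@density; nu <- mu / rho  # mm^2/s
  Re <- Vmean * a / nu
  delta <- a / Rb
  dr <- 1 / Nr
  th <- (seq_len(Nth) - 1) * 2 * pi / Nth
  rr <- seq_len(Nr) * dr                      # nodes, r = dr..1 (wall at Nr)
  kp <- c(2:Nth, 1); km <- c(Nth, 1:(Nth - 1))

  nid <- function(j, k) (k - 1) * Nr + j      # j = 1..Nr, k = 1..Nth
  nN <- Nr * Nth
  CTR <- nN + 1L                               # center node id

  # Laplacian triplets for a scalar with Dirichlet wall value (excluded
  # rows at j = Nr are handled by the caller).
  lapRow <- function(j, k, addf, wallDirichlet = TRUE) {
    r <- rr[j]
    addf(nid(j, k), -2 / dr^2 - 2 / (r^2 * (2 * pi / Nth)^2))
    if (j < Nr) addf(nid(j + 1, k), 1 / dr^2 + 1 / (r * 2 * dr))
    if (j > 1) addf(nid(j - 1, k), 1 / dr^2 - 1 / (r * 2 * dr))
    else addf(CTR, 1 / dr^2 - 1 / (r * 2 * dr))
    dth2 <- (2 * pi / Nth)^2
    addf(nid(j, kp[k]), 1 / (r^2 * dth2))
    addf(nid(j, km[k]), 1 / (r^2 * dth2))
  }

  # generic Poisson-type solve: ops assembled per call (small systems)
  dth <- 2 * pi / Nth

  # --- axial momentum: lap(w) - (u.grad) w = G, w|wall = 0 ---------------
  solveAxial <- function(ur, ut) {
    TI <- integer(16 * (nN + 1)); TJ <- TI; TV <- numeric(16 * (nN + 1))
    m <- 0L
    add <- function(rw, cl, v) {
      m <<- m + 1L; TI[m] <<- rw; TJ[m] <<- cl; TV[m] <<- v
    }
    b <- numeric(nN + 1)
    for (k in 1:Nth) for (j in 1:Nr) {
      rw <- nid(j, k)
      if (j == Nr) { add(rw, rw, 1); b[rw] <- 0; next }   # wall Dirichlet
      curRow <- rw
      lapRow(j, k, function(cl, v) add(curRow, cl, v))
      # advection -(ur dw/dr + ut/r dw/dth)
      if (!is.null(ur)) {
        r <- rr[j]
        if (j < Nr) add(rw, nid(j + 1, k), -ur[j, k] / (2 * dr))
        if (j > 1) add(rw, nid(j - 1, k), ur[j, k] / (2 * dr))
        else add(rw, CTR, ur[j, k] / (2 * dr))
        add(rw, nid(j, kp[k]), -ut[j, k] / (r * 2 * dth))
        add(rw, nid(j, km[k]), ut[j, k] / (r * 2 * dth))
      }
      b[rw] <- -1
    }
    # center node: lap = 4(mean(f at dr) - f_c)/dr^2 (secondary velocity ~ 0
    # at the center by symmetry)
    for (k in 1:Nth) add(CTR, nid(1, k), 4 / (Nth * dr^2))
    add(CTR, CTR, -4 / dr^2)
    b[CTR] <- -1
    A <- Matrix::sparseMatrix(i = TI[1:m], j = TJ[1:m], x = TV[1:m],
                              dims = c(nN + 1, nN + 1))
    as.numeric(Matrix::solve(A, b))
  }

  # --- coupled vorticity-streamfunction: lap(Om) = S; Om_wall by Thom;
  #     lap(psi) = -Om, psi_wall = 0 ---------------------------------------
  solveSecondary <- function(S) {
    ntot <- 2 * (nN + 1)
    iOm <- function(j, k) nid(j, k); iPs <- function(j, k) nN + 1 + nid(j, k)
    omC <- nN + 1L; psC <- 2L * nN + 2L
    TI <- integer(20 * ntot); TJ <- TI; TV <- numeric(20 * ntot); m <- 0L
    add <- function(rw, cl, v) {
      m <<- m + 1L; TI[m] <<- rw; TJ[m] <<- cl; TV[m] <<- v
    }
    b <- numeric(ntot)
    for (k in 1:Nth) for (j in 1:Nr) {
      rw <- iOm(j, k)
      if (j == Nr) {               # Thom: Om_wall = -2 psi_{Nr-1}/dr^2
        add(rw, rw, 1)
        add(rw, iPs(Nr - 1, k), 2 / dr^2)
        next
      }
      curRow <- rw
      lapRow(j, k, function(cl, v) add(curRow, cl, v))
      b[rw] <- S[j, k]
    }
    for (k in 1:Nth) add(omC, iOm(1, k), 4 / (Nth * dr^2))
    add(omC, omC, -4 / dr^2)
    b[omC] <- 0                    # source vanishes at the center by symmetry
    for (k in 1:Nth) for (j in 1:Nr) {
      rw <- iPs(j, k)
      if (j == Nr) { add(rw, rw, 1); next }  # psi = 0 at wall
      curRow <- rw
      lapRow(j, k, function(cl, v) add(curRow, cl + nN + 1L, v))
      add(rw, iOm(j, k), 1)        # lap(psi) + Om = 0
    }
    for (k in 1:Nth) add(psC, iPs(1, k), 4 / (Nth * dr^2))
    add(psC, psC, -4 / dr^2)
    add(psC, omC, 1)
    A <- Matrix::sparseMatrix(i = TI[1:m], j = TJ[1:m], x = TV[1:m],
                              dims = c(ntot, ntot))
    x <- as.numeric(Matrix::solve(A, b))
    list(Om = matrix(x[1:nN], Nr, Nth), OmC = x[nN + 1],
         psi = matrix(x[(nN + 2):(2 * nN + 1)], Nr, Nth),
         psiC = x[2 * nN + 2])
  }

  discMean <- function(w, wC) {
    # area-weighted mean over the unit disc (node j owns the annulus
    # [r_j - dr/2, r_j + dr/2] split over the Nth sectors)
    rOut <- pmin(rr + dr / 2, 1); rIn <- rr - dr / 2
    aw <- pi * (rOut^2 - rIn^2) / Nth
    (sum(sweep(w, 1, aw, `*`)) + wC * pi * (dr / 2)^2) / pi
  }

  gradY <- function(f, fC) {
    # d f / dy, y = r sin(theta): sin(th) df/dr + cos(th)/r df/dth
    dfr <- f
    dfr[2:(Nr - 1), ] <- (f[3:Nr, ] - f[1:(Nr - 2), ]) / (2 * dr)
    dfr[1, ] <- (f[2, ] - fC) / (2 * dr)
    dfr[Nr, ] <- (f[Nr, ] - f[Nr - 1, ]) / dr
    dft <- (f[, kp] - f[, km]) / (2 * dth)
    sweep(dfr, 2, sin(th), `*`) + sweep(dft, 2, cos(th) / 1, `*`) / rr
  }

  # --- outer iteration -----------------------------------------------------
  wv <- solveAxial(NULL, NULL)
  w <- matrix(wv[1:nN], Nr, Nth); wC <- wv[nN + 1]
  scale0 <- Re / discMean(w, wC)
  w <- w * scale0; wC <- wC * scale0
  psi <- matrix(0, Nr, Nth); Om <- psi
  resHist <- numeric(0)
  for (it in seq_len(maxOuter)) {
    S <- delta * gradY(w^2, wC^2)
    sec <- solveSecondary(S)
    psiN <- sec$psi; OmN <- sec$Om
    # secondary velocities u_r = (1/r) dpsi/dth, u_t = -dpsi/dr
    ur <- (psiN[, kp] - psiN[, km]) / (2 * dth) / rr
    ut <- psiN
    ut[2:(Nr - 1), ] <- -(psiN[3:Nr, ] - psiN[1:(Nr - 2), ]) / (2 * dr)
    ut[1, ] <- -(psiN[2, ] - sec$psiC) / (2 * dr)
    ut[Nr, ] <- 0
    ur[Nr, ] <- 0
    wv <- solveAxial(ur, ut)
    wN <- matrix(wv[1:nN], Nr, Nth); wCN <- wv[nN + 1]
    sc <- Re / discMean(wN, wCN)
    wN <- wN * sc; wCN <- wCN * sc
    chg <- max(max(abs(wN - w)) / max(abs(wN)),
               if (max(abs(psiN)) > 0)
                 max(abs(psiN - psi)) / max(abs(psiN)) else 0)
    resHist <- c(resHist, chg)
    w <- wN; wC <- wCN; psi <- psiN; Om <- OmN
    if (chg < tol) break
  }
  if (tail(resHist, 1) > 100 * tol)
    warning("curved-tube solver: outer iteration change ",
            sprintf("%.2e", tail(resHist, 1)))

  # secondary velocities from the converged psi
  ur <- (psi[, kp] - psi[, km]) / (2 * dth) / rr
  ut <- psi
  ut[2:(Nr - 1), ] <- -(psi[3:Nr, ] - psi[1:(Nr - 2), ]) / (2 * dr)
  ut[1, ] <- -(psi[2, ] - 0) / (2 * dr)
  ut[Nr, ] <- 0; ur[Nr, ] <- 0

  # in-plane vorticity of the axial flow: (dw/dy) x_hat - (dw/dx) y_hat
  dwr <- w
  dwr[2:(Nr - 1), ] <- (w[3:Nr, ] - w[1:(Nr - 2), ]) / (2 * dr)
  dwr[1, ] <- (w[2, ] - wC) / (2 * dr)
  dwr[Nr, ] <- (0 - w[Nr - 1, ]) / (2 * dr)   # wall value 0
  dwt <- (w[, kp] - w[, km]) / (2 * dth)
  dwdx <- sweep(dwr, 2, cos(th), `*`) - sweep(dwt, 2, sin(th), `*`) / rr
  dwdy <- sweep(dwr, 2, sin(th), `*`) + sweep(dwt, 2, cos(th), `*`) / rr

  # dimensional scales
  vs <- nu / a          # velocity unit, mm/s
  os <- nu / a^2        # vorticity unit, 1/s

  # sweep along the bend onto the mesh node ordering (r fastest, then
  # theta, then station)
  phi <- seq(0, phiMax, length.out = Ns)
  velL <- vector("list", Ns); vortL <- vector("list", Ns)
  presL <- vector("list", Ns)
  cosT <- matrix(rep(cos(th), each = Nr), Nr, Nth)
  sinT <- matrix(rep(sin(th), each = Nr), Nr, Nth)
  ux <- ur * cosT - ut * sinT
  uy <- ur * sinT + ut * cosT
  for (mIdx in seq_len(Ns)) {
    p <- phi[mIdx]
    ex <- c(cos(p), 0, sin(p)); ey <- c(0, 1, 0)
    tv <- c(-sin(p), 0, cos(p))
    wf <- as.vector(w) * vs; uxf <- as.vector(ux) * vs
    uyf <- as.vector(uy) * vs
    velL[[mIdx]] <- cbind(wf * tv[1] + uxf * ex[1] + uyf * ey[1],
                          wf * tv[2] + uxf * ex[2] + uyf * ey[2],
                          wf * tv[3] + uxf * ex[3] + uyf * ey[3])
    of <- as.vector(Om) * os
    oxf <- as.vector(dwdy) * os; oyf <- as.vector(-dwdx) * os
    vortL[[mIdx]] <- cbind(of * tv[1] + oxf * ex[1] + oyf * ey[1],
                           of * tv[2] + oxf * ex[2] + oyf * ey[2],
                           of * tv[3] + oxf * ex[3] + oyf * ey[3])
    presL[[mIdx]] <- rep(-p * Rb / a * mu * nu / a^2 / 1000, nN)
  }

  gammaAx <- abs((4 * w[Nr - 1, ] - w[Nr - 2, ]) / (2 * dr)) * os
  gammaTh <- abs((4 * ut[Nr - 1, ] - ut[Nr - 2, ]) / (2 * dr)) * os
  gammaWall <- sqrt(gammaAx^2 + gammaTh^2)

  structured <- list(type = "curved", w = w, wC = wC, psi = psi, Om = Om,
                     ur = ur, ut = ut, rr = rr, th = th, dr = dr,
                     a = a, Rb = Rb, phiMax = phiMax, nu = nu, mu = mu,
                     Re = Re, delta = delta, Vmean = Vmean,
                     velScale = vs, vortScale = os,
                     gammaWall = gammaWall, Ns = Ns)
  new("FlowField", mesh = mesh, velocity = do.call(rbind, velL),
      pressure = unlist(presL), vorticity = do.call(rbind, vortL),
      divergenceNorm = 0, residuals = resHist, structured = structured)
}
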