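# Steady incompressible Newtonian flow in a straight tube: axisymmetric
# staggered finite volumes (u_z at z-faces, u_r at r-faces, p at centers),
# plug inlet, no-slip wall, zero-gradient outflow with outlet-face pressure
# reference. Stokes operator assembled once; convection added by Picard
# iteration. The converged axisymmetric solution is revolved onto the full
# 3D tube grid.

solveStraightTube <- function(mesh, Vin, props, tol = 1e-6,
                              maxPicard = 30L) {
  R <- mesh@geom$radius; L <- mesh@geom$length
  Nz <- mesh@dims[["ns"]]; Nr <- mesh@dims[["nr"]]
  Nth <- mesh@dims[["ntheta"]]
  mu <- props@mu; rho <- props@density
  Re <- rho * Vin * R / mu        # rho g/cm3, Vin mm/s, R mm, mu mPa.s
  dz <- (L / R) / Nz; dr <- 1 / Nr

  nU <- Nz * Nr; nV <- Nz * (Nr - 1); nP <- Nz * Nr
  iu <- function(i, j) (i - 2) * Nr + j            # i in 2..Nz+1
  iv <- function(i, j) nU + (i - 1) * (Nr - 1) + (j - 1)  # j in 2..Nr
  ip <- function(i, j) nU + nV + (i - 1) * Nr + j
  ntot <- nU + nV + nP

  TI <- integer(0); TJ <- integer(0); TV <- numeric(0)
  b <- numeric(ntot)
  addT <- function(r, c, v) {
    TI[[length(TI) + 1L]] <<- r; TJ[[length(TJ) + 1L]] <<- c
    TV[[length(TV) + 1L]] <<- v
  }
  # use environments of growing lists is slow; preallocate instead
  cap <- 14L * ntot
  TI <- integer(cap); TJ <- integer(cap); TV <- numeric(cap); nT <- 0L
  addT <- function(r, c, v) {
    nT <<- nT + 1L
    TI[nT] <<- r; TJ[nT] <<- c; TV[nT] <<- v
  }

  # --- z-momentum ----------------------------------------------------------
  for (i in 2:(Nz + 1)) for (j in 1:Nr) {
    row <- iu(i, j)
    rc <- (j - 0.5) * dr; rp <- j * dr; rm <- (j - 1) * dr
    # radial viscous
    if (j < Nr) {
      addT(row, iu(i, j + 1), rp / (rc * dr^2))
      addT(row, iu(i, j), -(rp + rm) / (rc * dr^2))
    } else {
      addT(row, iu(i, j), -(2 * rp + rm) / (rc * dr^2))
    }
    if (j > 1) addT(row, iu(i, j - 1), rm / (rc * dr^2))
    # axial viscous
    if (i <= Nz) addT(row, iu(i + 1, j), 1 / dz^2)
    if (i == Nz + 1) {
      addT(row, iu(i, j), -1 / dz^2)       # ghost u[Nz+2] = u[Nz+1]
    } else {
      addT(row, iu(i, j), -2 / dz^2)
    }
    if (i > 2) addT(row, iu(i - 1, j), 1 / dz^2)
    else b[row] <- b[row] - 1 / dz^2       # inlet plug u = 1
    # pressure gradient
    if (i <= Nz) {
      addT(row, ip(i, j), -1 / dz)
      addT(row, ip(i - 1, j), 1 / dz)
    } else {
      addT(row, ip(Nz, j), 2 / dz)         # outlet face pressure = 0
    }
  }

  # --- r-momentum ----------------------------------------------------------
  if (Nr >= 2) for (i in 1:Nz) for (j in 2:Nr) {
    row <- iv(i, j)
    rvj <- (j - 1) * dr; rvp <- j * dr; rvm <- (j - 2) * dr
    rcj <- (j - 0.5) * dr; rcm <- (j - 1.5) * dr
    # radial viscous d/dr[(1/r) d(r v)/dr]
    if (j < Nr) addT(row, iv(i, j + 1), rvp / (rcj * dr^2))
    addT(row, iv(i, j), -rvj / (rcj * dr^2) - rvj / (rcm * dr^2))
    if (j > 2) addT(row, iv(i, j - 1), rvm / (rcm * dr^2))
    # axial viscous
    if (i < Nz) addT(row, iv(i + 1, j), 1 / dz^2)
    if (i > 1) addT(row, iv(i - 1, j), 1 / dz^2)
    cc <- -2 / dz^2
    if (i == 1) cc <- cc - 1 / dz^2        # inlet ghost v = -v
    if (i == Nz) cc <- cc + 1 / dz^2       # outlet ghost v = v
    addT(row, iv(i, j), cc)
    # pressure gradient
    addT(row, ip(i, j), -1 / dr)
    addT(row, ip(i, j - 1), 1 / dr)
  }

  # --- continuity ----------------------------------------------------------
  for (i in 1:Nz) for (j in 1:Nr) {
    row <- ip(i, j)
    rc <- (j - 0.5) * dr; rfp <- j * dr; rfm <- (j - 1) * dr
    addT(row, iu(i + 1, j), 1 / dz)
    if (i > 1) addT(row, iu(i, j), -1 / dz)
    else b[row] <- b[row] + 1 / dz         # inlet plug u = 1
    if (j < Nr) addT(row, iv(i, j + 1), rfp / (rc * dr))
    if (j > 1) addT(row, iv(i, j), -rfm / (rc * dr))
  }

  Abase <- Matrix::sparseMatrix(i = TI[1:nT], j = TJ[1:nT], x = TV[1:nT],
                                dims = c(ntot, ntot))

  # Picard convection assembly from current fields U0 (Nz+1 x Nr, row 1 =
  # inlet plug), V0 (Nz x Nr+1 with boundary zeros).
  convTriplets <- function(U0, V0) {
    ci <- integer(12L * ntot); cj <- integer(12L * ntot)
    cv <- numeric(12L * ntot); bc2 <- numeric(ntot); m <- 0L
    put <- function(r, c, v) {
      m <<- m + 1L; ci[m] <<- r; cj[m] <<- c; cv[m] <<- v
    }
    for (i in 2:(Nz + 1)) for (j in 1:Nr) {
      row <- iu(i, j)
      u0 <- U0[i, j]
      v0 <- if (i <= Nz) (V0[i - 1, j] + V0[i - 1, j + 1] +
                            V0[i, j] + V0[i, j + 1]) / 4
            else (V0[Nz, j] + V0[Nz, j + 1]) / 2
      # -Re * u0 * du/dz
      if (i <= Nz) {
        put(row, iu(i + 1, j), -Re * u0 / (2 * dz))
        if (i > 2) put(row, iu(i - 1, j), Re * u0 / (2 * dz))
        else bc2[row] <- bc2[row] - Re * u0 / (2 * dz)
      } else {
        put(row, iu(i, j), -Re * u0 / dz)
        put(row, iu(i - 1, j), Re * u0 / dz)
      }
      # -Re * v0 * du/dr
      if (j == 1) {
        put(row, iu(i, 2), -Re * v0 / (2 * dr))
        put(row, iu(i, 1), Re * v0 / (2 * dr))
      } else if (j == Nr) {
        put(row, iu(i, Nr), Re * v0 / (2 * dr))
        put(row, iu(i, Nr - 1), Re * v0 / (2 * dr))
      } else {
        put(row, iu(i, j + 1), -Re * v0 / (2 * dr))
        put(row, iu(i, j - 1), Re * v0 / (2 * dr))
      }
    }
    if (Nr >= 2) for (i in 1:Nz) for (j in 2:Nr) {
      row <- iv(i, j)
      u0 <- (U0[i, j] + U0[i + 1, j] + U0[i, j - 1] + U0[i + 1, j - 1]) / 4
      v0 <- V0[i, j]
      # -Re * u0 * dv/dz
      if (i == 1) {
        put(row, iv(2, j), -Re * u0 / (2 * dz))
        put(row, iv(1, j), -Re * u0 / (2 * dz))
      } else if (i == Nz) {
        put(row, iv(Nz, j), -Re * u0 / (2 * dz))
        put(row, iv(Nz - 1, j), Re * u0 / (2 * dz))
      } else {
        put(row, iv(i + 1, j), -Re * u0 / (2 * dz))
        put(row, iv(i - 1, j), Re * u0 / (2 * dz))
      }
      # -Re * v0 * dv/dr (boundary neighbors are zero)
      if (j < Nr) put(row, iv(i, j + 1), -Re * v0 / (2 * dr))
      if (j > 2) put(row, iv(i, j - 1), Re * v0 / (2 * dr))
    }
    list(A = Matrix::sparseMatrix(i = ci[1:m], j = cj[1:m], x = cv[1:m],
                                  dims = c(ntot, ntot)), b = bc2)
  }

  unpack <- function(x) {
    U <- matrix(0, Nz + 1, Nr); U[1, ] <- 1
    for (i in 2:(Nz + 1)) U[i, ] <- x[iu(i, 1):iu(i, Nr)]
    V <- matrix(0, Nz, Nr + 1)
    if (Nr >= 2) for (i in 1:Nz) V[i, 2:Nr] <- x[iv(i, 2):iv(i, Nr)]
    P <- matrix(0, Nz, Nr)
    for (i in 1:Nz) P[i, ] <- x[ip(i, 1):ip(i, Nr)]
    list(U = U, V = V, P = P)
  }

  # --- solve ---------------------------------------------------------------
  x <- Matrix::solve(Abase, b)
  resHist <- numeric(0)
  if (Re > 1e-12) {
    for (it in seq_len(maxPicard)) {
      f <- unpack(as.numeric(x))
      cv <- convTriplets(f$U, f$V)
      A <- Abase + cv$A
      rhs <- b + cv$b
      res <- sqrt(sum(as.numeric(A %*% x - rhs)^2)) /
        max(1e-300, sqrt(sum(rhs^2)))
      resHist <- c(resHist, res)
      if (res < tol) break
      x <- Matrix::solve(A, rhs)
    }
    if (tail(resHist, 1) >= tol && length(resHist) >= maxPicard)
      stop("steady solver did not converge: residual history ",
           paste(sprintf("%.2e", resHist), collapse = ", "))
  } else {
    f <- unpack(as.numeric(x))
    res <- sqrt(sum(as.numeric(Abase %*% x - b)^2)) / sqrt(sum(b^2))
    resHist <- res
  }
  f <- unpack(as.numeric(x))

  # divergence residual (dimensionless)
  div <- matrix(0, Nz, Nr)
  for (i in 1:Nz) for (j in 1:Nr) {
    rc <- (j - 0.5) * dr
    div[i, j] <- (f$U[i + 1, j] - f$U[i, j]) / dz +
      (j * dr * f$V[i, j + 1] - (j - 1) * dr * f$V[i, j]) / (rc * dr)
  }

  # cell-center fields (dimensional)
  uc <- (f$U[1:Nz, , drop = FALSE] + f$U[2:(Nz + 1), , drop = FALSE]) / 2 * Vin
  vc <- (f$V[, 1:Nr, drop = FALSE] + f$V[, 2:(Nr + 1), drop = FALSE]) / 2 * Vin
  pc <- f$P * mu * Vin / R / 1000          # Pa
  # azimuthal vorticity at centers: dv/dz - du/dr (dimensional, 1/s)
  ddz <- function(M) {
    out <- M
    out[2:(Nz - 1), ] <- (M[3:Nz, , drop = FALSE] -
                            M[1:(Nz - 2), , drop = FALSE]) / (2 * dz)
    out[1, ] <- (M[2, ] - M[1, ]) / dz
    out[Nz, ] <- (M[Nz, ] - M[Nz - 1, ]) / dz
    out
  }
  ddr <- function(M) {
    out <- M
    out[, 2:(Nr - 1)] <- (M[, 3:Nr, drop = FALSE] -
                            M[, 1:(Nr - 2), drop = FALSE]) / (2 * dr)
    out[, 1] <- (M[, 2] - M[, 1]) / dr
    out[, Nr] <- (0 - M[, Nr - 1]) / (2 * dr)  # wall value ~ 0 beyond
    out
  }
  wth <- (ddz(vc / Vin) - ddr(uc / Vin)) * Vin / R

  # expand to the 3D node set (same ordering as tubeMesh nodes)
  th <- (seq_len(Nth) - 1) * 2 * pi / Nth
  jIdx <- rep(rep(1:Nr, Nth), Nz)
  kIdx <- rep(rep(1:Nth, each = Nr), Nz)
  iIdx <- rep(1:Nz, each = Nr * Nth)
  lin <- cbind(iIdx, jIdx)
  ct <- cos(th)[kIdx]; st <- sin(th)[kIdx]
  vel <- cbind(vc[lin] * ct, vc[lin] * st, uc[lin])
  vort <- cbind(-wth[lin] * st, wth[lin] * ct, 0)
  pres <- pc[lin]

  # one-sided second-order wall shear rate per axial cell (1/s)
  gammaWall <- abs((9 * f$U[1:Nz + 1, Nr] - f$U[1:Nz + 1, Nr - 1]) /
                     (3 * dr)) * Vin / R

  structured <- list(type = "straight", U = f$U, V = f$V, P = f$P,
                     dz = dz, dr = dr, R = R, L = L, Vin = Vin,
                     mu = mu, rho = rho, Re = Re,
                     zc = (seq_len(Nz) - 0.5) * dz * R,
                     rc = (seq_len(Nr) - 0.5) * dr * R,
                     theta = th, uc = uc, vc = vc, wth = wth,
                     gammaWall = gammaWall)
  new("FlowField", mesh = mesh, velocity = vel, pressure = pres,
      vorticity = vort, divergenceNorm = max(abs(div)),
      residuals = resHist, structured = structured)
}
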