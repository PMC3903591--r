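# Straight-tube steady solver against the Poiseuille closed form.

props <- testProps()
R <- 0.3; L <- 2.4

test_that("developing plug flow reaches the Poiseuille profile within 1 percent", {
  mesh <- tubeMesh(R, L, nr = 16, nz = 64, ntheta = 8)
  fld <- solveSteady3D(mesh, list(inletVelocity = 50), props)
  st <- fld@structured
  uex <- st$U[nrow(st$U), ] * 50
  ana <- 2 * 50 * (1 - (st$rc / R)^2)
  expect_lt(max(abs(uex - ana)) / (2 * 50), 0.01)
  # wall shear within 3 percent of 4 mu Q / (pi R^3) over the developed half
  Q <- 50 * pi * R^2
  ws <- wallShear(fld, props = props)
  tauAna <- 4 * props@mu * Q / (pi * R^3)
  expect_lt(abs(mean(ws@tau[ws@s > L / 2]) - tauAna) / tauAna, 0.03)
  # mass conservation within 0.1 percent
  rf <- (0:16) * R / 16
  annuli <- pi * (rf[-1]^2 - rf[-17]^2)
  fluxIn <- sum(st$U[1, ] * 50 * annuli)
  fluxOut <- sum(st$U[nrow(st$U), ] * 50 * annuli)
  expect_lt(abs(fluxOut - fluxIn) / fluxIn, 1e-3)
  expect_lt(fld@divergenceNorm, 1e-8)
})

test_that("the discretization converges at first order or better", {
  err <- function(level) {
    mesh <- tubeMesh(R, L, level = level, nr = 8, nz = 32, ntheta = 8)
    fld <- solveSteady3D(mesh, list(inletVelocity = 10), props)
    st <- fld@structured
    uex <- st$U[nrow(st$U), ] * 10
    max(abs(uex - 2 * 10 * (1 - (st$rc / R)^2))) / 20
  }
  e0 <- err(0); e1 <- err(1)
  expect_gte(log2(e0 / e1), 1)
})

test_that("refinement-level mean wall shear differs by less than 5 percent", {
  f0 <- solveSteady3D(tubeMesh(R, L, level = 0, nr = 8, nz = 32, ntheta = 8),
                      list(inletVelocity = 10), props)
  f1 <- solveSteady3D(tubeMesh(R, L, level = 1, nr = 8, nz = 32, ntheta = 8),
                      list(inletVelocity = 10), props)
  expect_lt(gridIndependence(f0, f1, "mean_wss"), 0.05)
  expect_equal(gridIndependence(f0, f0, "mean_wss"), 0)
  expect_error(gridIndependence(
    f0, solveSteady3D(tubeMesh(0.2, L, nr = 8, nz = 32, ntheta = 8),
                      list(inletVelocity = 10), props)),
    "different geometries")
})

test_that("the Stokes limit is linear in the boundary velocity", {
  mesh <- tubeMesh(R, L, nr = 12, nz = 48, ntheta = 8)
  fa <- solveSteady3D(mesh, list(inletVelocity = 1), props)
  fb <- solveSteady3D(mesh, list(inletVelocity = 2), props)
  expect_lte(fa@structured$Re, 1)
  dev <- max(abs(fb@velocity - 2 * fa@velocity)) / max(abs(fb@velocity))
  expect_lt(dev, 0.01)
})

test_that("reduced-order and 3D wall shear agree on a straight tube", {
  Vin <- 20
  mesh <- tubeMesh(R, L, nr = 16, nz = 64, ntheta = 8)
  fld <- solveSteady3D(mesh, list(inletVelocity = Vin), props)
  net <- solvePoiseuilleNetwork(
    data.frame(role = "tube", radius_mm = R, length_mm = L,
               flow_mm3_s = Vin * pi * R^2), NULL, props)
  ws <- wallShear(fld, props = props)
  expect_lt(abs(mean(ws@tau[ws@s > L / 2]) - net$tau_mPa) / net$tau_mPa,
            0.03)
})

test_that("configurations outside the laminar regime are rejected", {
  mesh <- tubeMesh(R, L, nr = 8, nz = 16, ntheta = 8)
  expect_error(solveSteady3D(mesh, list(inletVelocity = 5000), props),
               "laminar")
})
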