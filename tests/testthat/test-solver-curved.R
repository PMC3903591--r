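# Curved-tube (Dean) solver: secondary-flow structure, helicity symmetry,
# tracer order.

props <- testProps()
a <- 0.25; Rb <- 0.45

test_that("low-Dean curved flow has two mirror-symmetric counter-rotating cells", {
  mesh <- curvedTubeMesh(a, Rb, bendAngle = pi / 2)
  fld <- solveSteady3D(mesh, list(inletVelocity = 60), props)
  expect_equal(countSecondaryCells(fld), 2L)
  st <- fld@structured
  # mirror antisymmetry of the streamfunction about the curvature plane
  Nth <- length(st$th)
  flip <- c(1, Nth:2)
  expect_lt(max(abs(st$psi + st$psi[, flip])) / max(abs(st$psi)), 1e-8)
  # cross-plane kinetic-energy antisymmetry below 5 percent
  ke <- st$ur^2 + st$ut^2
  upper <- st$th > 0 & st$th < pi
  asym <- abs(sum(ke[, upper]) - sum(ke[, st$th > pi])) / sum(ke)
  expect_lt(asym, 0.05)
})

test_that("normalized helicity is bounded and chirality-balanced on the arch", {
  mesh <- curvedTubeMesh(a, Rb, bendAngle = pi / 2)
  fld <- solveSteady3D(mesh, list(inletVelocity = 60), props)
  hel <- normalizedHelicity(fld)
  expect_true(all(abs(hel@hn) <= 1))
  expect_gt(max(abs(hel@hn)), 0.1)   # genuinely helical secondary flow
  bal <- helicityBalance(hel)
  expect_lt(bal$imbalance, 0.10)
})

test_that("straight-tube flow has negligible normalized helicity", {
  mesh <- tubeMesh(0.3, 2.4, nr = 12, nz = 48, ntheta = 8)
  fld <- solveSteady3D(mesh, list(inletVelocity = 30), props)
  hel <- normalizedHelicity(fld)
  expect_lt(max(abs(hel@hn)), 0.02)
})

test_that("helicity degeneracy floor zeroes samples with vanishing magnitudes", {
  mesh <- tubeMesh(0.2, 1, nr = 6, nz = 12, ntheta = 6)
  fld <- solveSteady3D(mesh, list(inletVelocity = 5), props)
  fld@velocity[] <- 0
  hel <- normalizedHelicity(fld)
  expect_true(all(hel@hn == 0))
  # constructed aligned / orthogonal vectors
  fld@velocity <- matrix(rep(c(1, 0, 0), each = nrow(fld@velocity)),
                         ncol = 3)
  fld@vorticity <- matrix(rep(c(1, 0, 0), each = nrow(fld@velocity)),
                          ncol = 3)
  expect_true(all(normalizedHelicity(fld)@hn == 1))
  fld@vorticity <- matrix(rep(c(0, 1, 0), each = nrow(fld@velocity)),
                          ncol = 3)
  expect_true(all(normalizedHelicity(fld)@hn == 0))
})

test_that("tracers released in the two halves stay in disjoint sectors", {
  mesh <- curvedTubeMesh(a, Rb, bendAngle = pi / 2)
  fld <- solveSteady3D(mesh, list(inletVelocity = 60), props)
  mix <- tracerMixing(fld, n = 200, seed = 3L)
  expect_lt(mix$mixingFraction, 0.05)
  # straight tube: axisymmetric flow cannot mix the halves at all
  fs <- solveSteady3D(tubeMesh(0.3, 2.4, nr = 12, nz = 48, ntheta = 8),
                      list(inletVelocity = 30), props)
  expect_equal(tracerMixing(fs, n = 100, seed = 4L)$mixingFraction, 0)
})
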