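props <- testProps()

test_that("wall shear stress is mu times shear rate at every sample", {
  fld <- solveSteady3D(tubeMesh(0.25, 1.5, nr = 10, nz = 30, ntheta = 8),
                       list(inletVelocity = 25), props)
  ws <- wallShear(fld, props = props)
  expect_equal(ws@tau, props@mu * ws@gamma, tolerance = 1e-12)
  expect_true(all(ws@tau >= 0))
  expect_true(validObject(ws))
})

test_that("centerline hemodynamics evaluate Re and Womersley from station quantities", {
  cfg <- makeStageConfig(18.5)
  # unit-arithmetic check: Vc = 10 mm/s, a = 0.25 mm, nu = 2.5 mm^2/s -> Re = 1
  cl <- pointsCenterline(cbind(0, 0, seq(0, 1, length.out = 11)),
                         radius = 0.25)
  bp <- new("BloodProperties", hct = 0.35, mu = 2.5 * 1.06, nu = 2.5,
            density = 1.06, note = "")
  ch <- centerlineHemodynamics(rep(10, 11), cl, bp, cfg)
  expect_equal(ch$Re, rep(1, 11))
  expect_equal(ch$alpha, rep(0.25 * sqrt(cfg@omega / 2.5), 11))
  # null velocity: Re = 0, alpha unchanged
  ch0 <- centerlineHemodynamics(rep(0, 11), cl, bp, cfg)
  expect_true(all(ch0$Re == 0))
  expect_equal(ch0$alpha, ch$alpha)
})

test_that("centerline velocities sampled from the 3D field match the axial profile", {
  R <- 0.3; L <- 2.4; Vin <- 20
  fld <- solveSteady3D(tubeMesh(R, L, nr = 16, nz = 64, ntheta = 8),
                       list(inletVelocity = Vin), props)
  pts <- cbind(0, 0, seq(1.6, 2.2, length.out = 9))
  cl <- pointsCenterline(pts, radius = R)
  ch <- centerlineHemodynamics(fld, cl, props, makeStageConfig(16.5))
  expect_true(all(abs(ch$Vc_mm_s / (2 * Vin) - 1) < 0.03))
  expect_false(any(ch$flagged))
  # outside-domain stations are flagged
  far <- pointsCenterline(cbind(0, 0, c(5, 6, 7)), radius = R)
  expect_warning(chF <- centerlineHemodynamics(fld, far, props,
                                               makeStageConfig(16.5)),
                 "outside")
  expect_true(all(chF$flagged))
})

test_that("unwrapped maps are faithful: uniform fields, hole bookkeeping, mean", {
  L <- 1.6
  fld <- solveSteady3D(tubeMesh(0.2, L, nr = 12, nz = 48, ntheta = 16),
                       list(inletVelocity = 20), props)
  ws <- wallShear(fld, props = props)
  # bins commensurate with the wall grid so binning is exact averaging
  mp <- unwrapMap(ws, nS = 24L, nTheta = 16L)
  expect_lt(abs(mean(mp@values) - mean(ws@tau)) / mean(ws@tau), 0.01)
  # developed region of a straight tube: constant map
  dv <- mp@values[mp@s > L / 2, ]
  expect_lt((max(dv) - min(dv)) / mean(dv), 0.02)
  # one hole at a landmark
  mph <- unwrapMap(ws, nS = 24L, nTheta = 16L,
                   landmarks = data.frame(s_mm = 0.8, theta_deg = 90,
                                          radius_mm = 0.1))
  expect_equal(mapHoleCount(mph), 1L)
  expect_true(all(is.na(mph@values[mph@holes])))
  mp2 <- unwrapMap(ws, nS = 24L, nTheta = 16L,
                   landmarks = data.frame(s_mm = c(0.4, 1.2),
                                          theta_deg = c(0, 180),
                                          radius_mm = c(0.08, 0.08)))
  expect_equal(mapHoleCount(mp2), 2L)
})

test_that("unwrapped curved-arch maps localize the azimuthal shear pattern", {
  fld <- solveSteady3D(curvedTubeMesh(0.25, 0.45, bendAngle = pi / 2),
                       list(inletVelocity = 60), props)
  ws <- wallShear(fld, props = props)
  mp <- unwrapMap(ws, nS = 17L, nTheta = 32L)
  # the map's azimuthal maximum reproduces the wall-sample maximum
  mapArg <- mp@theta[which.max(colMeans(mp@values))]
  smpArg <- ws@theta[which.max(ws@tau)]
  dAng <- abs((mapArg - smpArg + 180) %% 360 - 180)
  expect_lt(dAng, 25)
  # the azimuthal contrast in the map matches the samples within binning
  expect_equal(max(colMeans(mp@values)) / min(colMeans(mp@values)),
               max(ws@tau) / min(ws@tau), tolerance = 0.05)
})
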