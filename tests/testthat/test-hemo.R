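test_that("the hematocrit schedule is linear through its anchors", {
  expect_equal(hctAtAge(10.5), 0.20)
  expect_equal(hctAtAge(19.5), 0.438)
  expect_equal(hctAtAge((10.5 + 19.5) / 2), 0.319)
  expect_error(hctAtAge(9.0), "out of")
  expect_error(hctAtAge(20.5), "out of")
})

test_that("the viscosity law reproduces the calibrated endpoint viscosities", {
  expect_equal(viscosityFromHct(hctAtAge(11.5))@nu, 1.87, tolerance = 1e-9)
  expect_equal(viscosityFromHct(hctAtAge(18.5))@nu, 2.53, tolerance = 1e-9)
  # monotone in hematocrit
  nus <- vapply(c(0.20, 0.30, 0.438), function(hh) viscosityFromHct(hh)@nu,
                numeric(1))
  expect_true(all(diff(nus) > 0))
  # dynamic/kinematic consistency through the density
  bp <- viscosityFromHct(0.35, density = 1.06)
  expect_equal(bp@nu, bp@mu / bp@density, tolerance = 1e-9)
  # out-of-validity hematocrits warn in the note but still return
  expect_match(viscosityFromHct(0.05)@note, "outside")
  expect_error(viscosityFromHct(1.2), "in \\(0, 1\\)")
})

test_that("Murray fractions follow the cube law and normalize", {
  expect_equal(unname(murrayFractions(c(1, 1))), c(0.5, 0.5))
  expect_equal(unname(murrayFractions(c(2, 1))), c(8 / 9, 1 / 9))
  rng <- fetoflow:::setLocalSeed(21L)
  for (k in 1:20) {
    r <- runif(sample(2:6, 1), 0.05, 2)
    f <- murrayFractions(r)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f > 0 & f < 1))
  }
  fetoflow:::restoreSeed(rng)
  expect_error(murrayFractions(numeric(0)), "empty")
  expect_error(murrayFractions(c(1, 0)), "> 0")
})

test_that("boundary assembly satisfies the parabolic-flow relation and mass balance", {
  model <- velocityAgeModel(defaultVelocityCoeffs())
  tr <- generateVesselTree(makeStageConfig(16.5, seed = 2L))
  bc <- assembleBoundaries(tr, model, 16.5)
  # Q_dao = V * pi R^2 / 2 (parabolic mean is half of peak)
  V <- evalVelocity(model, 16.5)
  Rdao <- bc@outlets$radius_mm[bc@outlets$role == "descending_aorta"]
  expect_equal(bc@outlets$flow_mm3_s[bc@outlets$role == "descending_aorta"],
               V * pi * Rdao^2 / 2, tolerance = 1e-12)
  # global mass balance to 1e-9 relative
  expect_lt(abs(sum(bc@inlets$flow_mm3_s) - sum(bc@outlets$flow_mm3_s)) /
              bc@totalFlow, 1e-9)
  # both root plug velocities equal
  expect_equal(diff(bc@inlets$velocity_mm_s), 0)
  # assembled outlet flows reproduce the Murray fractions exactly
  fr <- murrayFractions(bc@outlets$radius_mm)
  expect_equal(bc@outlets$flow_mm3_s / bc@totalFlow, unname(fr),
               tolerance = 1e-12)
  # outlet peak velocities back-computed from parabolic profiles
  expect_equal(bc@outlets$peak_velocity_mm_s,
               2 * bc@outlets$flow_mm3_s / (pi * bc@outlets$radius_mm^2))
})

test_that("dimensionless outputs are invariant under a length-unit change", {
  # scale all radii mm -> cm: fractions unchanged
  r <- c(0.28, 0.13, 0.09)
  expect_equal(unname(murrayFractions(r)), unname(murrayFractions(r / 10)))
  # Reynolds number invariance: V ~ 1/L for fixed Q, so use consistent Q
  props <- testProps()
  net1 <- solvePoiseuilleNetwork(
    data.frame(role = "t", radius_mm = 0.3, length_mm = 2, flow_mm3_s = 5),
    NULL, props)
  # same physical tube expressed in cm: Q in cm^3/s, R in cm; nu must also
  # be in cm^2/s, i.e. Re = 2Q/(pi R nu) is unit-free
  Re2 <- 2 * (5 / 1000) / (pi * 0.03 * (props@nu / 100))
  expect_equal(net1$Re, Re2, tolerance = 1e-12)
})
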