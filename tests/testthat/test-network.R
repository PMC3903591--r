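test_that("Poiseuille relations hold per segment", {
  props <- new("BloodProperties", hct = 0.35, mu = 2, nu = 2 / 1.06,
               density = 1.06, note = "")
  net <- solvePoiseuilleNetwork(
    data.frame(role = "tube", radius_mm = 1, length_mm = 3,
               flow_mm3_s = pi), NULL, props)
  expect_equal(net$tau_mPa, 8)               # 4 mu Q / (pi R^3)
  expect_equal(net$dp_mPa, 8 * 2 * 3)        # 8 mu L Q / (pi R^4)
  expect_equal(net$vmax_mm_s, 2)             # 2 Q / (pi R^2)
  expect_equal(net$gamma_per_s, 4)           # tau / mu
})

test_that("symmetric bifurcations split flow equally and junctions balance mass", {
  model <- velocityAgeModel(defaultVelocityCoeffs())
  tr <- generateVesselTree(makeStageConfig(17.5, seed = 6L), jitterCV = 0)
  props <- bloodPropertiesAtAge(17.5)
  bc <- assembleBoundaries(tr, model, 17.5)
  net <- solvePoiseuilleNetwork(tr, bc, props)
  q <- function(role) net$flow_mm3_s[net$role == role]
  # ductus insertion: arch + ductus = descending aorta
  expect_equal(q("arch") + q("ductus"), q("descending_aorta"),
               tolerance = 1e-9)
  # pulmonary trunk: ductus + both PAs
  expect_equal(q("ductus") + q("left_pulmonary_artery") +
                 q("right_pulmonary_artery"), q("pulmonary_trunk"),
               tolerance = 1e-9)
  # equal radii imply equal Murray flows
  fr <- murrayFractions(c(0.1, 0.1))
  expect_equal(fr[[1]], fr[[2]])
})

test_that("Murray-scaled trees have segment-independent wall shear", {
  # children sized so Q ~ R^3 holds on every segment
  props <- testProps()
  k <- 12                      # flow per unit cubed radius
  radii <- c(0.3, 0.22, 0.26, 0.15, 0.1)
  df <- data.frame(role = paste0("s", seq_along(radii)),
                   radius_mm = radii, length_mm = 1,
                   flow_mm3_s = k * radii^3)
  net <- solvePoiseuilleNetwork(df, NULL, props)
  expect_equal(diff(range(net$tau_mPa)), 0, tolerance = 1e-12)
  expect_equal(net$tau_mPa[1], 4 * props@mu * k / pi, tolerance = 1e-12)
})

test_that("inconsistent flow assignments are rejected", {
  model <- velocityAgeModel(defaultVelocityCoeffs())
  tr <- generateVesselTree(makeStageConfig(16.5, seed = 2L))
  bc <- assembleBoundaries(tr, model, 16.5)
  # corrupt an outlet flow: junction balance at the ductus must fail
  bc2 <- bc
  bc2@outlets$flow_mm3_s[bc2@outlets$role == "left_pulmonary_artery"] <-
    bc2@totalFlow * 2
  props <- bloodPropertiesAtAge(16.5)
  expect_error(solvePoiseuilleNetwork(tr, bc2, props), "inconsistency")
})
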