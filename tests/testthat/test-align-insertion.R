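test_that("landmark alignment pins to cross-subject means and preserves constants", {
  p1 <- list(x = seq(0, 1, length.out = 50), values = rep(3, 50),
             landmarks = c(a = 0.2, b = 0.5))
  p2 <- list(x = seq(0, 2, length.out = 60), values = rep(3, 60),
             landmarks = c(a = 0.6, b = 1.2))
  al <- alignProfiles(list(p1, p2), c("a", "b"))
  expect_equal(unname(al$landmarks), c(0.25, 0.55))
  expect_equal(unname(al$mean), rep(3, length(al$x)))
  expect_equal(max(al$sd), 0)
  # single subject: identity-shaped rescaling
  al1 <- alignProfiles(list(p1), c("a", "b"))
  expect_equal(unname(al1$landmarks), c(0.2, 0.5))
  expect_equal(unname(al1$mean), rep(3, length(al1$x)))
})

test_that("missing or out-of-order landmarks are rejected", {
  p1 <- list(x = 0:10 / 10, values = rep(1, 11), landmarks = c(a = 0.2))
  expect_error(alignProfiles(list(p1), c("a", "b")), "missing landmark")
  p2 <- list(x = 0:10 / 10, values = rep(1, 11),
             landmarks = c(a = 0.7, b = 0.3))
  expect_error(alignProfiles(list(p2), c("a", "b")), "out of order")
})

test_that("alignment warps a varying profile onto the pinned coordinate", {
  # a bump at the landmark stays at the pinned landmark after warping
  mkP <- function(lm) {
    x <- seq(0, 1, length.out = 200)
    list(x = x, values = exp(-((x - lm) / 0.05)^2), landmarks = c(a = lm))
  }
  al <- alignProfiles(list(mkP(0.3), mkP(0.5)), "a")
  expect_equal(unname(al$landmarks), 0.4)
  for (s in 1:2)
    expect_lt(abs(al$x[which.max(al$aligned[s, ])] - 0.4), 0.02)
})

test_that("insertion angles reproduce constructed junction geometry", {
  z <- seq(1, 0, length.out = 60)
  parent <- pointsCenterline(cbind(0, 0, z))          # flows downward
  jn <- c(0, 0, 0.5)
  perp <- pointsCenterline(cbind(seq(-0.5, 0, length.out = 40), 0, 0.5))
  expect_equal(insertionAngle(parent, perp, jn), 90, tolerance = 2)
  coll <- pointsCenterline(cbind(0, 0, seq(1, 0.5, length.out = 40)))
  expect_equal(insertionAngle(parent, coll, jn), 180, tolerance = 2)
  oblique <- pointsCenterline(cbind(seq(-0.4, 0, length.out = 40), 0,
                                    seq(0.9, 0.5, length.out = 40)))
  expect_equal(insertionAngle(parent, oblique, jn), 135, tolerance = 2)
  expect_error(insertionAngle(parent, perp, c(3, 3, 3)), "mismatch")
})

test_that("the generator's ductus angle trend is recovered from ground-truth centerlines", {
  ages <- c(14.5, 15.5, 16.5, 17.5, 18.5)
  rec <- vapply(ages, function(a) {
    tr <- generateVesselTree(makeStageConfig(a, seed = 5L), jitterCV = 0)
    jn <- as.numeric(tr@landmarks[tr@landmarks$name == "ductus_insertion",
                                  c("x", "y", "z")])
    insertionAngle(segmentCenterline(tr, "descending_aorta"),
                   segmentCenterline(tr, "ductus"), jn, tol = 0.2)
  }, numeric(1))
  nominal <- 100 + 50 * (ages - 14.5) / 4
  expect_true(all(abs(rec - nominal) < 5))
  expect_true(all(diff(rec) > 0))
})
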