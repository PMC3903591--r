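test_that("vessel averages reproduce uniform fields and partition additivity", {
  st <- data.frame(role = rep(c("a", "b"), each = 10), s_mm = rep(1:10, 2),
                   radius_mm = 0.2, area_mm2 = 0.1, Vc_mm_s = 5,
                   tau_mPa = 2, gamma_per_s = 1, Re = 1, alpha = 0.5)
  va <- vesselAverages(st, list(A = "a", B = "b"), age_days = 15.5)
  expect_equal(va$tau_mPa, c(2, 2))
  expect_equal(va$Vc_mm_s, c(5, 5))
  # two vessels splitting stations 50/50: station-weighted mean = global
  st$tau_mPa <- c(rep(1, 10), rep(3, 10))
  va2 <- vesselAverages(st, list(A = "a", B = "b"))
  expect_equal(weighted.mean(va2$tau_mPa, va2$n_stations), mean(st$tau_mPa))
  expect_error(vesselAverages(st, list(A = "a", B = c("a", "b"))),
               "overlapping")
})

test_that("Pearson rho and zero-slope p match closed-form computation on small data", {
  x <- c(1, 2, 3, 5, 8, 9, 11, 14)
  y <- c(2.2, 2.8, 3.1, 4.9, 8.3, 8.8, 10.5, 15.1)
  tab <- data.frame(age_days = x, tau_mPa = y)
  ts <- trendStatistics(tab, quantities = "tau_mPa", covariates = "age_days")
  n <- length(x)
  rhoMan <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ts$rho, rhoMan, tolerance = 1e-12)
  tstat <- rhoMan * sqrt((n - 2) / (1 - rhoMan^2))
  expect_equal(ts$slope_p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  # perfectly linear data: rho = 1, p at the numerical floor
  tabP <- data.frame(age_days = 1:6, tau_mPa = 2 * (1:6) + 3)
  tsP <- suppressWarnings(trendStatistics(tabP, "tau_mPa", "age_days"))
  expect_equal(tsP$rho, 1, tolerance = 1e-12)
  expect_lt(tsP$slope_p, 1e-12)
  # constant covariate: undefined, reported as such
  tabC <- data.frame(age_days = rep(2, 5), tau_mPa = rnorm(5))
  tsC <- trendStatistics(tabC, "tau_mPa", "age_days")
  expect_true(is.na(tsC$rho))
  expect_match(tsC$note, "constant")
})

test_that("exact Mann-Whitney p values match enumeration and reference results", {
  # tie-free case: agrees with the exact distribution
  x <- c(1.2, 2.3, 3.1, 4.8); y <- c(0.9, 2.0, 3.5, 4.1)
  expect_equal(mannWhitneyExact(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # brute-force check on all inputs with n <= 8 per a seeded battery
  rng <- fetoflow:::setLocalSeed(31L)
  for (k in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(rnorm(n1), 1); b <- round(rnorm(n2, 0.3), 1)  # ties possible
    res <- mannWhitneyExact(a, b)
    # direct enumeration oracle (independent implementation)
    pool <- c(a, b); rk <- rank(pool)
    idx <- combn(n1 + n2, n1)
    W <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    Wobs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    pOracle <- mean(abs(W - n1 * n2 / 2) >= abs(Wobs - n1 * n2 / 2) - 1e-9)
    expect_equal(res$p.value, pOracle)
  }
  fetoflow:::restoreSeed(rng)
  # identical samples: p = 1 under exact permutation
  expect_equal(twoSampleCheck(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(twoSampleCheck(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("the empirical stage sweep recovers the developmental trend structure", {
  sw <- stageSweep(seed = 2L)
  ts <- sw$stats
  g <- function(q, cv) ts[ts$quantity == q & ts$covariate == cv, ]
  # strong positive size and velocity trends with age
  expect_gt(g("Vc_mm_s", "age_days")$rho, 0.6)
  areaAge <- cor(sw$trend$area_mm2, sw$trend$age_days)
  expect_gt(areaAge, 0.6)
  # wall shear stress against vessel size: weak, slope CI covers zero
  tsA <- g("tau_mPa", "area_mm2")
  expect_lt(abs(tsA$rho), 0.5)
  expect_true(tsA$slope_lo < 0 & tsA$slope_hi > 0)
})

test_that("Murray-consistent growth holds vessel-mean shear nearly constant", {
  sw <- stageSweep(seed = 2L, velocityMode = "shear_preserving",
                   longitudinal = TRUE, noiseCV = 0)
  tt <- sw$trend
  for (v in unique(tt$vessel)) {
    tau <- tt$tau_mPa[tt$vessel == v]
    area <- tt$area_mm2[tt$vessel == v]
    expect_lt((max(tau) - min(tau)) / mean(tau), 0.10)
    expect_gt(max(area) / min(area), 2)
  }
})

test_that("predicted branch velocities match Murray-consistent measurements", {
  mv <- murrayValidationAnalog(seed = 11L)
  expect_true(all(mv$p_value > 0.1))
  expect_equal(nrow(mv), 10L)   # 5 ages x 2 branch vessels
})
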