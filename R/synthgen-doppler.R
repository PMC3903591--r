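# Doppler-like peak-velocity dataset generator. Velocities follow a
# quadratic velocity-age curve for the descending aorta, with aortic-root
# and pulmonary-root velocities equal in expectation, and multiplicative
# lognormal measurement noise of configurable coefficient of variation.

# Default quadratic velocity-age coefficients (c0, c1, c2) of
# V(t) = c0 + c1 t + c2 t^2 in mm/s: V(14.5) = 60, V(16.5) = 95,
# V(18.5) = 140 mm/s, an increasing convex trend with magnitudes typical of
# high-frequency-ultrasound peak velocities in the fetal mouse descending
# aorta over E14.5-E18.5.
defaultVelocityCoeffs <- function() c(105.3125, -21.25, 1.25)

#' Generate a Doppler-like velocity dataset
#'
#' For each stage configuration and vessel, draws \code{replicates}
#' peak-velocity records around the noiseless velocity-age curve with
#' multiplicative lognormal noise of coefficient of variation
#' \code{noiseCV} (noise factor has mean exactly 1, so records are unbiased
#' around the curve). Aortic-root and pulmonary-root records share the same
#' expectation (\code{rootRatio} times the descending-aorta curve).
#'
#' @param configs list of \linkS4class{StageConfig} (or a single one).
#' @param coeffs quadratic coefficients (c0, c1, c2) of the
#'   descending-aorta peak-velocity curve, mm/s; default
#'   \code{defaultVelocityCoeffs()}.
#' @param noiseCV coefficient of variation of the multiplicative noise.
#' @param replicates records per (vessel, age), >= 1.
#' @param seed RNG seed.
#' @param rootRatio ratio of root plug velocity to descending-aorta peak.
#' @return a \linkS4class{DopplerSet}.
#' @export
generateDoppler <- function(configs, coeffs = defaultVelocityCoeffs(),
                            noiseCV = 0.1, replicates = 5L, seed = 1L,
                            rootRatio = 0.65) {
  if (is(configs, "StageConfig")) configs <- list(configs)
  if (replicates < 1) stop("replicates must be >= 1")
  ages <- vapply(configs, function(cf) cf@ageDays, numeric(1))
  tt <- seq(min(ages), max(ages), length.out = 65)
  vv <- coeffs[1] + coeffs[2] * tt + coeffs[3] * tt^2
  if (any(vv <= 0))
    stop("velocity curve takes non-positive values inside the age window")
  rng0 <- setLocalSeed(seed)
  on.exit(restoreSeed(rng0), add = TRUE)
  sig <- if (noiseCV > 0) sqrt(log(1 + noiseCV^2)) else 0
  vessels <- c(descending_aorta = 1, aortic_root = rootRatio,
               pulmonary_root = rootRatio)
  rec <- list(); tru <- list()
  for (cf in configs) {
    t <- cf@ageDays
    vdao <- coeffs[1] + coeffs[2] * t + coeffs[3] * t^2
    for (vn in names(vessels)) {
      mu <- vdao * vessels[[vn]]
      noise <- if (sig > 0) rlnorm(replicates, -sig^2 / 2, sig)
               else rep(1, replicates)
      rec[[length(rec) + 1L]] <- data.frame(
        vessel = vn, age_days = t, replicate = seq_len(replicates),
        velocity_mm_s = mu * noise, stringsAsFactors = FALSE)
      tru[[length(tru) + 1L]] <- data.frame(
        vessel = vn, age_days = t, velocity_mm_s = mu,
        stringsAsFactors = FALSE)
    }
  }
  new("DopplerSet", records = do.call(rbind, rec),
      trueCoeffs = as.numeric(coeffs), trueValues = do.call(rbind, tru),
      noiseCV = noiseCV, seed = as.integer(seed))
}

#' Shear-preserving descending-aorta velocity at an age
#'
#' Velocity scaling under Murray-consistent (shear-homeostatic) growth: wall
#' shear stress tau = 2 mu V / R stays constant across ages when
#' \eqn{V(t) = V_{ref} (R(t)/R_{ref}) (\nu_{ref}/\nu(t))}. Anchored at the
#' E18.5 value of the empirical quadratic curve.
#'
#' @param t age(s), days in [14.5, 18.5].
#' @param coeffs empirical quadratic coefficients supplying the E18.5
#'   anchor velocity.
#' @return descending-aorta peak velocity, mm/s.
#' @export
shearPreservingVelocity <- function(t, coeffs = defaultVelocityCoeffs()) {
  vref <- coeffs[1] + coeffs[2] * 18.5 + coeffs[3] * 18.5^2
  nuref <- viscosityFromHct(hctAtAge(18.5))@nu
  vapply(t, function(ti) {
    vref * (stageScale(ti) / stageScale(18.5)) *
      (nuref / viscosityFromHct(hctAtAge(ti))@nu)
  }, numeric(1))
}
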