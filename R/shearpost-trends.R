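# Vessel-grouped averages and the end-to-end developmental stage sweep
# (reduced-order path): per-vessel, per-age mean wall shear stress and
# rate, centerline velocity, lumen area and Reynolds number.

# Vessel grouping used in the staged analyses: ascending aorta + arch are
# pooled as "AAo", the descending aorta stands alone, and the pulmonary
# trunk and ductus arteriosus are analyzed collectively.
defaultVesselDefinitions <- function() {
  list(AAo = c("ascending_aorta", "arch"),
       DAo = "descending_aorta",
       `PT+ductus` = c("pulmonary_trunk", "ductus"))
}

#' Vessel-grouped averages of station hemodynamics
#'
#' Averages per-station wall shear stress/rate, centerline velocity, area
#' and Reynolds number within named vessel groups. Vessel definitions must
#' not overlap.
#'
#' @param stations data.frame from \code{\link{networkStations}} (or of
#'   the same shape).
#' @param vesselDefinitions named list mapping group name to segment
#'   roles; default \code{defaultVesselDefinitions()}.
#' @param age_days age attached to the output rows.
#' @return data.frame: vessel, age_days, tau_mPa, gamma_per_s, Vc_mm_s,
#'   area_mm2, Re, alpha (station means), max_Re, n_stations.
#' @export
vesselAverages <- function(stations,
                           vesselDefinitions = defaultVesselDefinitions(),
                           age_days = NA_real_) {
  roles <- unlist(vesselDefinitions)
  if (anyDuplicated(roles))
    stop("overlapping vessel definitions: ",
         paste(roles[duplicated(roles)], collapse = ", "))
  out <- list()
  for (vn in names(vesselDefinitions)) {
    sel <- stations$role %in% vesselDefinitions[[vn]]
    if (!any(sel)) next
    ss <- stations[sel, ]
    out[[vn]] <- data.frame(
      vessel = vn, age_days = age_days,
      tau_mPa = mean(ss$tau_mPa), gamma_per_s = mean(ss$gamma_per_s),
      Vc_mm_s = mean(ss$Vc_mm_s), area_mm2 = mean(ss$area_mm2),
      Re = mean(ss$Re), alpha = mean(ss$alpha), max_Re = max(ss$Re),
      n_stations = nrow(ss), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Developmental stage sweep (reduced-order pipeline)
#'
#' Runs the full synthetic pipeline across gestational stages: stage
#' configuration, synthetic tree, hematocrit-dependent blood properties,
#' velocity-age model (refit from generated Doppler data, or the
#' shear-preserving growth curve), Murray's-law boundary assembly and the
#' Poiseuille network solution, then vessel-grouped averages.
#'
#' @param ages gestational ages, days.
#' @param seed base RNG seed (tree and Doppler seeds derive from it).
#' @param velocityMode \code{"empirical"} (quadratic velocity-age trend,
#'   refit from seeded noisy Doppler records) or \code{"shear_preserving"}
#'   (Murray-consistent growth: velocity scaled to hold wall shear
#'   constant, with the same measurement noise applied).
#' @param coeffs quadratic coefficients of the generating velocity curve.
#' @param noiseCV Doppler measurement noise CV used in the refit.
#' @param replicates Doppler replicates per age.
#' @param longitudinal if TRUE, the same synthetic subject (same anatomical
#'   jitter) is grown across all ages, isolating the growth law from
#'   between-subject scatter; if FALSE (default) each age is a different
#'   subject, as in a cross-sectional study.
#' @return list with \code{trend} (vessel x age table), \code{stations}
#'   (all stations), \code{stats} (trend statistics), \code{model} (the
#'   velocity-age model used).
#' @export
stageSweep <- function(ages = c(14.5, 15.5, 16.5, 17.5, 18.5), seed = 1L,
                       velocityMode = c("empirical", "shear_preserving"),
                       coeffs = defaultVelocityCoeffs(), noiseCV = 0.1,
                       replicates = 5L, longitudinal = FALSE) {
  velocityMode <- match.arg(velocityMode)
  configs <- lapply(ages, function(a) makeStageConfig(a, seed = seed))
  if (velocityMode == "empirical") {
    dop <- generateDoppler(configs, coeffs = coeffs, noiseCV = noiseCV,
                           replicates = replicates, seed = seed + 7L)
    model <- fitVelocityAge(dop)
  } else {
    vv <- shearPreservingVelocity(ages, coeffs)
    sig <- if (noiseCV > 0) sqrt(log(1 + noiseCV^2)) else 0
    rng0 <- setLocalSeed(seed + 7L)
    df <- do.call(rbind, lapply(seq_along(ages), function(i) {
      noise <- if (sig > 0) rlnorm(replicates, -sig^2 / 2, sig)
               else rep(1, replicates)
      data.frame(age_days = ages[i], velocity_mm_s = vv[i] * noise)
    }))
    restoreSeed(rng0)
    model <- fitVelocityAge(df)
  }
  trend <- list(); stations <- list()
  for (i in seq_along(ages)) {
    cf <- configs[[i]]
    cf@seed <- if (longitudinal) as.integer(seed)
               else as.integer(seed + i)   # per-stage subject
    tree <- generateVesselTree(cf)
    props <- bloodPropertiesAtAge(cf@ageDays, cf)
    bc <- assembleBoundaries(tree, model, cf@ageDays)
    st <- networkStations(tree, bc, props, cf)
    stations[[i]] <- cbind(st, age_days = cf@ageDays)
    trend[[i]] <- vesselAverages(st, age_days = cf@ageDays)
  }
  trendTab <- do.call(rbind, c(trend, list(make.row.names = FALSE)))
  list(trend = trendTab,
       stations = do.call(rbind, c(stations, list(make.row.names = FALSE))),
       stats = trendStatistics(trendTab), model = model)
}

#' Murray's-law validation analog
#'
#' Emulates the ultrasound validation of Murray's-law boundary conditions:
#' for each age and subject, branch-outlet peak velocities predicted from
#' the subject's own descending-aorta flow plus Murray's law are compared
#' with that subject's "measured" branch velocities (the Murray-consistent
#' truth with multiplicative lognormal measurement noise), using the
#' exact-permutation Mann-Whitney test per (age, vessel).
#'
#' @param ages gestational ages, days.
#' @param seed base RNG seed.
#' @param nSubjects subjects (litters) per age.
#' @param noiseCV Doppler measurement repeatability CV on the measured
#'   velocities (smaller than the between-subject anatomical spread).
#' @param jitterCV between-subject anatomical (radius) variation of the
#'   generated trees.
#' @param vessels branch vessels compared.
#' @return data.frame: age_days, vessel, p_value, n per group.
#' @export
murrayValidationAnalog <- function(ages = c(14.5, 15.5, 16.5, 17.5, 18.5),
                                   seed = 1L, nSubjects = 5L,
                                   noiseCV = 0.04, jitterCV = 0.08,
                                   vessels = c("innominate",
                                               "left_common_carotid")) {
  model <- velocityAgeModel(defaultVelocityCoeffs())
  rng0 <- setLocalSeed(seed + 99L)
  on.exit(restoreSeed(rng0), add = TRUE)
  sig <- sqrt(log(1 + noiseCV^2))
  out <- list()
  for (age in ages) {
    pred <- matrix(NA_real_, nSubjects, length(vessels),
                   dimnames = list(NULL, vessels))
    meas <- pred
    for (sbj in seq_len(nSubjects)) {
      cf <- makeStageConfig(age, seed = seed + 1000L * sbj)
      tree <- generateVesselTree(cf, jitterCV = jitterCV)
      bc <- assembleBoundaries(tree, model, age)
      for (vn in vessels) {
        vhat <- bc@outlets$peak_velocity_mm_s[bc@outlets$role == vn]
        pred[sbj, vn] <- vhat
        meas[sbj, vn] <- vhat * rlnorm(1, -sig^2 / 2, sig)
      }
    }
    for (vn in vessels) {
      tst <- twoSampleCheck(pred[, vn], meas[, vn])
      out[[length(out) + 1L]] <- data.frame(
        age_days = age, vessel = vn, p_value = tst$p.value,
        n = nSubjects, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
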