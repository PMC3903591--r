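# Blood-property and boundary-condition engine: hematocrit schedule,
# hematocrit-dependent viscosity, quadratic velocity-age model, Murray's-law
# flow splitting, and inlet/outlet boundary assembly.

#' Hematocrit at a gestational age
#'
#' Linear hematocrit schedule between the configured anchors: 20\% at E10.5
#' rising to 43.8\% at term.
#'
#' @param t gestational age, days; must lie in [10.5, termDay].
#' @param config a \linkS4class{StageConfig} supplying the anchors; if
#'   omitted, the default anchors (0.20 at E10.5, 0.438 at term 19.5) are used.
#' @return hematocrit fraction.
#' @examples
#' hctAtAge(10.5)   # 0.20
#' hctAtAge(19.5)   # 0.438
#' @export
hctAtAge <- function(t, config = NULL) {
  early <- if (is.null(config)) 0.20 else config@hctAnchorEarly
  term <- if (is.null(config)) 0.438 else config@hctAnchorTerm
  termDay <- if (is.null(config)) 19.5 else config@termDay
  if (any(t < 10.5 - 1e-9) || any(t > termDay + 1e-9))
    stop("age t out of hematocrit schedule range [10.5, ", termDay, "]")
  early + (term - early) * (t - 10.5) / (termDay - 10.5)
}

# Constants of the hematocrit-viscosity law nu = A * exp(B * Hct) [cSt],
# fixed in closed form so that the kinematic viscosities at the hematocrits
# of E11.5 and E18.5 (linear schedule, term 19.5) equal the reference values
# 1.87 and 2.53 cSt for fetal blood. The exponential form is the standard
# low-shear dependence of whole-blood viscosity on hematocrit.
.viscCal <- local({
  h1 <- 0.20 + (0.438 - 0.20) * (11.5 - 10.5) / 9   # Hct at E11.5
  h2 <- 0.20 + (0.438 - 0.20) * (18.5 - 10.5) / 9   # Hct at E18.5
  B <- log(2.53 / 1.87) / (h2 - h1)
  A <- 1.87 / exp(B * h1)
  list(A = A, B = B, range = c(0.15, 0.55))
})

#' Blood viscosity from hematocrit
#'
#' Evaluates the package's hematocrit-viscosity law
#' \eqn{\nu(Hct) = A e^{B\,Hct}} (cSt), calibrated so that the E11.5 and
#' E18.5 hematocrits of the linear schedule map to 1.87 and 2.53 cSt.
#' Dynamic viscosity is \eqn{\mu = \rho \nu} with blood density
#' \code{density} g/cm^3 (mPa.s when \eqn{\nu} is in cSt).
#'
#' @param hct hematocrit fraction in (0, 1).
#' @param density blood density, g/cm^3 (default 1.06).
#' @return a \linkS4class{BloodProperties}. If \code{hct} lies outside the
#'   calibrated validity range a warning is recorded in the \code{note} slot
#'   (the value is still returned).
#' @examples
#' viscosityFromHct(hctAtAge(11.5))  # nu = 1.87 cSt
#' viscosityFromHct(hctAtAge(18.5))  # nu = 2.53 cSt
#' @export
viscosityFromHct <- function(hct, density = 1.06) {
  if (!is.numeric(hct) || length(hct) != 1 || !is.finite(hct))
    stop("hct must be a single finite number")
  if (hct <= 0 || hct >= 1) stop("hct must be in (0, 1)")
  note <- ""
  if (hct < .viscCal$range[1] || hct > .viscCal$range[2])
    note <- sprintf("hct %.3f outside calibrated validity range [%.2f, %.2f]",
                    hct, .viscCal$range[1], .viscCal$range[2])
  nu <- .viscCal$A * exp(.viscCal$B * hct)
  new("BloodProperties", hct = hct, mu = nu * density, nu = nu,
      density = density, note = note)
}

#' Blood properties at a gestational age
#'
#' Convenience composition of \code{\link{hctAtAge}} and
#' \code{\link{viscosityFromHct}}.
#'
#' @inheritParams hctAtAge
#' @param density blood density, g/cm^3.
#' @return a \linkS4class{BloodProperties}.
#' @export
bloodPropertiesAtAge <- function(t, config = NULL, density = 1.06)
  viscosityFromHct(hctAtAge(t, config), density = density)

#' Fit the quadratic velocity-age model
#'
#' Ordinary least-squares second-order polynomial fit of descending-aorta
#' peak velocity against gestational age, the velocity-age trend used to set
#' flow boundary conditions.
#'
#' @param doppler a \linkS4class{DopplerSet}, or a data.frame with columns
#'   \code{age_days} and \code{velocity_mm_s} (descending-aorta records).
#' @param vessel which vessel's records to fit (default
#'   \code{"descending_aorta"}).
#' @return a \linkS4class{VelocityAgeModel} with residuals.
#' @export
fitVelocityAge <- function(doppler, vessel = "descending_aorta") {
  df <- if (is(doppler, "DopplerSet")) {
    r <- doppler@records
    r[r$vessel == vessel, c("age_days", "velocity_mm_s")]
  } else as.data.frame(doppler)[, c("age_days", "velocity_mm_s")]
  if (length(unique(df$age_days)) < 3)
    stop("need >= 3 distinct ages for a quadratic fit (rank-deficient design)")
  fit <- lm(velocity_mm_s ~ age_days + I(age_days^2), data = df)
  cf <- unname(coef(fit))
  new("VelocityAgeModel",
      coeffs = cf,
      tRange = range(df$age_days),
      residuals = unname(residuals(fit)),
      fitInfo = list(n = nrow(df), sigma = summary(fit)$sigma))
}

#' Construct a velocity-age model from known coefficients
#'
#' @param coeffs numeric(3), (c0, c1, c2) of V(t) = c0 + c1 t + c2 t^2, mm/s.
#' @param tRange validity window in days.
#' @return a \linkS4class{VelocityAgeModel}.
#' @export
velocityAgeModel <- function(coeffs, tRange = c(14.5, 18.5)) {
  new("VelocityAgeModel", coeffs = as.numeric(coeffs), tRange = tRange,
      residuals = numeric(0), fitInfo = list(source = "assigned"))
}

#' Evaluate a velocity-age model
#'
#' @param model a \linkS4class{VelocityAgeModel}.
#' @param t age(s), days.
#' @return peak descending-aorta velocity, mm/s.
#' @export
evalVelocity <- function(model, t) {
  cf <- model@coeffs
  cf[1] + cf[2] * t + cf[3] * t^2
}

#' Murray's-law outlet flow fractions
#'
#' Splits total volumetric flow across outlets in proportion to the cube of
#' the outlet radius: \eqn{f_i = r_i^3 / \sum_j r_j^3}.
#'
#' @param radii outlet radii (any consistent unit), all > 0.
#' @return named numeric vector of fractions summing to 1.
#' @examples
#' murrayFractions(c(2, 1))   # 8/9, 1/9
#' @export
murrayFractions <- function(radii) {
  if (length(radii) == 0) stop("empty outlet list")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("all outlet radii must be finite and > 0")
  f <- radii^3 / sum(radii^3)
  names(f) <- names(radii)
  f
}

# Terminal outlet roles of the great-artery tree, and the two root inlets.
.outletRoles <- c("descending_aorta", "innominate", "left_common_carotid",
                  "left_subclavian", "left_pulmonary_artery",
                  "right_pulmonary_artery")
.inletRoles <- c("ascending_aorta", "pulmonary_trunk")

# Terminal radius of a tree segment by role (radius at the far end).
segmentEndRadius <- function(tree, role) {
  s <- tree@segments[[role]]
  if (is.null(s)) stop("tree has no segment with role '", role, "'")
  tail(s$radius, 1)
}

segmentStartRadius <- function(tree, role) {
  s <- tree@segments[[role]]
  if (is.null(s)) stop("tree has no segment with role '", role, "'")
  s$radius[1]
}

#' Assemble flow boundary conditions for a tree
#'
#' Computes the descending-aorta volumetric flow from the velocity-age model
#' assuming a parabolic profile (mean velocity = half the measured peak),
#' distributes total flow over all outlets by Murray's law, back-computes
#' parabolic peak velocities per outlet, and sets equal plug velocities at
#' the aortic and pulmonary roots such that total inflow equals total
#' outflow.
#'
#' @param tree a \linkS4class{VesselTree} with a descending-aorta outlet and
#'   at least one other outlet.
#' @param model a \linkS4class{VelocityAgeModel}.
#' @param age gestational age, days, at which to evaluate the model.
#' @return a \linkS4class{FlowBoundarySet}.
#' @export
assembleBoundaries <- function(tree, model, age) {
  roles <- intersect(.outletRoles, names(tree@segments))
  if (!"descending_aorta" %in% roles)
    stop("tree must have a descending-aorta outlet")
  if (length(roles) < 2) stop("tree must have at least one non-DAo outlet")
  rOut <- vapply(roles, function(r) segmentEndRadius(tree, r), numeric(1))
  if (any(rOut <= 0)) stop("outlet with zero radius")
  fr <- murrayFractions(rOut)
  Vdao <- evalVelocity(model, age)
  if (Vdao <= 0) stop("model velocity must be positive at age ", age)
  Rdao <- rOut[["descending_aorta"]]
  Qdao <- Vdao * pi * Rdao^2 / 2          # parabolic: mean = peak/2
  Qtot <- Qdao / fr[["descending_aorta"]]
  Qout <- Qtot * fr
  peakOut <- 2 * Qout / (pi * rOut^2)
  inRoles <- intersect(.inletRoles, names(tree@segments))
  rIn <- vapply(inRoles, function(r) segmentStartRadius(tree, r), numeric(1))
  vPlug <- Qtot / sum(pi * rIn^2)          # equal plug velocity at both roots
  inlets <- data.frame(role = inRoles, radius_mm = unname(rIn),
                       velocity_mm_s = vPlug,
                       flow_mm3_s = unname(vPlug * pi * rIn^2),
                       stringsAsFactors = FALSE)
  outlets <- data.frame(role = roles, radius_mm = unname(rOut),
                        fraction = unname(fr), flow_mm3_s = unname(Qout),
                        peak_velocity_mm_s = unname(peakOut),
                        stringsAsFactors = FALSE)
  new("FlowBoundarySet", inlets = inlets, outlets = outlets, totalFlow = Qtot)
}
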