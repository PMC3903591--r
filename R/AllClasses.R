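#' @import methods
#' @importFrom stats lm coef cor cor.test pt qt rnorm rlnorm runif sd var
#'   quantile pnorm approx predict wilcox.test residuals
#' @importFrom utils combn head tail
#' @importFrom grDevices chull
NULL

#' Gestational-stage physiology configuration
#'
#' Holds the gestational-age-indexed physiological quantities that drive both
#' synthetic data generation and flow simulation: heart rate (and the derived
#' angular frequency used by the Womersley number), ejection-duration ratio,
#' the linear hematocrit schedule anchors, and the descending-aorta reference
#' diameter used to anchor all synthetic dimensions.
#'
#' @slot ageDays gestational age in days (mouse, E14.5--E18.5 for the staged
#'   analyses).
#' @slot heartRate heart rate, beats/min.
#' @slot omega angular frequency of the heart rate, rad/s
#'   (\code{2*pi*heartRate/60}).
#' @slot ejectionRatio systolic (ejection) fraction of the cardiac cycle.
#' @slot hctAnchorEarly hematocrit fraction at E10.5.
#' @slot hctAnchorTerm hematocrit fraction at term.
#' @slot termDay gestational day taken as "term".
#' @slot daoDiameter descending-aorta reference diameter at this age, mm.
#' @slot seed integer RNG seed attached to this configuration.
#' @exportClass StageConfig
setClass("StageConfig",
  representation(
    ageDays = "numeric", heartRate = "numeric", omega = "numeric",
    ejectionRatio = "numeric", hctAnchorEarly = "numeric",
    hctAnchorTerm = "numeric", termDay = "numeric",
    daoDiameter = "numeric", seed = "integer"
  )
)

setValidity("StageConfig", function(object) {
  msg <- character()
  if (object@ageDays < 10.5 || object@ageDays > object@termDay)
    msg <- c(msg, "ageDays must lie in [10.5, termDay]")
  if (object@ejectionRatio <= 0 || object@ejectionRatio >= 1)
    msg <- c(msg, "ejectionRatio must be in (0, 1)")
  if (abs(object@omega - 2 * pi * object@heartRate / 60) > 1e-9)
    msg <- c(msg, "omega must equal 2*pi*heartRate/60")
  if (object@hctAnchorEarly <= 0 || object@hctAnchorEarly >= 1 ||
      object@hctAnchorTerm <= 0 || object@hctAnchorTerm >= 1)
    msg <- c(msg, "hematocrit anchors must be in (0, 1)")
  if (object@daoDiameter <= 0) msg <- c(msg, "daoDiameter must be positive")
  if (length(msg)) msg else TRUE
})

#' Parametric great-artery tree
#'
#' A ground-truth tube tree: each segment is a swept-ellipse tube along a
#' sampled space curve with a radius profile, a cross-section ellipticity
#' profile (minor/major diameter ratio, 1 = circular), and an anatomical role
#' label. Junctions carry insertion angles; landmarks name branch-ostium
#' arclength positions used downstream for profile alignment and map holes.
#'
#' @slot segments named list; each element has \code{role}, \code{points}
#'   (n x 3 matrix, mm), \code{radius} (n, mm; nominal circular-equivalent
#'   radius, so cross-section area is pi*radius^2 at any ellipticity),
#'   \code{ellipticity} (n, in (0,1]), \code{elongAxis} (n x 3, in-plane
#'   elongation direction, rows may be zero for circular sections).
#' @slot junctions data.frame with columns parent, child, x, y, z, angleDeg.
#' @slot landmarks data.frame with columns name, segment, arclength, x, y, z.
#' @slot ageDays gestational age the tree represents.
#' @slot seed generating seed.
#' @exportClass VesselTree
setClass("VesselTree",
  representation(
    segments = "list", junctions = "data.frame", landmarks = "data.frame",
    ageDays = "numeric", seed = "integer"
  )
)

setValidity("VesselTree", function(object) {
  msg <- character()
  for (s in object@segments) {
    if (any(!is.finite(s$radius)) || any(s$radius <= 0))
      msg <- c(msg, sprintf("segment '%s': radii must be strictly positive", s$role))
    if (any(s$ellipticity <= 0) || any(s$ellipticity > 1))
      msg <- c(msg, sprintf("segment '%s': ellipticity must be in (0, 1]", s$role))
    if (nrow(s$points) != length(s$radius))
      msg <- c(msg, sprintf("segment '%s': points/radius length mismatch", s$role))
  }
  if (nrow(object@junctions) &&
      any(object@junctions$angleDeg <= 0 | object@junctions$angleDeg > 180))
    msg <- c(msg, "junction insertion angles must be in (0, 180]")
  if (length(msg)) msg else TRUE
})

#' Episcopic-like 3D image stack
#'
#' A serial-section-style grayscale voxel stack with per-axis spacing and, for
#' synthetic stacks, the exact generating lumen mask retained as ground truth.
#' Axis order is fixed (slice, row, column); physical position of voxel
#' (i,j,k) (0-based) is index * spacing.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size per axis, micrometres.
#' @slot mask 3D logical array of the generating lumen (ground truth), or a
#'   0-length logical when unknown.
#' @slot provenance list recording generator id and noise parameters.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(voxels = "array", spacing = "numeric",
                 mask = "logical", provenance = "list")
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3) msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (any(!is.finite(object@voxels))) msg <- c(msg, "intensities must be finite")
  if (length(object@mask) && !identical(dim(array(object@mask, dim(object@voxels))),
                                        dim(object@voxels)) &&
      length(object@mask) != length(object@voxels))
    msg <- c(msg, "mask must match voxel grid")
  if (length(msg)) msg else TRUE
})

#' Doppler-like velocity measurement set
#'
#' Replicated peak-velocity records per (vessel role, gestational age), drawn
#' around a noiseless ground-truth velocity-age curve that is retained for
#' recovery tests.
#'
#' @slot records data.frame with columns vessel, age_days, replicate,
#'   velocity_mm_s.
#' @slot trueCoeffs numeric(3) quadratic coefficients (c0, c1, c2) of the
#'   generating descending-aorta curve V(t) = c0 + c1 t + c2 t^2, mm/s.
#' @slot trueValues data.frame of noiseless curve evaluations per record key.
#' @slot noiseCV coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @slot seed generating seed.
#' @exportClass DopplerSet
setClass("DopplerSet",
  representation(records = "data.frame", trueCoeffs = "numeric",
                 trueValues = "data.frame", noiseCV = "numeric",
                 seed = "integer")
)

setValidity("DopplerSet", function(object) {
  msg <- character()
  if (any(object@records$velocity_mm_s <= 0))
    msg <- c(msg, "velocities must be positive")
  if (length(object@trueCoeffs) != 3)
    msg <- c(msg, "trueCoeffs must have length 3")
  if (length(msg)) msg else TRUE
})

#' Binary lumen segmentation aligned to an image stack
#'
#' @slot voxels 3D logical array (TRUE = lumen).
#' @slot spacing numeric(3), inherited voxel size, micrometres.
#' @slot labels 3D integer array of 6-connected lumen component labels
#'   (0 = background).
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(voxels = "array", spacing = "numeric", labels = "array")
)

setValidity("SegmentationMask", function(object) {
  msg <- character()
  if (!is.logical(object@voxels)) msg <- c(msg, "voxels must be logical")
  if (length(dim(object@voxels)) != 3) msg <- c(msg, "voxels must be 3D")
  if (!identical(dim(object@voxels), dim(object@labels)))
    msg <- c(msg, "labels must match voxel grid")
  if (length(msg)) msg else TRUE
})

#' Triangulated lumen surface
#'
#' @slot vertices n x 3 matrix, mm.
#' @slot faces m x 3 integer matrix of vertex indices, consistently oriented.
#' @slot openBoundaries list of integer vertex loops at clipped vessel ends.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", openBoundaries = "list")
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3) msg <- c(msg, "vertices must be n x 3")
  if (nrow(object@faces) && (min(object@faces) < 1 ||
      max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "faces index invalid vertices")
  if (length(msg)) msg else TRUE
})

#' Ordered vessel centerline
#'
#' @slot points ordered n x 3 samples, mm.
#' @slot tangents unit tangent per point.
#' @slot arclength cumulative arclength, mm, strictly increasing.
#' @slot radius per-point lumen radius: the average of the maximum and
#'   minimum cross-sectional radius (equivalently the maximal-inscribed-sphere
#'   radius for near-elliptic sections), mm.
#' @slot branchIds integer branch/topology id per point.
#' @exportClass Centerline
setClass("Centerline",
  representation(points = "matrix", tangents = "matrix",
                 arclength = "numeric", radius = "numeric",
                 branchIds = "integer")
)

setValidity("Centerline", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (length(object@arclength) != n) msg <- c(msg, "arclength length mismatch")
  if (n > 1 && any(diff(object@arclength) <= 0))
    msg <- c(msg, "arclength must be strictly increasing")
  if (length(object@radius) && any(object@radius <= 0))
    msg <- c(msg, "radius must be positive")
  nt <- sqrt(rowSums(object@tangents^2))
  if (length(nt) && any(abs(nt - 1) > 1e-6))
    msg <- c(msg, "tangents must be unit-norm")
  if (length(msg)) msg else TRUE
})

#' Blood rheological properties
#'
#' Dynamic and kinematic viscosity at a given hematocrit, with the density
#' used to convert between them.
#'
#' @slot hct hematocrit fraction.
#' @slot mu dynamic viscosity, mPa.s.
#' @slot nu kinematic viscosity, cSt (mm^2/s).
#' @slot density g/cm^3.
#' @slot note character; records a validity warning when the hematocrit lies
#'   outside the relation's calibrated range.
#' @exportClass BloodProperties
setClass("BloodProperties",
  representation(hct = "numeric", mu = "numeric", nu = "numeric",
                 density = "numeric", note = "character")
)

setValidity("BloodProperties", function(object) {
  msg <- character()
  if (object@mu <= 0 || object@nu <= 0) msg <- c(msg, "viscosities must be positive")
  if (object@hct <= 0 || object@hct >= 1) msg <- c(msg, "hct must be in (0, 1)")
  if (abs(object@nu - object@mu / object@density) / object@nu > 1e-6)
    msg <- c(msg, "nu must equal mu/density to 6 significant figures")
  if (length(msg)) msg else TRUE
})

#' Quadratic velocity-age model
#'
#' Second-order polynomial model of peak descending-aorta velocity against
#' gestational age, V(t) = c0 + c1 t + c2 t^2 (mm/s, t in days).
#'
#' @slot coeffs numeric(3): (c0, c1, c2).
#' @slot tRange valid gestational window, days.
#' @slot residuals fit residuals, mm/s (0-length for exact/assigned models).
#' @slot fitInfo list with fit diagnostics.
#' @exportClass VelocityAgeModel
setClass("VelocityAgeModel",
  representation(coeffs = "numeric", tRange = "numeric",
                 residuals = "numeric", fitInfo = "list")
)

setValidity("VelocityAgeModel", function(object) {
  msg <- character()
  if (length(object@coeffs) != 3) msg <- c(msg, "coeffs must have length 3")
  tt <- seq(object@tRange[1], object@tRange[2], length.out = 33)
  v <- object@coeffs[1] + object@coeffs[2] * tt + object@coeffs[3] * tt^2
  if (any(v <= 0)) msg <- c(msg, "V(t) must be positive on tRange")
  if (length(msg)) msg else TRUE
})

#' Flow boundary-condition set
#'
#' Plug inlet velocities at the aortic and pulmonary roots plus Murray's-law
#' outlet flow fractions with parabolic outlet profiles.
#'
#' @slot inlets data.frame: role, radius_mm, velocity_mm_s (plug),
#'   flow_mm3_s.
#' @slot outlets data.frame: role, radius_mm, fraction, flow_mm3_s,
#'   peak_velocity_mm_s (parabolic peak = 2 x mean).
#' @slot totalFlow total volumetric flow, mm^3/s.
#' @exportClass FlowBoundarySet
setClass("FlowBoundarySet",
  representation(inlets = "data.frame", outlets = "data.frame",
                 totalFlow = "numeric")
)

setValidity("FlowBoundarySet", function(object) {
  msg <- character()
  if (abs(sum(object@outlets$fraction) - 1) > 1e-9)
    msg <- c(msg, "outlet fractions must sum to 1 within 1e-9")
  if (any(object@outlets$fraction <= 0))
    msg <- c(msg, "every outlet fraction must be > 0")
  if (nrow(object@inlets) > 1 &&
      diff(range(object@inlets$velocity_mm_s)) > 1e-9 * max(object@inlets$velocity_mm_s))
    msg <- c(msg, "root plug velocities must be equal")
  if (length(msg)) msg else TRUE
})

#' Structured tube-fitted flow mesh
#'
#' Desk-scale structured mesh over a straight or constant-curvature tube
#' segment (axial stations x radial shells x azimuthal sectors), with named
#' boundary patches and per-patch extension lengths in local diameters.
#'
#' @slot type "straight_tube" or "curved_tube".
#' @slot dims named integer vector (ns, nr, ntheta) of cell counts.
#' @slot geom list of geometric parameters (radius mm, length mm, bend radius
#'   mm, bend angle rad, as applicable).
#' @slot nodes N x 3 node coordinate matrix, mm.
#' @slot patches character vector of boundary patch names.
#' @slot extensions named numeric, per-patch extension length in diameters.
#' @slot level refinement level (0 = coarse, 1 = fine).
#' @exportClass FlowMesh
setClass("FlowMesh",
  representation(type = "character", dims = "integer", geom = "list",
                 nodes = "matrix", patches = "character",
                 extensions = "numeric", level = "numeric")
)

setValidity("FlowMesh", function(object) {
  msg <- character()
  if (!object@type %in% c("straight_tube", "curved_tube", "tube_network"))
    msg <- c(msg, "type must be straight_tube, curved_tube or tube_network")
  if (any(object@dims < 2)) msg <- c(msg, "all dims must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Volumetric steady flow solution
#'
#' Velocity, pressure (up to a constant) and vorticity per node of a
#' \linkS4class{FlowMesh}, with the divergence residual and solver history.
#' The \code{structured} slot retains the solver's native structured arrays
#' (used by wall-shear post-processing for one-sided wall gradients).
#'
#' @slot mesh the FlowMesh solved on.
#' @slot velocity N x 3 matrix, mm/s.
#' @slot pressure numeric N, Pa (defined up to a constant).
#' @slot vorticity N x 3 matrix, 1/s.
#' @slot divergenceNorm maximum cellwise divergence residual (relative).
#' @slot residuals solver residual history.
#' @slot structured list of solver-native structured arrays.
#' @exportClass FlowField
setClass("FlowField",
  representation(mesh = "FlowMesh", velocity = "matrix", pressure = "numeric",
                 vorticity = "matrix", divergenceNorm = "numeric",
                 residuals = "numeric", structured = "list")
)

#' Wall shear field
#'
#' Wall-sample shear rate (normal gradient of tangential velocity at the
#' wall) and shear stress (mu times shear rate), with the (arclength,
#' azimuth) parameterization used for unwrapped maps.
#'
#' @slot positions n x 3 wall sample positions, mm.
#' @slot s arclength from the tube root per sample, mm.
#' @slot theta azimuth per sample, degrees in [0, 360).
#' @slot gamma wall shear rate, 1/s (magnitude).
#' @slot tau wall shear stress, mPa (mu * gamma).
#' @slot mu dynamic viscosity used, mPa.s.
#' @exportClass WallShearField
setClass("WallShearField",
  representation(positions = "matrix", s = "numeric", theta = "numeric",
                 gamma = "numeric", tau = "numeric", mu = "numeric")
)

setValidity("WallShearField", function(object) {
  msg <- character()
  if (any(object@gamma < 0) || any(object@tau < 0))
    msg <- c(msg, "shear magnitudes must be non-negative")
  rel <- abs(object@tau - object@mu * object@gamma)
  sc <- pmax(object@tau, 1e-300)
  if (any(rel / sc > 1e-6 & rel > 1e-12))
    msg <- c(msg, "tau must equal mu*gamma to 6 significant figures")
  if (length(msg)) msg else TRUE
})

#' Normalized helicity field
#'
#' Normalized helicity density Hn = (V . w)/(|V||w|) per interior node, the
#' cosine of the angle between velocity and vorticity; set to 0 where either
#' magnitude is below the degeneracy floor.
#'
#' @slot nodes n x 3 sample positions, mm.
#' @slot hn normalized helicity in [-1, 1].
#' @slot floor magnitude floor below which Hn is defined as 0.
#' @exportClass HelicityField
setClass("HelicityField",
  representation(nodes = "matrix", hn = "numeric", floor = "numeric")
)

setValidity("HelicityField", function(object) {
  if (any(abs(object@hn) > 1 + 1e-12)) "|Hn| must be <= 1" else TRUE
})

#' Unwrapped wall map
#'
#' Wall quantity binned over (arclength from root) x (azimuth in degrees),
#' with masked holes at branch ostia and an orientation key recording which
#' azimuth faces the superior/dorsal surface.
#'
#' @slot values ns x ntheta matrix of binned values (NA where masked).
#' @slot s arclength bin centers, mm.
#' @slot theta azimuth bin centers, degrees in [0, 360).
#' @slot holes logical ns x ntheta, TRUE at masked ostial holes.
#' @slot orientationKey character, anatomical direction at azimuth 0.
#' @exportClass UnwrappedMap
setClass("UnwrappedMap",
  representation(values = "matrix", s = "numeric", theta = "numeric",
                 holes = "matrix", orientationKey = "character")
)
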