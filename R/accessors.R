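#' Accessors for fetoflow S4 containers
#'
#' Accessor generics for the package's data containers, in place of direct
#' slot access.
#'
#' @param x an object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("groundTruthMask", function(x) standardGeneric("groundTruthMask"))
#' @rdname accessors
#' @export
setGeneric("treeSegments", function(x) standardGeneric("treeSegments"))
#' @rdname accessors
#' @export
setGeneric("treeJunctions", function(x) standardGeneric("treeJunctions"))
#' @rdname accessors
#' @export
setGeneric("treeLandmarks", function(x) standardGeneric("treeLandmarks"))
#' @rdname accessors
#' @export
setGeneric("dopplerRecords", function(x) standardGeneric("dopplerRecords"))
#' @rdname accessors
#' @export
setGeneric("trueCurveCoeffs", function(x) standardGeneric("trueCurveCoeffs"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("centerlinePoints", function(x) standardGeneric("centerlinePoints"))
#' @rdname accessors
#' @export
setGeneric("centerlineArclength", function(x) standardGeneric("centerlineArclength"))
#' @rdname accessors
#' @export
setGeneric("centerlineRadius", function(x) standardGeneric("centerlineRadius"))
#' @rdname accessors
#' @export
setGeneric("centerlineTangents", function(x) standardGeneric("centerlineTangents"))
#' @rdname accessors
#' @export
setGeneric("modelCoeffs", function(x) standardGeneric("modelCoeffs"))
#' @rdname accessors
#' @export
setGeneric("nodeVelocity", function(x) standardGeneric("nodeVelocity"))
#' @rdname accessors
#' @export
setGeneric("nodePressure", function(x) standardGeneric("nodePressure"))
#' @rdname accessors
#' @export
setGeneric("nodeVorticity", function(x) standardGeneric("nodeVorticity"))
#' @rdname accessors
#' @export
setGeneric("fieldNodes", function(x) standardGeneric("fieldNodes"))
#' @rdname accessors
#' @export
setGeneric("wallTau", function(x) standardGeneric("wallTau"))
#' @rdname accessors
#' @export
setGeneric("wallGamma", function(x) standardGeneric("wallGamma"))
#' @rdname accessors
#' @export
setGeneric("helicityValues", function(x) standardGeneric("helicityValues"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
setMethod("voxelData", "ImageStack", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "SegmentationMask", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelSpacing", "ImageStack", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname accessors
setMethod("groundTruthMask", "ImageStack", function(x) {
  if (!length(x@mask)) return(NULL)
  array(x@mask, dim(x@voxels))
})
#' @rdname accessors
setMethod("treeSegments", "VesselTree", function(x) x@segments)
#' @rdname accessors
setMethod("treeJunctions", "VesselTree", function(x) x@junctions)
#' @rdname accessors
setMethod("treeLandmarks", "VesselTree", function(x) x@landmarks)
#' @rdname accessors
setMethod("dopplerRecords", "DopplerSet", function(x) x@records)
#' @rdname accessors
setMethod("trueCurveCoeffs", "DopplerSet", function(x) x@trueCoeffs)
#' @rdname accessors
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
setMethod("centerlinePoints", "Centerline", function(x) x@points)
#' @rdname accessors
setMethod("centerlineArclength", "Centerline", function(x) x@arclength)
#' @rdname accessors
setMethod("centerlineRadius", "Centerline", function(x) x@radius)
#' @rdname accessors
setMethod("centerlineTangents", "Centerline", function(x) x@tangents)
#' @rdname accessors
setMethod("modelCoeffs", "VelocityAgeModel", function(x) x@coeffs)
#' @rdname accessors
setMethod("nodeVelocity", "FlowField", function(x) x@velocity)
#' @rdname accessors
setMethod("nodePressure", "FlowField", function(x) x@pressure)
#' @rdname accessors
setMethod("nodeVorticity", "FlowField", function(x) x@vorticity)
#' @rdname accessors
setMethod("fieldNodes", "FlowField", function(x) x@mesh@nodes)
#' @rdname accessors
setMethod("wallTau", "WallShearField", function(x) x@tau)
#' @rdname accessors
setMethod("wallGamma", "WallShearField", function(x) x@gamma)
#' @rdname accessors
setMethod("helicityValues", "HelicityField", function(x) x@hn)
#' @rdname accessors
setMethod("mapValues", "UnwrappedMap", function(x) x@values)

setMethod("show", "StageConfig", function(object) {
  cat(sprintf("StageConfig: E%.1f | HR %.0f bpm (omega %.2f rad/s) | ejection %.2f\n",
              object@ageDays, object@heartRate, object@omega, object@ejectionRatio))
  cat(sprintf("  Hct schedule: %.3f @E10.5 -> %.3f @E%.1f | DAo diameter %.3f mm | seed %d\n",
              object@hctAnchorEarly, object@hctAnchorTerm, object@termDay,
              object@daoDiameter, object@seed))
})

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree (E%.1f, seed %d): %d segments, %d junctions, %d landmarks\n",
              object@ageDays, object@seed, length(object@segments),
              nrow(object@junctions), nrow(object@landmarks)))
  for (s in object@segments)
    cat(sprintf("  %-20s n=%3d  radius %.3f-%.3f mm\n", s$role,
                nrow(s$points), min(s$radius), max(s$radius)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d x %d voxels @ (%.1f, %.1f, %.1f) um%s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3],
              if (length(object@mask)) " [ground-truth mask retained]" else ""))
})

setMethod("show", "DopplerSet", function(object) {
  cat(sprintf("DopplerSet: %d records, %d vessels, ages %.1f-%.1f, noise CV %.3f\n",
              nrow(object@records), length(unique(object@records$vessel)),
              min(object@records$age_days), max(object@records$age_days),
              object@noiseCV))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %s voxels, %d lumen voxels, %d component(s)\n",
              paste(dim(object@voxels), collapse = " x "),
              sum(object@voxels), max(object@labels)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, %d open boundary loop(s)\n",
              nrow(object@vertices), nrow(object@faces),
              length(object@openBoundaries)))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, length %.3f mm, radius %.3f-%.3f mm\n",
              nrow(object@points), max(object@arclength),
              min(object@radius), max(object@radius)))
})

setMethod("show", "BloodProperties", function(object) {
  cat(sprintf("BloodProperties: Hct %.3f | mu %.3f mPa.s | nu %.3f cSt | rho %.2f g/cm3\n",
              object@hct, object@mu, object@nu, object@density))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "VelocityAgeModel", function(object) {
  cat(sprintf("VelocityAgeModel: V(t) = %.4g + %.4g t + %.4g t^2 mm/s on [%.1f, %.1f]\n",
              object@coeffs[1], object@coeffs[2], object@coeffs[3],
              object@tRange[1], object@tRange[2]))
})

setMethod("show", "FlowBoundarySet", function(object) {
  cat(sprintf("FlowBoundarySet: total flow %.4g mm3/s, %d inlet(s), %d outlet(s)\n",
              object@totalFlow, nrow(object@inlets), nrow(object@outlets)))
})

setMethod("show", "FlowMesh", function(object) {
  cat(sprintf("FlowMesh (%s, level %g): %s cells, patches: %s\n",
              object@type, object@level,
              paste(object@dims, collapse = " x "),
              paste(object@patches, collapse = ", ")))
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField on %s mesh: %d nodes, max |V| %.4g mm/s, div residual %.2g\n",
              object@mesh@type, nrow(object@velocity),
              max(sqrt(rowSums(object@velocity^2))), object@divergenceNorm))
})

setMethod("show", "WallShearField", function(object) {
  cat(sprintf("WallShearField: %d samples, tau %.4g-%.4g mPa (mu %.3f mPa.s)\n",
              length(object@tau), min(object@tau), max(object@tau), object@mu))
})

setMethod("show", "HelicityField", function(object) {
  cat(sprintf("HelicityField: %d samples, Hn range [%.3f, %.3f]\n",
              length(object@hn), min(object@hn), max(object@hn)))
})

setMethod("show", "UnwrappedMap", function(object) {
  cat(sprintf("UnwrappedMap: %d x %d bins (s x azimuth), %d hole bins, azimuth 0 = %s\n",
              nrow(object@values), ncol(object@values), sum(object@holes),
              object@orientationKey))
})
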