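# File interchange: multi-page TIFF stacks with JSON sidecar metadata,
# CSV Doppler records, JSON vessel trees, ASCII STL surfaces and legacy
# VTK polydata centerlines / point fields.

#' Write an image stack as multi-page TIFF plus sidecar metadata
#'
#' One TIFF page per slice (first axis); intensities are linearly scaled
#' to [0, 1] for storage and the scale recorded in the JSON sidecar
#' (\code{<path>.json}) together with spacing, origin and provenance.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
writeImageStack <- function(stack, path) {
  v <- stack@voxels
  rg <- range(v)
  scl <- if (diff(rg) > 0) diff(rg) else 1
  vn <- (v - rg[1]) / scl
  pages <- lapply(seq_len(dim(v)[1]), function(i) vn[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(spacing_um = stack@spacing, axis_order = c("slice", "row", "col"),
         intensity_offset = rg[1], intensity_scale = scl,
         provenance = stack@provenance),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read an image stack written by \code{\link{writeImageStack}}
#'
#' @param path TIFF path (expects \code{<path>.json} sidecar).
#' @return an \linkS4class{ImageStack} (without ground-truth mask).
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) v[i, , ] <- pages[[i]]
  v <- v * meta$intensity_scale + meta$intensity_offset
  prov <- if (is.null(meta$provenance)) list() else as.list(meta$provenance)
  new("ImageStack", voxels = v, spacing = as.numeric(meta$spacing_um),
      mask = logical(0), provenance = prov)
}

#' Serialize a vessel tree to structured JSON
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param path output path.
#' @export
writeVesselTree <- function(tree, path) {
  segs <- lapply(tree@segments, function(s)
    list(role = s$role, points = s$points, radius = s$radius,
         ellipticity = s$ellipticity, elongAxis = s$elongAxis))
  jsonlite::write_json(
    list(ageDays = tree@ageDays, seed = tree@seed, segments = segs,
         junctions = tree@junctions, landmarks = tree@landmarks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel tree written by \code{\link{writeVesselTree}}
#'
#' @param path JSON path.
#' @return a \linkS4class{VesselTree}.
#' @export
readVesselTree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(x$segments, function(s)
    list(role = s$role, points = matrix(unlist(s$points), ncol = 3),
         radius = as.numeric(s$radius),
         ellipticity = as.numeric(s$ellipticity),
         elongAxis = matrix(unlist(s$elongAxis), ncol = 3)))
  vesselTree(segs, junctions = as.data.frame(x$junctions),
             landmarks = as.data.frame(x$landmarks),
             ageDays = x$ageDays, seed = x$seed)
}

#' Write Doppler records as CSV
#'
#' @param doppler a \linkS4class{DopplerSet}.
#' @param path output path.
#' @export
writeDopplerCSV <- function(doppler, path) {
  utils::write.csv(doppler@records, path, row.names = FALSE)
  invisible(path)
}

#' Read Doppler records from CSV
#'
#' @param path CSV with columns vessel, age_days, replicate,
#'   velocity_mm_s.
#' @return data.frame (usable directly by \code{\link{fitVelocityAge}}).
#' @export
readDopplerCSV <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output path.
#' @export
writeSTL <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid fetoflow", con)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- rowUnitize(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]))
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2],
                       nrm[i, 3]), con)
    writeLines("  outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("    vertex %.9g %.9g %.9g", v[f[i, k], 1],
                         v[f[i, k], 2], v[f[i, k], 3]), con)
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid fetoflow", con)
  invisible(path)
}

#' Write a centerline as legacy VTK polydata
#'
#' @param centerline a \linkS4class{Centerline}.
#' @param path output path.
#' @export
writeCenterlineVTK <- function(centerline, path) {
  p <- centerline@points
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fetoflow centerline",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(p, 1, function(r) paste(r, collapse = " ")), con)
  writeLines(sprintf("LINES 1 %d", n + 1), con)
  writeLines(paste(c(n, seq_len(n) - 1), collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS radius_mm float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", centerline@radius), con)
  invisible(path)
}

#' Write a flow field as legacy VTK point data
#'
#' Nodes with named arrays velocity_mm_s, pressure_Pa, vorticity_per_s.
#'
#' @param field a \linkS4class{FlowField}.
#' @param path output path.
#' @export
writeFieldVTK <- function(field, path) {
  p <- field@mesh@nodes
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fetoflow flow field",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(p, 1, function(r) paste(r, collapse = " ")), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS velocity_mm_s float"), con)
  writeLines(apply(field@velocity, 1, function(r) paste(r, collapse = " ")),
             con)
  writeLines(c("SCALARS pressure_Pa float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", field@pressure), con)
  writeLines("VECTORS vorticity_per_s float", con)
  writeLines(apply(field@vorticity, 1, function(r) paste(r, collapse = " ")),
             con)
  invisible(path)
}
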