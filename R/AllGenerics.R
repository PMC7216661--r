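#' Access the intensity grid of a CTVolume
#'
#' @param x a \linkS4class{CTVolume}.
#' @return The 3-D numeric array, \code{dim = c(nz, ny, nx)}.
#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))

#' @rdname ctData
#' @export
setMethod("ctData", "CTVolume", function(x) x@data)

#' Voxel pitch of a CTVolume
#'
#' @param x a \linkS4class{CTVolume}.
#' @return numeric(3) pitch \code{(dz, dy, dx)} in mm.
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))

#' @rdname voxelPitch
#' @export
setMethod("voxelPitch", "CTVolume", function(x) x@pitch)

#' @describeIn ctData dimensions \code{(nz, ny, nx)} of the grid.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

#' Physical extent of a CTVolume
#'
#' @param x a \linkS4class{CTVolume}.
#' @return numeric(3), extent in mm along (z, y, x).
#' @examples
#' physicalExtent(CTVolume(array(0, c(860, 1024, 1024)), pitch = 0.3))
#' @export
setGeneric("physicalExtent", function(x) standardGeneric("physicalExtent"))

#' @rdname physicalExtent
#' @export
setMethod("physicalExtent", "CTVolume", function(x) dim(x@data) * x@pitch)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  ext <- d * object@pitch
  rng <- range(object@data)
  cat(sprintf("CTVolume: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  pitch    : %g x %g x %g mm\n",
              object@pitch[1], object@pitch[2], object@pitch[3]))
  cat(sprintf("  extent   : %.1f x %.1f x %.1f mm\n", ext[1], ext[2], ext[3]))
  cat(sprintf("  intensity: [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "BimodalModes", function(object) {
  cat(sprintf("BimodalModes: air %g, soil %g (separation %g)\n",
              object@mAir, object@mSoil, modeSeparation(object)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  median kernel  : %d voxels\n", object@kMed))
  cat(sprintf("  blur kernel    : %d px\n", object@kBlur))
  cat(sprintf("  threshold      : %s\n",
              if (is.na(object@threshold)) "off" else format(object@threshold)))
  cat(sprintf("  size opening   : %s (connectivity %d)\n",
              if (is.na(object@minSize)) "off" else
                sprintf(">= %g voxels", object@minSize), object@connectivity))
  cat(sprintf("  crop cylinder  : %s\n",
              if (is.na(object@cropDiameterMm)) "off" else
                sprintf("%g mm diameter x %g mm deep",
                        object@cropDiameterMm, object@cropHeightMm)))
  cat(sprintf("  export         : %s\n", object@exportMode))
})

setMethod("show", "RootSystemTruth", function(object) {
  cat(sprintf("RootSystemTruth: %d roots (%s architecture, seed %d)\n",
              length(object@roots), object@archetype, object@seed))
  if (length(object@roots)) {
    dia <- vapply(object@roots, function(r) r$diameter, numeric(1))
    cat(sprintf("  diameters: %.2f - %.2f mm\n", min(dia), max(dia)))
  }
})

setMethod("show", "ScanProtocol", function(object) {
  cat("ScanProtocol\n")
  print(protocolTable(object), row.names = FALSE)
})

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf("DetectionReport: %d roots, %d detected (%.1f%%), %d undetected (%.1f%%)\n",
              object@nDetected + object@nUndetected, object@nDetected,
              object@percentDetected, object@nUndetected,
              object@percentUndetected))
})

#' @describeIn scoreDetection per-root rows of a report.
#' @export
setGeneric("perRoot", function(x) standardGeneric("perRoot"))

#' @rdname scoreDetection
#' @export
setMethod("perRoot", "DetectionReport", function(x) x@perRoot)

#' @describeIn scoreDetection detected / undetected counts and percentages
#'   as a named numeric vector.
#' @export
setGeneric("detectionCounts", function(x) standardGeneric("detectionCounts"))

#' @rdname scoreDetection
#' @export
setMethod("detectionCounts", "DetectionReport", function(x) {
  c(n_detected = x@nDetected, n_undetected = x@nUndetected,
    percent_detected = x@percentDetected,
    percent_undetected = x@percentUndetected)
})
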