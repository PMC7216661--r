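## Image-quality and visualization measures.

#' Contrast-to-noise ratio between root and soil regions
#'
#' \code{CNR = |S1 - S2| / sigma}, where S1 is the mean intensity of the
#' root-fraction voxels, S2 the mean of the soil-fraction voxels, and
#' sigma the population standard deviation of the soil fraction. A higher
#' CNR means roots stand out more from soil. CNR is invariant under
#' global affine intensity maps \code{v -> a v + b}, a > 0.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param rootMask,soilMask disjoint voxel selections: logical arrays of
#'   the volume's dimensions, or integer index vectors into the grid.
#' @return Nonnegative numeric CNR.
#' @section Errors: empty or overlapping masks, and \code{sigma == 0}
#'   (undefined CNR), are errors.
#' @export
cnr <- function(volume, rootMask, soilMask) {
  stopifnot(is(volume, "CTVolume"))
  root_idx <- mask_indices(rootMask, dim(volume@data), "rootMask")
  soil_idx <- mask_indices(soilMask, dim(volume@data), "soilMask")
  if (length(intersect(root_idx, soil_idx)))
    stop("root and soil masks must be disjoint")
  s1 <- mean(volume@data[root_idx])
  soil <- volume@data[soil_idx]
  s2 <- mean(soil)
  sigma <- sqrt(mean((soil - s2)^2))  # population sd
  if (sigma == 0) stop("soil-fraction standard deviation is zero; CNR undefined")
  abs(s1 - s2) / sigma
}

mask_indices <- function(mask, d, what) {
  if (is.logical(mask)) {
    if (!identical(dim(mask), as.integer(d)) && length(mask) != prod(d))
      stop(what, " does not match the volume dimensions")
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
    if (any(idx < 1L | idx > prod(d))) stop(what, " indexes outside the volume")
  }
  if (length(idx) == 0L) stop(what, " is empty")
  idx
}

#' Maximum intensity projection
#'
#' Projects the per-ray maximum along one axis. Axis \code{"z"} gives the
#' top-down (horizontal) view of the pot; \code{"y"} and \code{"x"} give
#' side (vertical) views. Increasing any voxel never decreases any
#' projection pixel.
#'
#' @param volume a non-empty \linkS4class{CTVolume}.
#' @param axis "z", "y" or "x".
#' @return 2-D matrix: (y, x) for axis z; (z, x) for axis y; (z, y) for
#'   axis x.
#' @export
mip <- function(volume, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  stopifnot(is(volume, "CTVolume"))
  keep <- switch(axis, z = c(2L, 3L), y = c(1L, 3L), x = c(1L, 2L))
  apply(volume@data, keep, max)
}

#' Write a projection as an 8-bit grayscale PNG
#'
#' @param projection matrix from \code{\link{mip}} (values in [0, 255]).
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeProjection <- function(projection, path) {
  v <- pmin(pmax(projection, 0), 255)
  png::writePNG(v / 255, path)
  invisible(path)
}
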