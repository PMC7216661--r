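## The root-segmentation transform chain:
##   normalize -> 3-D median -> invert -> per-slice blur-subtraction edge
##   detection -> (optional threshold + 3-D size opening) -> cylinder crop
##   -> 8-bit export.
## Roots absorb less X-ray than calcined clay, so after inversion they are
## the bright structures; subtracting a box-blurred copy of each slice
## flattens the remaining smooth soil background to zero.

check_odd <- function(k, what) {
  if (length(k) != 1L || is.na(k) || k < 1L || k %% 2L == 0L)
    stop(what, " must be an odd integer >= 1 (got ", k, ")")
  as.integer(k)
}

#' 3-D median filter
#'
#' Replaces each voxel by the median of its k x k x k cubic neighborhood.
#' Borders use edge replication. Kernel size 1 is the identity. The median
#' suppresses granular soil speckle while preserving tube-like root
#' structures better than linear smoothing; kernel size 7 gives the best
#' root-to-soil contrast at 0.3 mm voxels.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param k odd kernel edge in voxels.
#' @param workers number of parallel workers; the volume is split into
#'   z-chunks with a halo of \code{(k-1)/2} slices so the result is
#'   byte-identical for any worker count.
#' @return The filtered \linkS4class{CTVolume}.
#' @export
medianFilter3D <- function(volume, k = 7L, workers = 1L) {
  stopifnot(is(volume, "CTVolume"))
  k <- check_odd(k, "median kernel size")
  if (k == 1L) return(volume)
  d <- dim(volume@data)
  if (workers <= 1L || d[1] < 2L * workers) {
    out <- array(median3d_cpp(as.vector(volume@data), d, k), d)
    return(CTVolume(out, volume@pitch))
  }
  r <- (k - 1L) %/% 2L
  bounds <- chunk_bounds(d[1], workers)
  parts <- parallel::mclapply(bounds, function(b) {
    z0 <- max(1L, b[1] - r); z1 <- min(d[1], b[2] + r)
    sub <- volume@data[z0:z1, , , drop = FALSE]
    res <- array(median3d_cpp(as.vector(sub), dim(sub), k), dim(sub))
    res[(b[1] - z0 + 1L):(b[2] - z0 + 1L), , , drop = FALSE]
  }, mc.cores = workers)
  CTVolume(do.call(abind_z, parts), volume@pitch)
}

chunk_bounds <- function(n, chunks) {
  chunks <- max(1L, min(as.integer(chunks), n))
  cut <- floor(seq(0L, n, length.out = chunks + 1L))
  lapply(seq_len(chunks), function(i) c(cut[i] + 1L, cut[i + 1L]))
}

abind_z <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  nz <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(nz, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    out[at:(at + dim(p)[1] - 1L), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Invert a normalized volume about the soil anchor
#'
#' Computes \code{v' = max(0, anchor - v)}. On a mode-normalized volume
#' (soil at 1024) roots, being darker than soil, become the bright
#' foreground; soil maps to approximately zero; denser-than-soil material
#' (pot wall, minerals, v > anchor) clamps to zero.
#'
#' @param volume a normalized \linkS4class{CTVolume}.
#' @param anchor intensity about which to invert (default 1024, the soil
#'   normalization anchor).
#' @return The inverted \linkS4class{CTVolume}.
#' @export
invertVolume <- function(volume, anchor = 1024) {
  stopifnot(is(volume, "CTVolume"))
  out <- anchor - volume@data
  out[out < 0] <- 0
  CTVolume(out, volume@pitch)
}

#' Blur-subtraction edge detection on one slice
#'
#' \code{out = max(0, slice - boxblur(slice, k))}: subtracting a k x k
#' box-averaged copy removes everything smooth at scale k, leaving
#' fine bright structures (roots) as edges. Edge replication at borders.
#' Kernel size 1 subtracts the slice from itself and yields all zeros.
#'
#' @param slice 2-D numeric matrix (one z-slice).
#' @param kBlur odd blur kernel edge in pixels (default 21).
#' @return Matrix of the same size, nonnegative.
#' @export
edgeDetectSlice <- function(slice, kBlur = 21L) {
  stopifnot(is.matrix(slice))
  kBlur <- check_odd(kBlur, "blur kernel size")
  out <- slice - box_blur_cpp(slice, kBlur)
  out[out < 0] <- 0
  out
}

#' Per-slice edge detection over a volume
#'
#' Applies \code{\link{edgeDetectSlice}} independently to every z-slice.
#' Slices are independent, so any worker count gives identical output.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param kBlur odd blur kernel edge in pixels.
#' @param workers number of parallel workers.
#' @return The edge-detected \linkS4class{CTVolume}.
#' @export
edgeDetectVolume <- function(volume, kBlur = 21L, workers = 1L) {
  stopifnot(is(volume, "CTVolume"))
  kBlur <- check_odd(kBlur, "blur kernel size")
  d <- dim(volume@data)
  idx <- seq_len(d[1])
  apply_one <- function(i) edgeDetectSlice(volume@data[i, , ], kBlur)
  slices <- if (workers > 1L) {
    parallel::mclapply(idx, apply_one, mc.cores = workers)
  } else {
    lapply(idx, apply_one)
  }
  out <- array(0, d)
  for (i in idx) out[i, , ] <- slices[[i]]
  CTVolume(out, volume@pitch)
}

#' Threshold and 3-D size opening
#'
#' Builds the binary mask \code{volume >= threshold}, labels its 3-D
#' connected components under the chosen connectivity, deletes components
#' smaller than \code{minSize} voxels, and returns the grayscale volume
#' masked to the survivors. Used to remove small non-root segments
#' (voids, water gradients); off by default in the standard chain since
#' it can also erase fine young roots.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param threshold intensity threshold (>= 0) on the working scale.
#' @param minSize minimum component voxel count to keep (>= 1); 1 keeps
#'   the mask unchanged (pure thresholding).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return The opened \linkS4class{CTVolume}; an all-zero result is valid.
#' @export
thresholdAndOpen <- function(volume, threshold, minSize = 1L,
                             connectivity = 26L) {
  stopifnot(is(volume, "CTVolume"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (minSize < 1) stop("minSize must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(volume@data)
  mask <- volume@data >= threshold
  labels <- label3d_cpp(as.vector(mask), d, as.integer(connectivity))
  keep <- mask
  if (any(labels > 0L)) {
    sizes <- tabulate(labels)
    small <- which(sizes < minSize)
    if (length(small)) keep[array(labels %in% small, d)] <- FALSE
  }
  CTVolume(volume@data * keep, volume@pitch)
}

#' Crop a volume to a centered cylinder
#'
#' Zeroes voxels whose (y, x) center lies outside the circle of the given
#' diameter centered on the slice center, or whose depth below the top
#' slice exceeds the given height. Used to trim away the pot wall and
#' roots touching it. Grid dimensions are unchanged.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param diameterMm cylinder diameter in mm.
#' @param heightMm cylinder height in mm, measured down from the top slice.
#' @return The cropped \linkS4class{CTVolume}.
#' @export
cropCylinder <- function(volume, diameterMm = 180, heightMm = 250) {
  stopifnot(is(volume, "CTVolume"))
  if (diameterMm <= 0 || heightMm <= 0) stop("crop dimensions must be > 0")
  d <- dim(volume@data)
  ext <- d * volume@pitch  # (z, y, x) mm
  if (diameterMm > min(ext[2], ext[3]) || heightMm > ext[1])
    stop(sprintf(paste0("crop cylinder (%g mm diameter x %g mm) exceeds the ",
                        "volume extent (%g x %g x %g mm)"),
                 diameterMm, heightMm, ext[1], ext[2], ext[3]))
  yc <- ((seq_len(d[2]) - 0.5) * volume@pitch[2]) - ext[2] / 2
  xc <- ((seq_len(d[3]) - 0.5) * volume@pitch[3]) - ext[3] / 2
  inside_yx <- outer(yc^2, xc^2, "+") <= (diameterMm / 2)^2
  zc <- (seq_len(d[1]) - 0.5) * volume@pitch[1]
  inside_z <- zc <= heightMm
  out <- volume@data
  out[!inside_z, , ] <- 0
  mask3 <- aperm(array(inside_yx, c(d[2], d[3], d[1])), c(3, 1, 2))
  out[!mask3] <- 0
  CTVolume(out, volume@pitch)
}

#' Export a processed volume to the 8-bit range
#'
#' \code{clip} mode truncates values above 255 (preserving absolute edge
#' magnitudes, hence comparability across time points of a 4-D series);
#' \code{rescale} maps \code{[0, max]} linearly onto \code{[0, 255]} for
#' display. Values are rounded half-up to integers in [0, 255].
#'
#' @param volume a nonnegative working \linkS4class{CTVolume}.
#' @param mode "clip" (default) or "rescale".
#' @return An 8-bit \linkS4class{CTVolume} (integral values in [0, 255]).
#' @export
export8bit <- function(volume, mode = c("clip", "rescale")) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "CTVolume"))
  v <- volume@data
  if (min(v) < 0) stop("export expects a nonnegative working volume")
  if (mode == "rescale") {
    m <- max(v)
    if (m > 0) v <- v * (255 / m)
  } else {
    v[v > 255] <- 255
  }
  CTVolume(array(floor(v + 0.5), dim(v)), volume@pitch)  # round half-up
}

#' Run the full root-segmentation chain
#'
#' normalize -> 3-D median -> invert -> per-slice edge detection ->
#' optional threshold + size opening -> cylinder crop -> 8-bit export.
#' The output is byte-identical for any \code{workers} value.
#'
#' @param volume a raw (16-bit scale) \linkS4class{CTVolume}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param modes optional \linkS4class{BimodalModes} override; detected
#'   from the histogram when \code{NULL}.
#' @param workers number of parallel workers for the median and edge
#'   stages.
#' @return The processed 8-bit \linkS4class{CTVolume}.
#' @examples
#' cfg <- pipelineConfig(cropDiameterMm = NA)  # no crop on a small grid
#' vol <- CTVolume(array(22000 + rnorm(20^3, 0, 10), c(20, 20, 20)))
#' out <- runPipeline(vol, cfg, modes = bimodalModes(8000, 22000))
#' @export
runPipeline <- function(volume, config = pipelineConfig(), modes = NULL,
                        workers = 1L) {
  stopifnot(is(volume, "CTVolume"), is(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  v <- stage("normalize", normalizeVolume(volume, modes))
  v <- stage("median", medianFilter3D(v, config@kMed, workers))
  v <- stage("invert", invertVolume(v))
  v <- stage("edge", edgeDetectVolume(v, config@kBlur, workers))
  if (!is.na(config@threshold) && !is.na(config@minSize)) {
    v <- stage("open", thresholdAndOpen(v, config@threshold, config@minSize,
                                        config@connectivity))
  }
  if (!is.na(config@cropDiameterMm) && !is.na(config@cropHeightMm)) {
    v <- stage("crop", cropCylinder(v, config@cropDiameterMm,
                                    config@cropHeightMm))
  }
  stage("export", export8bit(v, config@exportMode))
}
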