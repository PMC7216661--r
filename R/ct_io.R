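## Slice-stack I/O. A CT volume travels as an ordered stack of 2-D
## grayscale slice files (16-bit TIFF/PNG in, 8-bit out, or headerless raw
## with a JSON sidecar). Slice order is always the lexicographic file
## order, never filesystem enumeration order.

RAW_SIDECAR <- "stack_manifest.json"

#' Build a StackManifest for an existing slice directory
#'
#' Matches files by extension pattern, sorts them lexicographically and
#' records slice geometry. For \code{format = "raw"} the geometry is read
#' from the JSON sidecar written by \code{\link{saveSliceStack}}.
#'
#' @param directory directory containing one file per slice.
#' @param format "tiff", "png" or "raw".
#' @param pattern optional regular expression used to select files;
#'   defaults to the canonical extension of \code{format}.
#' @return A \linkS4class{StackManifest}.
#' @export
stackManifest <- function(directory, format = c("tiff", "png", "raw"),
                          pattern = NULL) {
  format <- match.arg(format)
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  if (is.null(pattern)) {
    pattern <- switch(format,
      tiff = "\\.tiff?$", png = "\\.png$", raw = "\\.raw$")
  }
  files <- sort(list.files(directory, pattern = pattern))
  if (length(files) == 0L) stop("no slice files matching '", pattern,
                                "' in ", directory)
  width <- height <- NA_integer_
  bitDepth <- 16L
  endian <- "little"
  if (format == "raw") {
    sidecar <- file.path(directory, RAW_SIDECAR)
    if (!file.exists(sidecar))
      stop("raw stacks need a sidecar manifest: ", sidecar, " is missing")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    need <- c("width", "height", "bit_depth", "endian")
    missing <- setdiff(need, names(meta))
    if (length(missing))
      stop("sidecar manifest lacks field(s): ", paste(missing, collapse = ", "))
    width <- as.integer(meta$width); height <- as.integer(meta$height)
    bitDepth <- as.integer(meta$bit_depth); endian <- meta$endian
  }
  new("StackManifest", directory = directory, files = files, format = format,
      width = width, height = height, bitDepth = bitDepth, endian = endian)
}

read_slice <- function(path, manifest) {
  switch(manifest@format,
    tiff = tiff::readTIFF(path, as.is = TRUE) + 0,  # integers, as double
    png = {
      img <- png::readPNG(path, info = TRUE)
      depth <- attr(img, "info")$bit.depth
      if (!depth %in% c(8L, 16L))
        stop("unsupported PNG bit depth (", depth, ") in ", path)
      round(img * (2^depth - 1))
    },
    raw = {
      n <- manifest@width * manifest@height
      con <- file(path, "rb"); on.exit(close(con))
      v <- readBin(con, what = "integer", n = n,
                   size = manifest@bitDepth / 8L, signed = FALSE,
                   endian = manifest@endian)
      if (length(v) != n)
        stop("raw slice ", path, " holds ", length(v),
             " pixels, expected ", n)
      matrix(as.double(v), nrow = manifest@height, ncol = manifest@width)
    })
}

#' Load a CT volume from a stack of 2-D grayscale slices
#'
#' Slices are stacked in lexicographic filename order: slice 1 of the
#' volume is the first file, taken as the topmost slice of the pot.
#' All slices must exist and share identical dimensions.
#'
#' @param manifest a \linkS4class{StackManifest}, or a directory path
#'   (then \code{format} selects the reader).
#' @param pitch voxel pitch in mm, scalar or \code{c(dz, dy, dx)}.
#' @param format used only when \code{manifest} is a directory path.
#' @return A \linkS4class{CTVolume}; slice \code{i} of the volume is
#'   bit-identical to the pixel grid of file \code{i}.
#' @seealso \code{\link{saveSliceStack}}
#' @export
loadSliceStack <- function(manifest, pitch = 0.3, format = "tiff") {
  if (is.character(manifest)) manifest <- stackManifest(manifest, format)
  stopifnot(is(manifest, "StackManifest"))
  paths <- file.path(manifest@directory, manifest@files)
  gone <- paths[!file.exists(paths)]
  if (length(gone)) stop("missing slice file: ", gone[[1L]])
  slices <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    sl <- read_slice(paths[[i]], manifest)
    if (!is.matrix(sl))
      stop("slice ", paths[[i]], " is not single-channel grayscale")
    if (i > 1L && !identical(dim(sl), dim(slices[[1L]])))
      stop("slice dimension mismatch in ", paths[[i]], ": ",
           paste(dim(sl), collapse = "x"), " vs ",
           paste(dim(slices[[1L]]), collapse = "x"))
    slices[[i]] <- sl
  }
  nz <- length(slices)
  ny <- nrow(slices[[1L]]); nx <- ncol(slices[[1L]])
  data <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) data[i, , ] <- slices[[i]]
  CTVolume(data, pitch)
}

write_slice <- function(mat, path, format, bitDepth, endian) {
  switch(format,
    tiff = tiff::writeTIFF(mat / (2^bitDepth - 1), path,
                           bits.per.sample = bitDepth),
    png = {
      if (bitDepth != 8L) stop("PNG export is 8-bit only")
      png::writePNG(mat / 255, path)
    },
    raw = {
      con <- file(path, "wb"); on.exit(close(con))
      writeBin(as.integer(mat), con, size = bitDepth / 8L, endian = endian)
    })
  invisible(NULL)
}

#' Save a CT volume as a stack of 2-D grayscale slices
#'
#' Writes one file per z-slice with zero-padded numeric names
#' (\code{slice_0000}, ...) so that lexicographic order equals slice
#' order; reloading with \code{\link{loadSliceStack}} reproduces the
#' volume exactly. Values must be integral and within the declared bit
#' depth: out-of-range values are an error, never silently clipped.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param directory output directory (created if needed).
#' @param format "tiff", "png" or "raw".
#' @param bitDepth 8 or 16. PNG export supports 8-bit only.
#' @param endian byte order for raw output.
#' @return The \linkS4class{StackManifest} of the written stack,
#'   invisibly. Raw stacks also get a JSON sidecar recording geometry.
#' @export
saveSliceStack <- function(volume, directory, format = c("tiff", "png", "raw"),
                           bitDepth = 8L, endian = "little") {
  format <- match.arg(format)
  stopifnot(is(volume, "CTVolume"))
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  vmax <- 2^bitDepth - 1
  rng <- range(volume@data)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("volume values [%g, %g] outside the %d-bit range [0, %d]",
                 rng[1], rng[2], bitDepth, vmax))
  if (any(volume@data != round(volume@data)))
    stop("volume values must be integral for ", bitDepth, "-bit export")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume@data)
  ext <- switch(format, tiff = "tif", png = "png", raw = "raw")
  files <- sprintf("slice_%04d.%s", seq_len(d[1]) - 1L, ext)
  for (i in seq_len(d[1])) {
    write_slice(volume@data[i, , ], file.path(directory, files[[i]]),
                format, bitDepth, endian)
  }
  if (format == "raw") {
    jsonlite::write_json(
      list(width = d[3], height = d[2], bit_depth = bitDepth,
           endian = endian, n_slices = d[1],
           voxel_pitch_mm = volume@pitch),
      file.path(directory, RAW_SIDECAR), auto_unbox = TRUE)
  }
  invisible(new("StackManifest", directory = directory, files = files,
                format = format, width = d[3], height = d[2],
                bitDepth = bitDepth, endian = endian))
}
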