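## Mode-anchored grayscale normalization. Reconstructed scans of a
## soil-filled pot have a bimodal histogram (air mode low, soil mode high);
## anchoring air -> 0 and soil -> 1024 makes volumes comparable across
## scans whose window width/level differ, without any per-slice rescaling.

#' Grayscale histogram of a CT volume
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param binWidth bin width in gray levels (>= 1); default 16, a
#'   convenient granularity on the 16-bit scale.
#' @return A data.frame with columns \code{center} (bin centers) and
#'   \code{count}; counts sum to the voxel count and the bins cover the
#'   observed intensity range.
#' @export
computeHistogram <- function(volume, binWidth = 16) {
  stopifnot(is(volume, "CTVolume"))
  if (binWidth < 1) stop("binWidth must be >= 1")
  v <- as.vector(volume@data)
  if (length(v) == 0L) stop("empty volume")
  lo <- floor(min(v))
  idx <- floor((v - lo) / binWidth) + 1L
  counts <- tabulate(idx, nbins = max(idx))
  # bin i covers gray levels [lo + (i-1)*bw, lo + i*bw); for integer data
  # the representative center is the midpoint of the covered levels, so a
  # bin width of 1 reports the gray level itself
  centers <- lo + (seq_along(counts) - 1L) * binWidth + (binWidth - 1) / 2
  data.frame(center = centers, count = counts)
}

#' Locate the air and soil modes of a bimodal histogram
#'
#' Smooths the histogram with a centered moving average, finds local
#' maxima, and returns the two tallest peaks at least
#' \code{minSeparation} gray levels apart. The lower-intensity mode is
#' the air fraction (air absorbs less X-ray than soil).
#'
#' @param histogram data.frame from \code{\link{computeHistogram}}.
#' @param smoothingWindow moving-average window in bins (default 5).
#' @param minSeparation minimum mode separation in gray levels
#'   (default 64 on the 16-bit scale).
#' @return A \linkS4class{BimodalModes}.
#' @section Errors: if fewer than two qualifying peaks exist (e.g. a
#'   unimodal histogram), fails with a message instructing the caller to
#'   supply modes manually via \code{\link{bimodalModes}}.
#' @export
findBimodalModes <- function(histogram, smoothingWindow = 5,
                             minSeparation = 64) {
  stopifnot(is.data.frame(histogram), nrow(histogram) > 0L)
  counts <- histogram$count
  centers <- histogram$center
  w <- as.integer(smoothingWindow)
  if (w > 1L) {
    r <- w %/% 2L
    padded <- c(rep(counts[1L], r), counts, rep(counts[length(counts)], r))
    counts <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2L))
    counts <- counts[(r + 1L):(r + length(histogram$count))]
  }
  n <- length(counts)
  is_peak <- if (n == 1L) TRUE else {
    left <- c(-Inf, counts[-n])
    right <- c(counts[-1L], -Inf)
    counts > left & counts >= right
  }
  peaks <- which(is_peak)
  ord <- peaks[order(counts[peaks], decreasing = TRUE)]
  if (length(ord) >= 1L) {
    first <- ord[[1L]]
    # the second mode must be genuinely distinct: far enough away AND
    # separated from the first by a valley dropping below half its own
    # height, so noise bumps on the flank of a single mode never qualify
    for (second in ord[-1L]) {
      if (abs(centers[second] - centers[first]) < minSeparation) next
      if (counts[second] < 0.05 * counts[first]) break  # ord is by height
      between <- counts[min(first, second):max(first, second)]
      if (min(between) < 0.5 * counts[second]) {
        m <- sort(c(centers[first], centers[second]))
        return(bimodalModes(m[1L], m[2L]))
      }
    }
  }
  stop("histogram is not bimodal (no two prominent peaks separated by ",
       minSeparation, " gray levels); supply modes manually with ",
       "bimodalModes(mAir, mSoil)")
}

#' Normalize a CT volume to its air and soil modes
#'
#' Linearly rescales intensities so the air mode maps to 0 and the soil
#' mode to 1024, then rounds negative values up to zero:
#' \code{v' = max(0, 1024 * (v - mAir) / (mSoil - mAir))}. Values above
#' 1024 (dense minerals, pot wall) are retained untouched. The result is
#' a real-valued working volume.
#'
#' @param volume a \linkS4class{CTVolume} (typically raw 16-bit).
#' @param modes a \linkS4class{BimodalModes}; if missing, detected
#'   automatically via \code{\link{computeHistogram}} and
#'   \code{\link{findBimodalModes}} with their defaults.
#' @param binWidth,smoothingWindow,minSeparation passed to the automatic
#'   mode detection when \code{modes} is missing.
#' @return The normalized \linkS4class{CTVolume}.
#' @examples
#' vol <- CTVolume(array(c(100, 900, 500), c(3, 1, 1)))
#' ctData(normalizeVolume(vol, bimodalModes(100, 900)))[, 1, 1]
#' @export
normalizeVolume <- function(volume, modes = NULL, binWidth = 16,
                            smoothingWindow = 5, minSeparation = 64) {
  stopifnot(is(volume, "CTVolume"))
  if (is.null(modes)) {
    modes <- findBimodalModes(computeHistogram(volume, binWidth),
                              smoothingWindow, minSeparation)
  }
  stopifnot(is(modes, "BimodalModes"))
  sep <- modeSeparation(modes)
  if (sep == 0) stop("degenerate modes: mAir == mSoil")
  out <- 1024 * (volume@data - modes@mAir) / sep
  out[out < 0] <- 0
  CTVolume(out, volume@pitch)
}
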