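## Scoring of a processed volume against phantom ground truth: per-root
## detected/undetected calls, detection percentages, diameter-stratified
## summaries, and the median-kernel CNR sweep.

#' Score root detection against ground-truth centerlines
#'
#' A root's coverage is the fraction of its centerline voxels that have
#' at least one nonzero processed voxel within the tolerance radius
#' (Chebyshev distance, i.e. a cubic neighborhood of
#' \code{(2 tol + 1)^3} voxels). A root is detected iff its coverage is
#' at least \code{coverageThreshold}. This is the declared, testable
#' surrogate for the human visual detectability call made against
#' excavated-root photographs.
#'
#' @param processed a processed \linkS4class{CTVolume} (or 3-D array).
#' @param centerlines list of per-root integer matrices of (z, y, x)
#'   voxel indices, as returned by \code{\link{renderVolume}}.
#' @param truth optional \linkS4class{RootSystemTruth} supplying per-root
#'   diameters and classes for the report.
#' @param coverageThreshold coverage fraction required (default 0.5).
#' @param tolerance tolerance radius in voxels (default 1).
#' @return A \linkS4class{DetectionReport}. Detection is monotone:
#'   adding nonzero voxels to \code{processed} never lowers coverage.
#' @export
scoreDetection <- function(processed, centerlines, truth = NULL,
                           coverageThreshold = 0.5, tolerance = 1L) {
  data <- if (is(processed, "CTVolume")) processed@data else processed
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(centerlines) == 0L) stop("empty centerline set")
  hit <- dilate_box(data > 0, as.integer(tolerance))
  d <- dim(data)
  coverage <- vapply(centerlines, function(cl) {
    if (nrow(cl) == 0L) return(0)
    mean(hit[cbind(cl[, 1], cl[, 2], cl[, 3])])
  }, numeric(1))
  detected <- coverage >= coverageThreshold
  n <- length(coverage)
  diameters <- if (!is.null(truth)) {
    vapply(truth@roots, function(r) r$diameter, numeric(1))
  } else rep(NA_real_, n)
  classes <- if (!is.null(truth)) {
    vapply(truth@roots, function(r) r$class, character(1))
  } else rep(NA_character_, n)
  perRoot <- data.frame(id = seq_len(n), class = classes,
                        diameter_mm = diameters, coverage = coverage,
                        detected = detected)
  detectionReport(sum(detected), sum(!detected), perRoot)
}

# Binary dilation by a cubic structuring element of radius r (Chebyshev).
dilate_box <- function(mask, r) {
  if (r == 0L) return(mask)
  d <- dim(mask)
  out <- mask
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dz == 0L && dy == 0L && dx == 0L) next
    z_src <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    y_src <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    x_src <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    out <- out | mask[z_src, y_src, x_src]
  }
  out
}

#' Build a DetectionReport from counts (and optionally per-root rows)
#'
#' Percentages are computed from the counts and sum to exactly 100
#' (\code{percentUndetected = 100 - percentDetected}).
#'
#' @param nDetected,nUndetected detection counts.
#' @param perRoot optional per-root data.frame.
#' @return A \linkS4class{DetectionReport}.
#' @examples
#' detectionCounts(detectionReport(68, 12))  # 85% detected, 15% not
#' @export
detectionReport <- function(nDetected, nUndetected,
                            perRoot = data.frame()) {
  n <- nDetected + nUndetected
  if (n < 1L) stop("report needs at least one root")
  pd <- 100 * nDetected / n
  new("DetectionReport", perRoot = perRoot,
      nDetected = as.integer(nDetected),
      nUndetected = as.integer(nUndetected),
      percentDetected = pd, percentUndetected = 100 - pd)
}

#' Five-number summaries of detected and undetected root diameters
#'
#' Min, first quartile, median, third quartile and max per group, the
#' statistics a box plot of detectable vs undetectable diameters draws.
#' Quartiles use linear interpolation between closest ranks
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param report a \linkS4class{DetectionReport} with per-root rows.
#' @return data.frame with columns \code{group}, \code{n}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max}; empty groups are
#'   reported with \code{n = 0} and \code{NA} statistics.
#' @export
diameterSummary <- function(report) {
  stopifnot(is(report, "DetectionReport"))
  pr <- report@perRoot
  if (nrow(pr) == 0L) stop("report has no per-root rows")
  one <- function(group, x) {
    if (length(x) == 0L) {
      return(data.frame(group = group, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(group = group, n = length(x), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  }
  rbind(one("detected", pr$diameter_mm[pr$detected]),
        one("undetected", pr$diameter_mm[!pr$detected]))
}

#' CNR of median-filtered volumes over a list of kernel sizes
#'
#' Filters the volume with each 3-D median kernel and evaluates the
#' root-to-soil CNR with the supplied masks. Kernel 1 is the unfiltered
#' volume. Duplicate kernels are deduplicated with a warning.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param rootMask,soilMask ground-truth masks passed to \code{\link{cnr}}.
#' @param kernels odd kernel sizes to sweep (default 1, 3, 5, 7, 9).
#' @param workers parallel workers for the median filter.
#' @return data.frame with columns \code{kernel} and \code{cnr}, sorted
#'   by kernel.
#' @export
kernelSweep <- function(volume, rootMask, soilMask,
                        kernels = c(1L, 3L, 5L, 7L, 9L), workers = 1L) {
  if (anyDuplicated(kernels)) {
    warning("duplicate kernel sizes dropped")
    kernels <- unique(kernels)
  }
  kernels <- sort(as.integer(kernels))
  vals <- vapply(kernels, function(k) {
    cnr(medianFilter3D(volume, k, workers), rootMask, soilMask)
  }, numeric(1))
  data.frame(kernel = kernels, cnr = vals)
}
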