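## Acquisition bookkeeping: scan duration, field-of-view geometry and
## X-ray dose budgets for repeated (4-D) scanning. The dose rate itself
## is an external input (e.g. from a dose calculator); no dose physics is
## derived from tube settings here.

#' Scan duration of a protocol
#'
#' Scanning time is the number of projections times the signal-averaging
#' frames, divided by the detector frame rate. Reported rounded down to
#' whole seconds (so 600 projections without averaging at 18 fps report
#' as 33 s). Binning changes detector resolution, not duration.
#'
#' @param protocol a \linkS4class{ScanProtocol}.
#' @return Integer number of whole seconds.
#' @examples
#' scanTimeS(scanProtocol())                            # 600
#' scanTimeS(scanProtocol(600, 1, 18, binning = "3x3")) # 33
#' @export
scanTimeS <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (protocol@fps <= 0) stop("fps must be > 0")
  floor(protocol@nProjections * protocol@averaging / protocol@fps)
}

#' Physical extent of an axis
#'
#' @param nVoxels number of voxels along the axis (>= 1).
#' @param pitchMm voxel pitch in mm (> 0).
#' @return Extent in mm.
#' @examples
#' physicalExtentMm(1024, 0.3)  # 307.2 mm = 30.72 cm
#' physicalExtentMm(860, 0.3)   # 258 mm = 25.8 cm
#' @export
physicalExtentMm <- function(nVoxels, pitchMm) {
  if (any(nVoxels < 1)) stop("nVoxels must be >= 1")
  if (any(pitchMm <= 0)) stop("pitch must be > 0")
  nVoxels * pitchMm
}

#' Geometric magnification of a cone-beam protocol
#'
#' Ratio of source-detector to source-rotation-axis distance.
#'
#' @param protocol a \linkS4class{ScanProtocol}.
#' @return Magnification ratio (>= 1).
#' @export
magnification <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (protocol@sodMm == 0) stop("source-rotation-axis distance is zero")
  protocol@sddMm / protocol@sodMm
}

#' Permissible scans within a cumulative dose budget
#'
#' How many scans fit under a cumulative-exposure safety limit:
#' \code{floor(limit / perScan)}. The default limit of 12.6 Gy is the
#' cumulative dose shown not to affect rice growth (9 daily scans of
#' 1.4 Gy).
#'
#' @param perScanGy absorbed dose per scan in Gy (> 0).
#' @param safetyLimitGy cumulative limit in Gy (default 12.6).
#' @return A list with \code{per_scan_gy}, \code{safety_limit_gy} and
#'   \code{scans_permissible} (integer), satisfying
#'   \code{scans * perScan <= limit < (scans + 1) * perScan}.
#' @examples
#' doseBudget(0.09)$scans_permissible  # 140
#' doseBudget(0.44)$scans_permissible  # 28
#' @export
doseBudget <- function(perScanGy, safetyLimitGy = 12.6) {
  if (perScanGy <= 0) stop("per-scan dose must be > 0")
  # decimal inputs rarely divide exactly in binary; snap ratios that are
  # within one part in 1e9 of an integer before flooring
  ratio <- safetyLimitGy / perScanGy
  n <- floor(ratio + 1e-9)
  list(per_scan_gy = perScanGy, safety_limit_gy = safetyLimitGy,
       scans_permissible = as.integer(n))
}

#' Cumulative dose over repeated scans
#'
#' @param perScanGy dose per scan in Gy.
#' @param nScans number of scans (>= 0).
#' @return Total dose in Gy (\code{perScanGy * nScans}).
#' @examples
#' cumulativeDose(1.4, 9)  # 12.6
#' @export
cumulativeDose <- function(perScanGy, nScans) {
  if (any(nScans < 0)) stop("nScans must be >= 0")
  perScanGy * nScans
}

#' Dose accrued during one scan from an externally supplied dose rate
#'
#' Multiplies the protocol's dose rate (Gy/h) by the scan duration. With
#' the 0.5 mm Cu-filter rate of 0.55 Gy/h and a 10-minute scan this gives
#' 0.0917 Gy, an upper bound for the thicker 1.0 mm filter actually used.
#'
#' @param protocol a \linkS4class{ScanProtocol} with
#'   \code{doseRateGyPerH} set.
#' @return Dose in Gy.
#' @export
doseRateScanGy <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (is.na(protocol@doseRateGyPerH))
    stop("protocol has no dose rate; supply doseRateGyPerH")
  protocol@doseRateGyPerH * scanTimeS(protocol) / 3600
}

#' Tabulate a scan protocol
#'
#' One-row data.frame of all acquisition fields plus derived scan time
#' and magnification, suitable for plain-text or CSV output.
#'
#' @param protocol a \linkS4class{ScanProtocol}.
#' @return data.frame with one row.
#' @export
protocolTable <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  data.frame(
    n_projections = protocol@nProjections,
    averaging = protocol@averaging,
    fps = protocol@fps,
    binning = protocol@binning,
    tube_kv = protocol@tubeKv,
    tube_ua = protocol@tubeUa,
    sdd_mm = protocol@sddMm,
    sod_mm = protocol@sodMm,
    cu_filter_mm = protocol@cuFilterMm,
    dose_rate_gy_per_h = protocol@doseRateGyPerH,
    scan_time_s = scanTimeS(protocol),
    magnification = magnification(protocol))
}
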