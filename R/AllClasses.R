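#' @import methods
NULL

#' CTVolume: a reconstructed X-ray CT volume
#'
#' Container for a 3-D scalar intensity grid with physical voxel pitch.
#' The grid is indexed \code{(z, y, x)} with slice \code{z = 1} the topmost
#' slice of the pot. Values are unsigned 16-bit on input (0..65535), move to
#' a signed/real working range after normalization, and are unsigned 8-bit
#' (0..255) on export.
#'
#' @slot data 3-D numeric array, \code{dim = c(nz, ny, nx)}.
#' @slot pitch numeric(3), voxel pitch \code{(dz, dy, dx)} in mm; all > 0.
#'   The default acquisition geometry has isotropic 0.3 mm voxels.
#' @export
setClass("CTVolume", representation(data = "array", pitch = "numeric"))

setValidity("CTVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (z, y, x)")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@pitch) != 3L) return("pitch must have 3 components (dz, dy, dx)")
  if (any(!is.finite(object@pitch)) || any(object@pitch <= 0))
    return("voxel pitch components must be positive")
  TRUE
})

#' Construct a CTVolume
#'
#' @param data 3-D numeric array indexed (z, y, x).
#' @param pitch voxel pitch in mm; either a scalar (isotropic) or
#'   \code{c(dz, dy, dx)}. Default 0.3 mm isotropic.
#' @return A \linkS4class{CTVolume}.
#' @examples
#' vol <- CTVolume(array(0, c(4, 8, 8)))
#' dim(vol)
#' @export
CTVolume <- function(data, pitch = 0.3) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  new("CTVolume", data = data, pitch = as.numeric(pitch))
}

#' StackManifest: description of an on-disk slice stack
#'
#' Records how a CT volume is laid out as an ordered stack of 2-D grayscale
#' slice files. Files are always sorted lexicographically, so zero-padded
#' numeric filenames enumerate slices top-down.
#'
#' @slot directory character, directory holding the slice files.
#' @slot files character vector of file names in slice (z) order.
#' @slot format one of \code{"tiff"}, \code{"png"}, \code{"raw"}.
#' @slot width,height integer slice dimensions (x, y).
#' @slot bitDepth integer, 8 or 16.
#' @slot endian byte order for raw slices ("little" or "big").
#' @export
setClass("StackManifest", representation(
  directory = "character", files = "character", format = "character",
  width = "integer", height = "integer", bitDepth = "integer",
  endian = "character"))

setValidity("StackManifest", function(object) {
  if (!object@format %in% c("tiff", "png", "raw")) return("unsupported format tag")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  if (object@format == "raw" && !object@endian %in% c("little", "big"))
    return("raw format requires endian 'little' or 'big'")
  TRUE
})

#' BimodalModes: located air and soil histogram modes
#'
#' The grayscale histogram of a soil-filled pot scan is bimodal: the lower
#' mode comes from the air fraction, the higher from the soil fraction
#' (air absorbs less X-ray than calcined clay; roots sit in between).
#'
#' @slot mAir intensity of the air-fraction mode.
#' @slot mSoil intensity of the soil-fraction mode; must exceed \code{mAir}.
#' @export
setClass("BimodalModes", representation(mAir = "numeric", mSoil = "numeric"))

setValidity("BimodalModes", function(object) {
  if (length(object@mAir) != 1L || length(object@mSoil) != 1L)
    return("modes must be scalars")
  if (!is.finite(object@mAir) || !is.finite(object@mSoil))
    return("modes must be finite")
  if (object@mAir >= object@mSoil) return("air mode must lie below soil mode")
  TRUE
})

#' Construct BimodalModes
#'
#' @param mAir,mSoil intensities of the air and soil histogram modes.
#' @return A \linkS4class{BimodalModes}.
#' @export
bimodalModes <- function(mAir, mSoil) new("BimodalModes", mAir = mAir, mSoil = mSoil)

#' @describeIn bimodalModes separation between the two modes.
#' @param object a \code{BimodalModes}.
#' @export
modeSeparation <- function(object) object@mSoil - object@mAir

#' PipelineConfig: tunables of the root-segmentation chain
#'
#' All tunables of the processing chain: 3-D median kernel, 2-D blur kernel
#' for edge detection, optional threshold plus 3-D size opening, cylindrical
#' crop, and 8-bit export mode.
#'
#' @slot kMed odd 3-D median kernel edge in voxels (default 7).
#' @slot kBlur odd 2-D mean-blur kernel edge in pixels (default 21).
#' @slot threshold intensity threshold on the working scale; \code{NA}
#'   disables thresholding/size opening (the default: small non-root
#'   segments are kept rather than risking erasure of fine young roots).
#' @slot minSize minimum connected-component voxel count kept by size
#'   opening; \code{NA} disables.
#' @slot connectivity 6, 18 or 26 (default 26 so thin diagonal root
#'   fragments are not split).
#' @slot cropDiameterMm,cropHeightMm cylinder kept around the slice centre,
#'   measured from the top slice (defaults 180 and 250 mm, the standard
#'   20 cm pot trimmed inside its wall); \code{NA} disables cropping.
#' @slot exportMode \code{"clip"} (default; preserves absolute edge
#'   magnitudes across time points) or \code{"rescale"} (display).
#' @export
setClass("PipelineConfig", representation(
  kMed = "integer", kBlur = "integer", threshold = "numeric",
  minSize = "numeric", connectivity = "integer",
  cropDiameterMm = "numeric", cropHeightMm = "numeric",
  exportMode = "character"))

setValidity("PipelineConfig", function(object) {
  if (object@kMed < 1L || object@kMed %% 2L == 0L) return("kMed must be odd and >= 1")
  if (object@kBlur < 1L || object@kBlur %% 2L == 0L) return("kBlur must be odd and >= 1")
  if (!is.na(object@minSize) && object@minSize < 1) return("minSize must be >= 1")
  if (!object@connectivity %in% c(6L, 18L, 26L)) return("connectivity must be 6, 18 or 26")
  if (!is.na(object@cropDiameterMm) && object@cropDiameterMm <= 0)
    return("crop diameter must be > 0")
  if (!is.na(object@cropHeightMm) && object@cropHeightMm <= 0)
    return("crop height must be > 0")
  if (!object@exportMode %in% c("clip", "rescale"))
    return("exportMode must be 'clip' or 'rescale'")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param kMed,kBlur,threshold,minSize,connectivity,cropDiameterMm,cropHeightMm,exportMode
#'   see \linkS4class{PipelineConfig}.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' pipelineConfig()                      # the standard chain
#' pipelineConfig(threshold = 10, minSize = 50)  # with size opening
#' @export
pipelineConfig <- function(kMed = 7L, kBlur = 21L, threshold = NA_real_,
                           minSize = NA_real_, connectivity = 26L,
                           cropDiameterMm = 180, cropHeightMm = 250,
                           exportMode = "clip") {
  new("PipelineConfig", kMed = as.integer(kMed), kBlur = as.integer(kBlur),
      threshold = as.numeric(threshold), minSize = as.numeric(minSize),
      connectivity = as.integer(connectivity),
      cropDiameterMm = as.numeric(cropDiameterMm),
      cropHeightMm = as.numeric(cropHeightMm), exportMode = exportMode)
}

#' PhantomConfig: parameters of the synthetic CT phantom
#'
#' Describes a synthetic micro-CT volume of a fibrous root system growing
#' in granular soil inside a cylindrical pot. Intensities live on the
#' unsigned 16-bit scale of reconstructed scans.
#'
#' @slot dim integer(3) grid dimensions \code{(nz, ny, nx)}.
#' @slot pitch voxel pitch in mm (isotropic).
#' @slot soilMean,soilSd mean and standard deviation of the soil fraction.
#' @slot airMean mean intensity of the air fraction.
#' @slot granularityMm spatial correlation length of the soil texture.
#' @slot scanNoiseSd standard deviation of the white reconstruction/photon
#'   noise added on top of the granular texture (16-bit scale).
#' @slot rootContrast fractional intensity deficit of pure root tissue
#'   relative to soil (0 < c < 1); a voxel fully inside a root has
#'   expected intensity \code{soilMean - rootContrast * soilMean}.
#' @slot psfSigmaMm Gaussian sigma (mm) of the scanner/reconstruction
#'   point-spread function applied to the attenuation-deficit field
#'   (roots, voids, cracks); 0 disables it.
#' @slot nRoots number of radicle/crown roots.
#' @slot archetype \code{"deep"}, \code{"shallow"} or \code{"intermediate"}
#'   root-system architecture.
#' @slot diameterRange root diameters are drawn uniformly from this range
#'   (mm) unless \code{rootDiameters} is given.
#' @slot rootDiameters optional explicit per-root diameters (recycled).
#' @slot includeVoids,includeCracks,potWall toggles for soil voids, near-
#'   surface cracks, and the bright pot-wall annulus.
#' @slot seed integer seed; identical seeds give bit-identical phantoms.
#' @export
setClass("PhantomConfig", representation(
  dim = "integer", pitch = "numeric", soilMean = "numeric", soilSd = "numeric",
  airMean = "numeric", granularityMm = "numeric", scanNoiseSd = "numeric",
  rootContrast = "numeric", psfSigmaMm = "numeric",
  nRoots = "integer", archetype = "character", diameterRange = "numeric",
  rootDiameters = "numeric", includeVoids = "logical", includeCracks = "logical",
  potWall = "logical", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 8L))
    return("dim must be 3 values, each >= 8")
  if (object@pitch <= 0) return("voxel pitch must be > 0")
  if (object@soilMean <= object@airMean) return("soilMean must exceed airMean")
  if (object@rootContrast <= 0 || object@rootContrast >= 1)
    return("rootContrast must lie strictly between 0 and 1")
  if (object@psfSigmaMm < 0) return("psfSigmaMm must be >= 0")
  if (object@scanNoiseSd < 0) return("scanNoiseSd must be >= 0")
  if (object@soilSd < 0) return("soilSd must be >= 0")
  if (object@nRoots < 0L) return("nRoots must be >= 0")
  if (!object@archetype %in% c("deep", "shallow", "intermediate"))
    return("archetype must be deep, shallow or intermediate")
  TRUE
})

#' RootSystemTruth: ground-truth root geometry of a phantom
#'
#' @slot roots list; each element has \code{centerline} (n x 3 matrix of
#'   (x, y, z) mm coordinates, z measured down from the top slice),
#'   \code{diameter} (mm) and \code{class} ("radicle" or "crown").
#' @slot archetype architecture label the roots were drawn from.
#' @slot potRadiusMm inner soil radius used when growing the roots.
#' @slot soilTopMm depth of the soil surface below the top slice.
#' @slot seed generating seed.
#' @export
setClass("RootSystemTruth", representation(
  roots = "list", archetype = "character", potRadiusMm = "numeric",
  soilTopMm = "numeric", seed = "integer"))

#' ScanProtocol: CT acquisition parameters
#'
#' Bookkeeping for scan-time, geometry and dose arithmetic. The dose rate
#' is an external input (e.g. from a dose calculator); no dose physics is
#' computed from tube settings.
#'
#' @slot nProjections projections per 360 degree rotation.
#' @slot averaging frames averaged per projection.
#' @slot fps detector frames per second.
#' @slot binning "none" or "3x3".
#' @slot tubeKv,tubeUa tube voltage (kV) and current (uA).
#' @slot sddMm,sodMm source-detector and source-rotation-axis distances.
#' @slot cuFilterMm copper filter thickness (mm).
#' @slot doseRateGyPerH dose rate at the rotation axis (Gy/h), externally
#'   supplied; \code{NA} if unknown.
#' @export
setClass("ScanProtocol", representation(
  nProjections = "integer", averaging = "integer", fps = "numeric",
  binning = "character", tubeKv = "numeric", tubeUa = "numeric",
  sddMm = "numeric", sodMm = "numeric", cuFilterMm = "numeric",
  doseRateGyPerH = "numeric"))

setValidity("ScanProtocol", function(object) {
  if (object@nProjections < 1L) return("nProjections must be >= 1")
  if (object@averaging < 1L) return("averaging must be >= 1")
  if (!is.finite(object@fps) || object@fps <= 0) return("fps must be > 0")
  if (!object@binning %in% c("none", "3x3")) return("binning must be 'none' or '3x3'")
  if (object@sodMm <= 0 || object@sddMm <= object@sodMm)
    return("need 0 < sodMm < sddMm")
  if (!is.na(object@doseRateGyPerH) && object@doseRateGyPerH < 0)
    return("dose rate must be >= 0")
  TRUE
})

#' Construct a ScanProtocol
#'
#' Defaults are the standard 10-minute acquisition: 1200 projections,
#' two-frame signal averaging, 4.0 fps, no binning, 225 kV / 500 uA,
#' source-detector 1200 mm, source-rotation-axis 900 mm, 1.0 mm Cu filter.
#'
#' @param nProjections,averaging,fps,binning,tubeKv,tubeUa,sddMm,sodMm,cuFilterMm,doseRateGyPerH
#'   see \linkS4class{ScanProtocol}.
#' @return A \linkS4class{ScanProtocol}.
#' @examples
#' scanTimeS(scanProtocol())                                   # 600 s
#' scanTimeS(scanProtocol(600, 1, 18, binning = "3x3"))        # 33 s
#' @export
scanProtocol <- function(nProjections = 1200L, averaging = 2L, fps = 4.0,
                         binning = "none", tubeKv = 225, tubeUa = 500,
                         sddMm = 1200, sodMm = 900, cuFilterMm = 1.0,
                         doseRateGyPerH = NA_real_) {
  new("ScanProtocol", nProjections = as.integer(nProjections),
      averaging = as.integer(averaging), fps = as.numeric(fps),
      binning = binning, tubeKv = tubeKv, tubeUa = tubeUa,
      sddMm = sddMm, sodMm = sodMm, cuFilterMm = cuFilterMm,
      doseRateGyPerH = as.numeric(doseRateGyPerH))
}

#' DetectionReport: per-root detection calls against ground truth
#'
#' @slot perRoot data.frame with columns \code{id}, \code{class},
#'   \code{diameter_mm}, \code{coverage}, \code{detected}.
#' @slot nDetected,nUndetected counts; their sum is the number of roots.
#' @slot percentDetected,percentUndetected percentages of the total;
#'   they sum to exactly 100.
#' @export
setClass("DetectionReport", representation(
  perRoot = "data.frame", nDetected = "integer", nUndetected = "integer",
  percentDetected = "numeric", percentUndetected = "numeric"))

setValidity("DetectionReport", function(object) {
  if (object@nDetected < 0L || object@nUndetected < 0L) return("negative counts")
  if (nrow(object@perRoot) > 0L &&
      object@nDetected + object@nUndetected != nrow(object@perRoot))
    return("counts must sum to the number of roots")
  TRUE
})
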