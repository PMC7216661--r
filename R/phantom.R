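## Seeded synthetic CT phantoms of fibrous root systems in granular soil.
## The generator emulates the statistical structure the segmentation chain
## assumes: a bimodal air/soil histogram, roots darker than calcined clay,
## spatially correlated soil texture, partial-volume attenuation of
## sub-voxel roots, voids, near-surface cracks and a bright pot wall.

#' Construct a PhantomConfig
#'
#' Defaults describe the standard test phantom: a 128^3 grid at the
#' scanner's 0.3 mm voxel pitch, soil and air modes at 22000 and 8000 on
#' the 16-bit scale, correlated soil texture with 0.6 mm correlation
#' length, and roots spanning the 0.2-1.2 mm diameter regime of rice
#' radicles and crown roots.
#'
#' @param dim,pitch,soilMean,soilSd,airMean,granularityMm,scanNoiseSd,rootContrast,psfSigmaMm,nRoots,archetype,diameterRange,rootDiameters,includeVoids,includeCracks,potWall,seed
#'   see \linkS4class{PhantomConfig}.
#' @return A \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(dim = c(128L, 128L, 128L), pitch = 0.3,
                          soilMean = 22000, soilSd = 1, airMean = 8000,
                          granularityMm = 0.6, scanNoiseSd = 5,
                          rootContrast = 0.5, psfSigmaMm = 0.25,
                          nRoots = 12L, archetype = "intermediate",
                          diameterRange = c(0.2, 1.2),
                          rootDiameters = numeric(0),
                          includeVoids = TRUE, includeCracks = TRUE,
                          potWall = TRUE, seed = 1L) {
  new("PhantomConfig", dim = as.integer(dim), pitch = pitch,
      soilMean = soilMean, soilSd = soilSd, airMean = airMean,
      granularityMm = granularityMm, scanNoiseSd = scanNoiseSd,
      rootContrast = rootContrast, psfSigmaMm = psfSigmaMm,
      nRoots = as.integer(nRoots), archetype = archetype,
      diameterRange = diameterRange, rootDiameters = rootDiameters,
      includeVoids = includeVoids, includeCracks = includeCracks,
      potWall = potWall, seed = as.integer(seed))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pot geometry shared by the generator and the renderer.
pot_geometry <- function(config) {
  ext <- config@dim * config@pitch  # (z, y, x) mm
  list(ext = ext,
       potRadiusMm = 0.47 * min(ext[2], ext[3]),
       wallThickMm = 1.0,
       # slice 1 is the soil surface: reconstructions of the potted column
       # start at the ground line, so no in-pot air band is rendered
       soilTopMm = 0)
}

#' Generate a ground-truth root system
#'
#' Grows \code{nRoots} piecewise-linear root paths from a crown point at
#' the pot center near the soil surface. The initial polar angle from the
#' vertical is drawn per architecture archetype (deep: steep; shallow:
#' near-horizontal; intermediate: between), each subsequent segment adds a
#' small random angular perturbation, and paths reflect inward off the pot
#' wall and bottom. Root diameters are drawn uniformly from
#' \code{diameterRange} unless \code{rootDiameters} is given (recycled).
#' The first root is labelled "radicle", the rest "crown". Reproducible
#' given the config seed.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{RootSystemTruth}.
#' @export
generateRootSystem <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  geo <- pot_geometry(config)
  n <- config@nRoots
  with_seed(config@seed, {
    diameters <- if (length(config@rootDiameters)) {
      rep_len(config@rootDiameters, max(n, 1L))
    } else {
      stats::runif(max(n, 1L), config@diameterRange[1], config@diameterRange[2])
    }
    roots <- vector("list", n)
    if (n > 0L) for (i in seq_len(n)) {
      roots[[i]] <- grow_root_path(i, n, diameters[[i]], config, geo)
    }
  })
  new("RootSystemTruth", roots = roots, archetype = config@archetype,
      potRadiusMm = geo$potRadiusMm, soilTopMm = geo$soilTopMm,
      seed = config@seed)
}

grow_root_path <- function(i, n, diameter, config, geo) {
  theta_deg <- switch(config@archetype,
    deep = stats::runif(1, 5, 25),
    shallow = stats::runif(1, 65, 85),
    intermediate = stats::runif(1, 35, 55))
  phi <- 2 * pi * (i - 1) / n + stats::runif(1, 0, 2 * pi / n)
  theta <- theta_deg * pi / 180
  dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  cx <- geo$ext[3] / 2; cy <- geo$ext[2] / 2
  depth_budget <- geo$ext[1] - geo$soilTopMm
  total_len <- stats::runif(1, 0.7, 0.95) * depth_budget
  step <- 1.2  # mm per segment
  n_seg <- max(3L, ceiling(total_len / step))
  # roots keep one median-kernel width of clearance from the wall: the
  # processing chain crops wall-touching roots away by design, so the
  # phantom grows its roots inside the retained cylinder
  margin <- diameter / 2 + 1.5
  r_max <- geo$potRadiusMm - geo$wallThickMm - margin
  z_min <- geo$soilTopMm + 0.5
  z_max <- geo$ext[1] - margin
  pts <- matrix(0, n_seg + 1L, 3L)  # columns x, y, z (mm)
  pts[1L, ] <- c(cx, cy, z_min + 0.1)
  for (s in seq_len(n_seg)) {
    dir <- dir + 0.12 * stats::rnorm(3)
    dir[3] <- dir[3] + 0.02  # slight gravitropism
    dir <- dir / sqrt(sum(dir^2))
    cand <- pts[s, ] + step * dir
    # reflect off the soil surface and pot bottom
    if (cand[3] < z_min) { cand[3] <- 2 * z_min - cand[3]; dir[3] <- -dir[3] }
    if (cand[3] > z_max) { cand[3] <- 2 * z_max - cand[3]; dir[3] <- -dir[3] }
    # reflect inward off the pot wall
    rad <- sqrt((cand[1] - cx)^2 + (cand[2] - cy)^2)
    if (rad > r_max) {
      u <- c(cand[1] - cx, cand[2] - cy) / rad
      over <- rad - r_max
      cand[1:2] <- cand[1:2] - 2 * over * u
      dr <- sum(dir[1:2] * u)
      dir[1:2] <- dir[1:2] - 2 * dr * u
    }
    pts[s + 1L, ] <- cand
  }
  colnames(pts) <- c("x", "y", "z")
  list(centerline = pts, diameter = diameter,
       class = if (i == 1L) "radicle" else "crown")
}

#' Voxel volume fractions of a union of tube segments
#'
#' Estimates, for every voxel, the fraction of its volume occupied by a
#' union of capsules (cylindrical segments with hemispherical caps) by
#' counting covered subvoxel centers on an \code{ss^3} grid. This is the
#' partial-volume model: a root thinner than a voxel only fractionally
#' darkens it, which is what limits detectability of sub-voxel roots.
#'
#' @param segments numeric matrix, one row per segment:
#'   \code{(x0, y0, z0, x1, y1, z1, radius)} in voxel units.
#' @param dim integer(3) grid dimensions \code{(nz, ny, nx)}.
#' @param ss supersampling factor per axis (default 3; absolute error of a
#'   single voxel fraction is about 1/(2 ss) near the tube surface).
#' @return Numeric array \code{dim = c(nz, ny, nx)} of fractions in [0, 1].
#' @export
tubeVoxelFractions <- function(segments, dim, ss = 3L) {
  stopifnot(is.matrix(segments), ncol(segments) == 7L)
  array(tube_fractions_cpp(segments, as.integer(dim), as.integer(ss)),
        as.integer(dim))
}

root_segments_vox <- function(truth, config, length_scale = 1,
                              diameter_scale = 1) {
  segs <- lapply(truth@roots, function(r) {
    pts <- clip_polyline(r$centerline, length_scale)
    if (nrow(pts) < 2L) return(NULL)
    k <- nrow(pts) - 1L
    cbind(pts[seq_len(k), 1], pts[seq_len(k), 2], pts[seq_len(k), 3],
          pts[seq_len(k) + 1L, 1], pts[seq_len(k) + 1L, 2],
          pts[seq_len(k) + 1L, 3],
          rep(r$diameter * diameter_scale / 2, k)) / config@pitch
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0L) return(matrix(0, 0L, 7L))
  do.call(rbind, segs)
}

# Truncate a polyline to the given fraction of its arc length.
clip_polyline <- function(pts, fraction) {
  if (fraction >= 1) return(pts)
  seg_len <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
  target <- fraction * sum(seg_len)
  if (target <= 0) return(pts[1L, , drop = FALSE])
  cum <- cumsum(seg_len)
  last <- which(cum >= target)[1L]
  excess <- cum[last] - target
  t <- 1 - excess / seg_len[last]
  end <- pts[last, ] + t * (pts[last + 1L, ] - pts[last, ])
  rbind(pts[seq_len(last), , drop = FALSE], end)
}

# Periodic FFT convolution with a normalized (sum 1) Gaussian kernel;
# models the scanner/reconstruction point-spread function.
gaussian_blur3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  kern <- lapply(d, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-x^2 / (2 * sigma_vox^2))
  })
  k3 <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  k3 <- k3 / sum(k3)
  Re(fft(fft(arr) * fft(k3), inverse = TRUE)) / prod(d)
}

# Gaussian-correlated unit-variance random field via FFT.
correlated_field <- function(d, sigma_vox) {
  white <- array(stats::rnorm(prod(d)), d)
  if (sigma_vox <= 0) return(white)
  kern <- lapply(d, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # periodic distances
    exp(-x^2 / (2 * sigma_vox^2))
  })
  k3 <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  sm <- Re(fft(fft(white) * fft(k3), inverse = TRUE)) / prod(d)
  sm / sqrt(mean(sm^2))  # rescale to unit variance
}

#' Render a phantom CT volume from ground truth
#'
#' Builds the 16-bit volume: a correlated-noise soil field, air above the
#' soil surface and outside the pot, an optional bright pot-wall annulus,
#' roots darkened by \code{rootContrast * soilMean * f} where \code{f} is
#' the voxel's root volume fraction (subvoxel supersampling; this is the
#' partial-volume effect that makes sub-voxel roots faint), plus optional
#' darker spherical voids and near-surface cracks. The combined
#' attenuation-deficit field is spread by a Gaussian point-spread
#' function (\code{psfSigmaMm}) before meeting the noise, as the
#' scanner's reconstruction does; the granular noise itself is
#' post-reconstruction texture and is not blurred. Bit-identical for
#' identical seeds.
#'
#' @param truth a \linkS4class{RootSystemTruth} (from
#'   \code{\link{generateRootSystem}}).
#' @param config the \linkS4class{PhantomConfig} used to generate it.
#' @param ss supersampling factor for volume fractions.
#' @param lengthScale,diameterScale scale factors applied to root length
#'   and diameter (used by the time-series generator).
#' @param noiseSeed optional seed override for the scan-noise draw.
#' @return A list: \code{volume} (\linkS4class{CTVolume}, 16-bit),
#'   \code{mask} (logical array, voxels with root fraction >= 0.5),
#'   \code{centerlines} (per-root integer matrices of (z, y, x) voxel
#'   indices traversed by the centerline), \code{fractions} (the root
#'   volume-fraction array).
#' @export
renderVolume <- function(truth, config, ss = 3L, lengthScale = 1,
                         diameterScale = 1, noiseSeed = NULL) {
  stopifnot(is(truth, "RootSystemTruth"), is(config, "PhantomConfig"))
  d <- config@dim
  geo <- pot_geometry(config)
  if (is.null(noiseSeed)) noiseSeed <- config@seed
  segs <- root_segments_vox(truth, config, lengthScale, diameterScale)
  frac <- if (nrow(segs)) tubeVoxelFractions(segs, d, ss) else array(0, d)
  vol <- with_seed(noiseSeed + 1L, {
    g <- correlated_field(d, config@granularityMm / config@pitch)
    # voxel-center coordinates (mm)
    zc <- (seq_len(d[1]) - 0.5) * config@pitch
    yc <- (seq_len(d[2]) - 0.5) * config@pitch - geo$ext[2] / 2
    xc <- (seq_len(d[3]) - 0.5) * config@pitch - geo$ext[3] / 2
    r_yx <- sqrt(outer(yc^2, xc^2, "+"))
    r3 <- aperm(array(r_yx, c(d[2], d[3], d[1])), c(3, 1, 2))
    above <- array(zc < geo$soilTopMm, d)
    soil_r <- geo$potRadiusMm - geo$wallThickMm
    in_soil <- r3 <= soil_r & !above
    in_wall <- r3 > soil_r & r3 <= geo$potRadiusMm
    v <- array(config@airMean, d) + 0.25 * config@soilSd * g
    v[in_soil] <- config@soilMean + config@soilSd * g[in_soil]
    if (config@potWall) {
      v[in_wall] <- pmin(1.45 * config@soilMean, 60000) +
        0.5 * config@soilSd * g[in_wall]
    } else {
      v[in_wall] <- config@soilMean + config@soilSd * g[in_wall]
    }
    # attenuation deficit of everything less dense than soil (roots,
    # voids, cracks); spread by the reconstruction point-spread function
    # before it meets the noise field
    deficit <- config@rootContrast * config@soilMean * frac
    if (config@includeVoids) {
      n_void <- max(1L, round(8 * prod(d) / 128^3))
      vr <- stats::runif(n_void, 0.5, 1.2)
      vrad <- stats::runif(n_void, 0, max(0.5, 0.8 * soil_r - max(vr)))
      vphi <- stats::runif(n_void, 0, 2 * pi)
      vz <- stats::runif(n_void, geo$soilTopMm + max(vr),
                         geo$ext[1] - max(vr))
      vox <- cbind(geo$ext[3] / 2 + vrad * cos(vphi),
                   geo$ext[2] / 2 + vrad * sin(vphi), vz,
                   geo$ext[3] / 2 + vrad * cos(vphi),
                   geo$ext[2] / 2 + vrad * sin(vphi), vz, vr) / config@pitch
      fv <- tubeVoxelFractions(vox, d, ss)
      deficit <- deficit + 0.35 * config@soilMean * fv
    }
    if (config@includeCracks) {
      n_crack <- 2L
      cphi <- stats::runif(n_crack, 0, 2 * pi)
      clen <- stats::runif(n_crack, 4, 8)
      cz <- geo$soilTopMm + stats::runif(n_crack, 0.5, 2.5)
      cx0 <- geo$ext[3] / 2 + stats::runif(n_crack, -4, 4)
      cy0 <- geo$ext[2] / 2 + stats::runif(n_crack, -4, 4)
      cseg <- cbind(cx0, cy0, cz,
                    cx0 + clen * cos(cphi), cy0 + clen * sin(cphi),
                    cz + stats::runif(n_crack, -0.5, 0.5),
                    rep(0.3, n_crack)) / config@pitch
      fc <- tubeVoxelFractions(cseg, d, ss)
      deficit <- deficit + 0.3 * config@soilMean * fc
    }
    if (any(deficit > 0)) {
      deficit <- gaussian_blur3d(deficit, config@psfSigmaMm / config@pitch)
    }
    v <- v - deficit
    # reconstruction/photon noise of rapid scanning: white at voxel scale,
    # on top of the correlated granular texture
    if (config@scanNoiseSd > 0) {
      v <- v + config@scanNoiseSd * stats::rnorm(length(v))
    }
    v[v < 0] <- 0
    v[v > 65535] <- 65535
    round(v)
  })
  list(volume = CTVolume(vol, config@pitch),
       mask = frac >= 0.5,
       centerlines = centerline_voxels(truth, config, lengthScale),
       fractions = frac)
}

# Voxel indices (z, y, x; 1-based) traversed by each root centerline.
centerline_voxels <- function(truth, config, length_scale = 1) {
  d <- config@dim
  lapply(truth@roots, function(r) {
    pts <- clip_polyline(r$centerline, length_scale)
    dense <- densify_polyline(pts, config@pitch / 3)
    iz <- floor(dense[, 3] / config@pitch) + 1L
    iy <- floor(dense[, 2] / config@pitch) + 1L
    ix <- floor(dense[, 1] / config@pitch) + 1L
    ok <- iz >= 1L & iz <= d[1] & iy >= 1L & iy <= d[2] & ix >= 1L & ix <= d[3]
    unique(cbind(z = iz[ok], y = iy[ok], x = ix[ok]))
  })
}

densify_polyline <- function(pts, step) {
  if (nrow(pts) < 2L) return(pts)
  out <- list()
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    out[[s]] <- if (s > 1L) seg[-1L, , drop = FALSE] else seg
  }
  do.call(rbind, out)
}

#' Render a 4-D growth time series
#'
#' Day \code{t} renders each root truncated to the fraction
#' \code{t / nDays} of its full arc length, with diameters scaled by
#' \code{0.6 + 0.4 t / nDays}, so root geometry is nested over time.
#' Scan noise is re-drawn independently each day (same soil realization a
#' scanner would see is not reproducible between scans); root geometry is
#' shared. \code{nDays = 1} renders the fully grown system and equals
#' \code{\link{renderVolume}}.
#'
#' @param truth a \linkS4class{RootSystemTruth}.
#' @param config the matching \linkS4class{PhantomConfig}.
#' @param nDays number of daily scans (>= 1).
#' @param ss supersampling factor.
#' @return List of \code{nDays} render results (see
#'   \code{\link{renderVolume}}).
#' @export
growTimeSeries <- function(truth, config, nDays, ss = 3L) {
  stopifnot(nDays >= 1L)
  lapply(seq_len(nDays), function(t) {
    renderVolume(truth, config, ss = ss,
                 lengthScale = t / nDays,
                 diameterScale = 0.6 + 0.4 * t / nDays,
                 noiseSeed = config@seed + 7919L * (t - 1L))
  })
}

#' Ground-truth region masks of a rendered phantom
#'
#' Builds disjoint root and soil masks for CNR evaluation: the root mask
#' is voxels with root volume fraction >= 0.5; the soil mask is soil-
#' interior voxels (inside the pot, below the soil surface, away from the
#' wall) at least \code{clearanceVox} voxels away from any root tissue.
#'
#' @param render result of \code{\link{renderVolume}}.
#' @param config the \linkS4class{PhantomConfig}.
#' @param clearanceVox Chebyshev clearance (voxels) between the soil mask
#'   and any voxel with nonzero root fraction (default 8: kernel radius
#'   plus point-spread reach, so filtered root tails do not leak into
#'   the soil reference region).
#' @return list with logical arrays \code{root} and \code{soil}.
#' @export
phantomMasks <- function(render, config, clearanceVox = 8L) {
  d <- config@dim
  geo <- pot_geometry(config)
  zc <- (seq_len(d[1]) - 0.5) * config@pitch
  yc <- (seq_len(d[2]) - 0.5) * config@pitch - geo$ext[2] / 2
  xc <- (seq_len(d[3]) - 0.5) * config@pitch - geo$ext[3] / 2
  r_yx <- sqrt(outer(yc^2, xc^2, "+"))
  r3 <- aperm(array(r_yx, c(d[2], d[3], d[1])), c(3, 1, 2))
  interior <- r3 <= (geo$potRadiusMm - geo$wallThickMm - 1) &
    array(zc > geo$soilTopMm + 1, d)
  near_root <- dilate_box(render$fractions > 0, as.integer(clearanceVox))
  list(root = render$mask, soil = interior & !near_root)
}
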