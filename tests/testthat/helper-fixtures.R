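# Small volumes and phantoms used across the suite. Everything is built
# in code; nothing is read from disk except what a test itself writes.

tiny_volume <- function(d = c(3L, 4L, 4L), value = 0, pitch = 0.3) {
  CTVolume(array(value, d), pitch)
}

random_volume <- function(d, seed, lo = 0, hi = 65535, pitch = 0.3) {
  set.seed(seed)
  CTVolume(array(round(runif(prod(d), lo, hi)), d), pitch)
}

# A small soil-filled phantom configuration that keeps test runtimes low.
small_phantom_config <- function(...) {
  defaults <- list(dim = c(48L, 48L, 48L), nRoots = 4L, rootDiameters = 1.0,
                   archetype = "deep", includeVoids = FALSE,
                   includeCracks = FALSE, seed = 7L)
  do.call(phantomConfig, utils::modifyList(defaults, list(...)))
}

# Pipeline configuration whose crop cylinder fits a phantom's pot: the
# cylinder sits just inside the pot wall, as in the real protocol where
# an 18 cm cylinder is trimmed out of a 20 cm pot.
phantom_pipeline_config <- function(cfg, ...) {
  ext <- cfg@dim * cfg@pitch
  pot_r <- 0.47 * min(ext[2], ext[3])
  pipelineConfig(cropDiameterMm = 2 * (pot_r - 2), cropHeightMm = ext[1] - 0.3,
                 ...)
}

# Mask of voxels inside a crop cylinder (same geometry as cropCylinder).
crop_interior_mask <- function(vol, diameterMm, heightMm) {
  d <- dim(vol)
  p <- voxelPitch(vol)
  ext <- d * p
  yc <- (seq_len(d[2]) - 0.5) * p[2] - ext[2] / 2
  xc <- (seq_len(d[3]) - 0.5) * p[3] - ext[3] / 2
  inxy <- outer(yc^2, xc^2, "+") <= (diameterMm / 2)^2
  zc <- (seq_len(d[1]) - 0.5) * p[1]
  aperm(array(inxy, c(d[2], d[3], d[1])), c(3, 1, 2)) &
    array(zc <= heightMm, d)
}

# Brute-force flood fill (R implementation, independent of the C++ one).
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  deg <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[deg > 0 & deg <= switch(as.character(connectivity),
                                       "6" = 1L, "18" = 2L, "26" = 3L), ]
  labels <- array(0L, d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || labels[z, y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(z, y, x))
    labels[z, y, x] <- nxt
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        nz <- cur[1] + offs$dz[o]; ny <- cur[2] + offs$dy[o]
        nx <- cur[3] + offs$dx[o]
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] || nx < 1 || nx > d[3])
          next
        if (mask[nz, ny, nx] && labels[nz, ny, nx] == 0L) {
          labels[nz, ny, nx] <- nxt
          queue[[length(queue) + 1L]] <- c(nz, ny, nx)
        }
      }
    }
  }
  labels
}
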