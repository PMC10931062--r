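# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive per-pixel / per-slice recomputation so they share
# no code path with the optimized implementations they check.

# Compact acquisition grid for algebraic / equivalence tests where the
# physical protocol does not matter: 6 x 6 mm FOV, 25 B-scans at 250 um
# (supports decimation factors 1, 2, 4, 8), 96 A-scans (62.5 um pitch),
# 64 depth samples at 14 um.
smallGeometry <- function(nBscans = 25L, isd = 250) {
  scanGeometryNew(isd = isd, nBscans = nBscans, nAscans = 96L,
                  nDepth = 64L, depthScale = 14)
}

smallAmdConfig <- function(nEyes, seed, preset = amdPreset()) {
  cohortConfig(nEyes, preset, geometry = smallGeometry(), seed = seed)
}

# an empty (all-background) volume on a given geometry
emptyVolume <- function(g = smallGeometry(), eyeId = "empty",
                        laterality = "right") {
  segVolumeNew(array(0L, c(g@nBscans, g@nDepth, g@nAscans)), g,
               eyeId = eyeId, laterality = laterality)
}

# volume with given voxels set: vox is a matrix with columns b, d, a
# (0-based) and a label code
volumeWithVoxels <- function(vox, code, g = smallGeometry(), ...) {
  v <- emptyVolume(g, ...)
  lab <- v@labels
  for (r in seq_len(nrow(vox)))
    lab[vox[r, 1L] + 1L, vox[r, 2L] + 1L, vox[r, 3L] + 1L] <- code
  segVolumeNew(lab, g, eyeId = v@eyeId, laterality = v@laterality)
}

# uniform slab of `thickVox` retina voxels in every column, starting at
# depth index d0 (0-based)
slabVolume <- function(g, thickVox, d0 = 10L, code = 1L) {
  lab <- array(0L, c(g@nBscans, g@nDepth, g@nAscans))
  lab[, d0 + seq_len(thickVox), ] <- code
  segVolumeNew(lab, g, eyeId = "slab", laterality = "right")
}

# Brute-force FOV sensitivity oracle: for every crop size, re-scan every
# pixel of every map against the closed crop rectangle.
oracleSensitivityMap <- function(maps, stepUm = 250) {
  g <- maps[[1L]]@geometry
  xs <- ascanPositionsUm(g)
  ys <- bscanPositionsUm(g)
  cx <- g@fovX / 2
  cy <- g@fovY / 2
  sizesX <- seq(stepUm, g@fovX, by = stepUm)
  sizesY <- seq(stepUm, g@fovY, by = stepUm)
  pos <- Filter(function(m) any(m@presence == 1L), maps)
  out <- matrix(0, length(sizesY), length(sizesX))
  for (iy in seq_along(sizesY)) {
    for (ix in seq_along(sizesX)) {
      # mask of pixels inside this crop, then re-scan every map against it
      inside <- outer(abs(ys - cy) <= sizesY[iy] / 2,
                      abs(xs - cx) <= sizesX[ix] / 2, `&`)
      hit <- 0L
      for (m in pos)
        hit <- hit + any(m@presence == 1L & inside)
      out[iy, ix] <- hit / length(pos)
    }
  }
  dimnames(out) <- list(sizeY_um = sizesY, sizeX_um = sizesX)
  out
}

# Brute-force ISD oracle: explicitly decimate the label array, then count
# voxels slice by slice with plain loops.
oracleIsdEye <- function(v, biomarker, factor) {
  codes <- switch(biomarker,
                  IRF = 2L, SRF = 3L, IRF_SRF = c(2L, 3L), PED = 4L,
                  retina = c(1L, 2L, 3L))
  g <- v@geometry
  kept <- seq(1L, g@nBscans, by = factor)
  isd <- g@isd * factor
  nKept <- length(kept)
  vol <- 0
  present <- FALSE
  for (j in seq_len(nKept)) {
    cnt <- sum(v@labels[kept[j], , ] %in% codes)
    if (cnt > 0L) present <- TRUE
    w <- if (j == 1L || j == nKept) isd / 2 else isd
    vol <- vol + cnt * (g@fovX / g@nAscans) * g@depthScale * w
  }
  list(present = present, volume = vol)
}

# exact Clopper-Pearson interval
binomCI <- function(x, n, level) {
  as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
}
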