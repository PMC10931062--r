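## Synthetic cohorts: layered retina phantom (ILM / Bruch's membrane
## surfaces with a central foveal depression) plus ellipsoidal fluid lesions
## whose en-face centers follow a fovea-centered isotropic Gaussian,
## truncated to the field of view. Only label geometry is emulated; there is
## no intensity/speckle realism because every downstream stage consumes
## labels only.

#' Disease presets for the synthetic generator
#'
#' `amdPreset()` encodes the exudative-AMD biomarker statistics the analysis
#' assumes: presence probabilities IRF 0.25, SRF 0.55, PED 0.90 and an
#' 800 um population spread of lesion centers about the fovea.
#' `rvoPreset()` encodes the RVO pattern: IRF 1.0, SRF 0.42, PED 0.0, with a
#' wider 1200 um spread for IRF (IRF in vein occlusion follows the foveal
#' peak less tightly than SRF/PED do in AMD).
#'
#' Lesion sizes have no published distribution; defaults (en-face semi-axis
#' 100-600 um, axial semi-axis 40-160 um, Poisson(1) extra lesions per
#' positive eye) are plausible for exudative macular disease and remain
#' fully configurable through [diseasePreset()].
#'
#' @param spatialMu population mean `(x, y)` of lesion centers in um;
#'   defaults to the field-of-view center (fovea)
#' @return a [DiseasePreset-class]
#' @export
amdPreset <- function(spatialMu = c(3000, 3000)) {
  diseasePreset(
    name = "AMD",
    prevalence = c(IRF = 0.25, SRF = 0.55, PED = 0.90),
    spatialMu = spatialMu,
    spatialSigma = c(IRF = 800, SRF = 800, PED = 800))
}

#' @rdname amdPreset
#' @export
rvoPreset <- function(spatialMu = c(3000, 3000)) {
  diseasePreset(
    name = "RVO",
    prevalence = c(IRF = 1.0, SRF = 0.42, PED = 0.0),
    spatialMu = spatialMu,
    spatialSigma = c(IRF = 1200, SRF = 800, PED = 800))
}

#' @rdname amdPreset
#' @param name preset label
#' @param prevalence named presence probabilities for `IRF`, `SRF`, `PED`
#' @param spatialSigma named per-biomarker population spread sigma_pop (um)
#' @param lesionCountMean Poisson mean for extra lesions per positive eye
#' @param lesionRadiusRange `(min, max)` en-face lesion semi-axis (um)
#' @param lesionHeightRange `(min, max)` axial lesion semi-axis (um)
#' @export
diseasePreset <- function(name, prevalence, spatialMu = c(3000, 3000),
                          spatialSigma = c(IRF = 800, SRF = 800, PED = 800),
                          lesionCountMean = 1,
                          lesionRadiusRange = c(100, 600),
                          lesionHeightRange = c(40, 160)) {
  new("DiseasePreset", name = name, prevalence = prevalence,
      spatialMu = as.numeric(spatialMu), spatialSigma = spatialSigma,
      lesionCountMean = lesionCountMean,
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      lesionHeightRange = as.numeric(lesionHeightRange))
}

#' Configure a synthetic cohort
#'
#' @param nEyes number of eyes
#' @param preset a [DiseasePreset-class]
#' @param geometry a [ScanGeometry-class]; default is the 6 x 6 mm, 49
#'   B-scan, 125 um ISD protocol
#' @param seed master integer seed; each eye uses an independent substream
#'   derived from `(seed, eye index)` so any single eye is reproducible in
#'   isolation
#' @param leftEyeFraction probability an eye is a left eye
#' @return a [CohortConfig-class]
#' @export
cohortConfig <- function(nEyes, preset, geometry = scanGeometryNew(),
                         seed = 1L, leftEyeFraction = 0.5) {
  new("CohortConfig", nEyes = as.integer(nEyes), preset = preset,
      geometry = geometry, seed = as.integer(seed),
      leftEyeFraction = leftEyeFraction)
}

## Lehmer-style substream derivation; keeps everything below 2^31 and makes
## per-eye generation order-independent.
.eyeSeed <- function(seed, index) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  s <- (s * 16807 + 12345) %% m
  s <- (s + as.numeric(index) * 2654435) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(s)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

## Truncated-Normal lesion center: rejection sampling against the FOV. For
## sigma_pop <= 1200 um on a 6000 um FOV rejection is rare and the
## truncation bias on mean/SD is negligible.
.sampleCenter <- function(mu, sigma, fovX, fovY) {
  for (i in 1:1000) {
    c_ <- stats::rnorm(2L, mean = mu, sd = sigma)
    if (c_[1L] >= 0 && c_[1L] <= fovX && c_[2L] >= 0 && c_[2L] <= fovY)
      return(c_)
  }
  pmin(pmax(c_, 0), c(fovX, fovY))
}

## Rasterize one ellipsoidal lesion: returns the linear indices (into the
## (nb, nd, nx) label array) of its voxels. type: "IRF" (inside the slab),
## "SRF" (dome above Bruch's membrane), "PED" (dome below it). ilm/bm are
## nb x nx matrices of fractional depth indices.
.rasterLesion <- function(g, ilm, bm, type, cx, cy, rx, ry, h) {
  nb <- g@nBscans; nd <- g@nDepth; nx <- g@nAscans
  px <- pitchXum(g); isd <- g@isd; ds <- g@depthScale
  if (2 * rx > g@fovX || 2 * ry > g@fovY || 2 * h > nd * ds)
    stop("lesion larger than volume (semi-axes ", rx, ", ", ry, ", ", h, ")")
  hvox <- h / ds
  idx <- list()
  colRange <- function(b, a, hv) {
    # depth range for one column given local axial half-extent hv (voxels)
    ilm_ <- ilm[b, a]; bm_ <- bm[b, a]
    switch(type,
      IRF = {
        anchor <- (ilm_ + bm_) / 2
        c(max(anchor - hv, ilm_), min(anchor + hv, bm_ - 1e-9))
      },
      SRF = c(max(bm_ - hv, ilm_), bm_ - 1e-9),
      PED = c(bm_, min(bm_ + hv, nd - 1)))
  }
  b0 <- max(ceiling((cy - ry) / isd), 0)
  b1 <- min(floor((cy + ry) / isd), nb - 1L)
  if (b1 >= b0) {
    for (bi in b0:b1) {
      fy <- ((bi * isd - cy) / ry)^2
      if (fy >= 1) next
      xhw <- rx * sqrt(1 - fy)
      a0 <- max(ceiling((cx - xhw) / px), 0)
      a1 <- min(floor((cx + xhw) / px), nx - 1L)
      if (a1 < a0) next
      for (ai in a0:a1) {
        fr <- fy + ((ai * px - cx) / rx)^2
        if (fr >= 1) next
        rng <- colRange(bi + 1L, ai + 1L, hvox * sqrt(1 - fr))
        d0 <- ceiling(rng[1L]); d1 <- floor(rng[2L])
        if (d1 >= d0)
          idx[[length(idx) + 1L]] <-
            (bi + 1L) + (d0:d1) * nb + ai * nb * nd
      }
    }
  }
  # guarantee at least one voxel at the lesion center so a positive eye is
  # always detectable in the reference scan
  bc <- min(max(round(cy / isd), 0), nb - 1L) + 1L
  ac <- min(max(round(cx / px), 0), nx - 1L) + 1L
  dctr <- switch(type,
    IRF = round((ilm[bc, ac] + bm[bc, ac]) / 2),
    SRF = ceiling(bm[bc, ac]) - 1,
    PED = ceiling(bm[bc, ac]))
  dctr <- min(max(dctr, 0), nd - 1L)
  idx[[length(idx) + 1L]] <- bc + dctr * nb + (ac - 1L) * nb * nd
  unlist(idx)
}

#' Generate one synthetic eye
#'
#' Draws a layered retina (smooth Bruch's membrane, ILM with a central
#' foveal depression) and, independently per biomarker with the preset's
#' presence probability, `1 + Poisson(lesionCountMean)` ellipsoidal lesions
#' whose en-face centers come from the preset's truncated Gaussian. IRF is
#' placed inside the retinal slab, SRF as a dome immediately above Bruch's
#' membrane, PED as a dome below it; labels are written in priority order
#' PED, then SRF, then IRF (later overwrites earlier).
#'
#' The returned volume carries the drawn lesion table (biomarker, center,
#' semi-axes in um) as attribute `"lesions"` for calibration checks; the
#' attribute is not persisted by [writeVolume()].
#'
#' @param config a [CohortConfig-class]
#' @param eyeIndex 1-based index of the eye within the cohort; together with
#'   the config seed it determines the eye's private random substream
#' @return a [SegVolume-class]
#' @export
sampleEye <- function(config, eyeIndex = 1L) {
  validObject(config)
  g <- config@geometry
  preset <- config@preset
  .withSeed(.eyeSeed(config@seed, eyeIndex), {
    nb <- g@nBscans; nd <- g@nDepth; nx <- g@nAscans
    x <- ascanPositionsUm(g); y <- bscanPositionsUm(g)
    lat <- if (stats::runif(1L) < config@leftEyeFraction) "left" else "right"

    # Bruch's membrane: gently tilted plane at ~65% depth. ILM: BM minus a
    # ~300 um retina that thins by ~100 um in a Gaussian foveal pit.
    tiltX <- stats::runif(1L, -0.01, 0.01) * nd
    tiltY <- stats::runif(1L, -0.01, 0.01) * nd
    thickUm <- stats::runif(1L, 280, 320)
    bm <- 0.65 * nd +
      tiltX * outer(rep(1, nb), (x - g@fovX / 2) / g@fovX) +
      tiltY * outer((y - g@fovY / 2) / g@fovY, rep(1, nx))
    r2 <- outer((y - g@fovY / 2)^2, (x - g@fovX / 2)^2, "+")
    thick <- (thickUm - 100 * exp(-r2 / (2 * 600^2))) / g@depthScale
    ilm <- bm - thick

    # slab fill by per-column depth ranges: integer depth d is retina iff
    # ceil(ilm) <= d <= ceil(bm) - 1 (d >= ilm and d < bm)
    lab <- array(0L, dim = c(nb, nd, nx))
    i0 <- pmax(ceiling(as.vector(ilm)), 0)
    i1 <- pmin(ceiling(as.vector(bm)) - 1, nd - 1L)
    lens <- pmax(i1 - i0 + 1L, 0L)
    j <- which(lens > 0L)                      # (b, x) columns, b fastest
    bcol <- (j - 1L) %% nb + 1L
    xcol <- (j - 1L) %/% nb
    lab[sequence(nvec = lens[j], from = bcol + i0[j] * nb + xcol * nb * nd,
                 by = nb)] <- 1L

    # draw all lesions first (fixed order IRF, SRF, PED for the stream),
    # then rasterize in overwrite-priority order PED < SRF < IRF
    les <- list()
    for (b in c("IRF", "SRF", "PED")) {
      if (stats::runif(1L) >= preset@prevalence[[b]]) next
      n <- 1L + stats::rpois(1L, preset@lesionCountMean)
      for (k in seq_len(n)) {
        ctr <- .sampleCenter(preset@spatialMu, preset@spatialSigma[[b]],
                             g@fovX, g@fovY)
        les[[length(les) + 1L]] <- data.frame(
          biomarker = b, cx = ctr[1L], cy = ctr[2L],
          rx = stats::runif(1L, preset@lesionRadiusRange[1L],
                            preset@lesionRadiusRange[2L]),
          ry = stats::runif(1L, preset@lesionRadiusRange[1L],
                            preset@lesionRadiusRange[2L]),
          h = stats::runif(1L, preset@lesionHeightRange[1L],
                           preset@lesionHeightRange[2L]))
      }
    }
    lesions <- if (length(les)) do.call(rbind, les) else
      data.frame(biomarker = character(), cx = numeric(), cy = numeric(),
                 rx = numeric(), ry = numeric(), h = numeric())
    for (b in c("PED", "SRF", "IRF")) {
      sel <- lesions[lesions$biomarker == b, , drop = FALSE]
      for (k in seq_len(nrow(sel)))
        lab[.rasterLesion(g, ilm, bm, b, sel$cx[k], sel$cy[k],
                          sel$rx[k], sel$ry[k], sel$h[k])] <- .LABELS[[b]]
    }

    v <- segVolumeNew(lab, g,
                      eyeId = sprintf("%s_eye_%03d", tolower(preset@name),
                                      eyeIndex),
                      laterality = lat,
                      disease = if (preset@name %in% c("AMD", "RVO"))
                        preset@name else "unknown")
    attr(v, "lesions") <- lesions
    v
  })
}

#' Generate and write a synthetic cohort
#'
#' Writes `nEyes` volumes (NIfTI + JSON sidecars) via [writeVolume()] plus a
#' cohort manifest CSV. Per-eye substreams derive from the master seed, so
#' regenerating any single eye with [sampleEye()] reproduces it exactly.
#'
#' @param config a [CohortConfig-class]
#' @param outDir writable output directory (created if needed)
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.csv` in `outDir`
#' @export
sampleCohort <- function(config, outDir) {
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", config@nEyes)
  for (i in seq_len(config@nEyes)) {
    v <- sampleEye(config, i)
    fn <- sprintf("%s.nii.gz", v@eyeId)
    writeVolume(v, file.path(outDir, fn))
    rows[[i]] <- data.frame(eye_id = v@eyeId, path = fn,
                            laterality = v@laterality, disease = v@disease)
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"),
                provenance = sprintf("synthetic %s cohort (octscan generator)",
                                     config@preset@name),
                seed = config@seed)
  invisible(readManifest(file.path(outDir, "manifest.csv")))
}
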