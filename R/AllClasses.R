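#' @import methods
NULL

## Label codes used throughout: one label per voxel, priority at generation
## time PED < SRF < IRF (later overwrites earlier).
.LABELS <- c(background = 0L, retina = 1L, IRF = 2L, SRF = 3L, PED = 4L)

## Biomarkers accepted by per-biomarker operations. "IRF_SRF" is the pooled
## IRF-or-SRF biomarker; "retina" is the total retina from ILM to Bruch's
## membrane and therefore includes intra-/subretinal fluid but not PED.
.BIOMARKER_CODES <- list(
  IRF     = 2L,
  SRF     = 3L,
  IRF_SRF = c(2L, 3L),
  PED     = 4L,
  retina  = c(1L, 2L, 3L)
)

.FLUID_BIOMARKERS <- c("IRF", "SRF", "IRF_SRF", "PED")
.ALL_BIOMARKERS <- c(.FLUID_BIOMARKERS, "retina")

## All code sets are contiguous, so membership reduces to a range test.
.hitArray <- function(lab, codes) {
  if (length(codes) == 1L) lab == codes
  else lab >= min(codes) & lab <= max(codes)
}

.biomarkerCodes <- function(biomarker) {
  if (!is.character(biomarker) || length(biomarker) != 1L ||
      !biomarker %in% names(.BIOMARKER_CODES)) {
    stop("unknown biomarker '", paste(biomarker, collapse = ","),
         "'; must be one of ", paste(names(.BIOMARKER_CODES), collapse = ", "))
  }
  .BIOMARKER_CODES[[biomarker]]
}

#' ScanGeometry: physical geometry of an OCT volume
#'
#' Describes the acquisition grid of a macular volume scan: the en-face field
#' of view, the interscan distance (ISD) along the slow axis, and the voxel
#' grid. B-scan `i` (0-based) sits at physical position `i * isdUm(g)` so the
#' B-scan positions span the closed interval `[0, fovYum]`, which forces
#' `(nBscans - 1) * isd == fovY`. A-scan `i` sits at `i * pitchXum(g)` with
#' pixel pitch `fovX / nAscans`.
#'
#' @slot fovX physical en-face width (fast axis), micrometres
#' @slot fovY physical slow-axis extent, micrometres
#' @slot isd interscan distance along the slow axis, micrometres
#' @slot nBscans number of B-scans (slow-axis samples)
#' @slot nAscans A-scans per B-scan (fast-axis samples)
#' @slot nDepth axial samples per A-scan
#' @slot depthScale axial micrometres per sample
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  slots = c(
    fovX = "numeric", fovY = "numeric", isd = "numeric",
    nBscans = "integer", nAscans = "integer", nDepth = "integer",
    depthScale = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msgs <- character()
  sc <- c(fovX = object@fovX, fovY = object@fovY, isd = object@isd,
          depthScale = object@depthScale)
  if (any(lengths(list(object@fovX, object@fovY, object@isd, object@nBscans,
                       object@nAscans, object@nDepth, object@depthScale)) != 1L))
    msgs <- c(msgs, "all geometry fields must be length 1")
  else {
    if (any(!is.finite(sc)) || any(sc <= 0))
      msgs <- c(msgs, "physical sizes (fovX, fovY, isd, depthScale) must be > 0")
    cnt <- c(object@nBscans, object@nAscans, object@nDepth)
    if (any(is.na(cnt)) || any(cnt < 1L))
      msgs <- c(msgs, "all sample counts must be >= 1")
    if (length(msgs) == 0L &&
        abs((object@nBscans - 1L) * object@isd - object@fovY) > 1e-6)
      msgs <- c(msgs, sprintf(
        "(nBscans - 1) * isd must equal fovY: (%d - 1) * %g != %g",
        object@nBscans, object@isd, object@fovY))
  }
  if (length(msgs)) msgs else TRUE
})

#' SegVolume: one eye's labeled segmentation volume
#'
#' The atomic input of every analysis: a 3D integer label array indexed
#' `[bscan, depth, ascan]` with codes 0 background, 1 retina (ILM to Bruch's
#' membrane), 2 IRF, 3 SRF, 4 PED, plus the acquisition geometry and eye
#' metadata. The en-face plane is `(bscan, ascan)`; after orientation
#' normalization (see [mirrorIfLeft()]) +x points nasal.
#'
#' @slot labels 3D integer array `[bscan, depth, ascan]`, codes 0..4
#' @slot geometry a [ScanGeometry-class]
#' @slot eyeId character identifier
#' @slot laterality `"left"` or `"right"`
#' @slot disease `"AMD"`, `"RVO"` or `"unknown"`
#' @slot normalized `TRUE` once laterality has been orientation-normalized
#' @exportClass SegVolume
setClass("SegVolume",
  slots = c(
    labels = "array", geometry = "ScanGeometry", eyeId = "character",
    laterality = "character", disease = "character", normalized = "logical"
  )
)

setValidity("SegVolume", function(object) {
  msgs <- character()
  g <- object@geometry
  d <- dim(object@labels)
  if (length(d) != 3L)
    msgs <- c(msgs, "labels must be a 3D array [bscan, depth, ascan]")
  else if (!identical(d, c(g@nBscans, g@nDepth, g@nAscans)))
    msgs <- c(msgs, sprintf(
      "label array shape (%s) does not match geometry (%d, %d, %d)",
      paste(d, collapse = ", "), g@nBscans, g@nDepth, g@nAscans))
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be integer-typed")
  else {
    rng <- range(object@labels)
    if (is.na(rng[1L]) || rng[1L] < 0L || rng[2L] > 4L)
      msgs <- c(msgs, "label codes restricted to {0,1,2,3,4}")
  }
  if (!object@laterality %in% c("left", "right"))
    msgs <- c(msgs, "laterality must be 'left' or 'right'")
  if (!object@disease %in% c("AMD", "RVO", "unknown"))
    msgs <- c(msgs, "disease must be 'AMD', 'RVO' or 'unknown'")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msgs <- c(msgs, "normalized must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' ColumnCountMap: per-column foreground voxel counts
#'
#' Result of projecting a [SegVolume-class] along depth: `counts[y, x]` is the
#' number of axial samples carrying the biomarker's label in A-scan column
#' `(y, x)`.
#'
#' @slot counts non-negative integer matrix `[bscan, ascan]`
#' @slot biomarker one of `"IRF"`, `"SRF"`, `"IRF_SRF"`, `"PED"`, `"retina"`
#' @slot eyeId character
#' @slot geometry a [ScanGeometry-class]
#' @exportClass ColumnCountMap
setClass("ColumnCountMap",
  slots = c(counts = "matrix", biomarker = "character", eyeId = "character",
            geometry = "ScanGeometry")
)

setValidity("ColumnCountMap", function(object) {
  g <- object@geometry
  if (!identical(dim(object@counts), c(g@nBscans, g@nAscans)))
    return("counts shape must be (nBscans, nAscans)")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (!object@biomarker %in% .ALL_BIOMARKERS)
    return("unknown biomarker")
  TRUE
})

#' EnFaceMap: binarized per-eye biomarker presence in the en-face plane
#'
#' `presence[y, x]` is 1 where the biomarker occurs anywhere along depth in
#' column `(y, x)` and 0 elsewhere; fluid height and quantity are deliberately
#' discarded (presence-only binarization).
#'
#' @slot presence integer matrix `[bscan, ascan]` of 0/1
#' @slot biomarker biomarker name
#' @slot eyeId character
#' @slot geometry a [ScanGeometry-class]
#' @exportClass EnFaceMap
setClass("EnFaceMap",
  slots = c(presence = "matrix", biomarker = "character", eyeId = "character",
            geometry = "ScanGeometry")
)

setValidity("EnFaceMap", function(object) {
  g <- object@geometry
  if (!identical(dim(object@presence), c(g@nBscans, g@nAscans)))
    return("presence shape must be (nBscans, nAscans)")
  if (!all(object@presence %in% c(0L, 1L)))
    return("presence values must be 0 or 1")
  if (!object@biomarker %in% .ALL_BIOMARKERS)
    return("unknown biomarker")
  TRUE
})

#' PopulationHeatmap: fraction of eyes positive per en-face location
#'
#' Elementwise mean of a cohort's binarized presence maps: `fraction[y, x]`
#' is the fraction of eyes (0..1) showing the biomarker at that location.
#'
#' @slot fraction numeric matrix `[bscan, ascan]` in `[0, 1]`
#' @slot nEyes denominator (number of aggregated eyes)
#' @slot biomarker biomarker name
#' @slot geometry a [ScanGeometry-class]
#' @exportClass PopulationHeatmap
setClass("PopulationHeatmap",
  slots = c(fraction = "matrix", nEyes = "integer", biomarker = "character",
            geometry = "ScanGeometry")
)

setValidity("PopulationHeatmap", function(object) {
  g <- object@geometry
  if (!identical(dim(object@fraction), c(g@nBscans, g@nAscans)))
    return("fraction shape must be (nBscans, nAscans)")
  if (any(object@fraction < -1e-12) || any(object@fraction > 1 + 1e-12))
    return("fraction values must lie in [0, 1]")
  if (object@nEyes < 1L) return("nEyes must be >= 1")
  TRUE
})

#' GaussianFit: isotropic 2D Gaussian fit of a population heatmap
#'
#' Parameters of the model
#' `f(x, y) = A * exp(-((x - muX)^2 + (y - muY)^2) / (2 * sigma^2))`
#' fitted in physical micrometre coordinates, with the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` over all grid points.
#'
#' @slot amplitude fitted amplitude A (fraction units)
#' @slot muX,muY fitted center, micrometres
#' @slot sigma fitted isotropic spread, micrometres
#' @slot rSquared coefficient of determination (`NaN` when undefined)
#' @slot converged optimizer convergence flag
#' @exportClass GaussianFit
setClass("GaussianFit",
  slots = c(amplitude = "numeric", muX = "numeric", muY = "numeric",
            sigma = "numeric", rSquared = "numeric", converged = "logical")
)

setValidity("GaussianFit", function(object) {
  if (object@converged && (!is.finite(object@sigma) || object@sigma <= 0))
    return("sigma must be > 0 for a converged fit")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    return("rSquared cannot exceed 1")
  TRUE
})

#' CropWindow: a centered rectangular field-of-view crop
#'
#' Physical crop rectangle `[cx - wx/2, cx + wx/2] x [cy - wy/2, cy + wy/2]`
#' (closed; boundary pixels count as inside).
#'
#' @slot widthX,widthY physical crop size, micrometres
#' @slot centerX,centerY crop center, micrometres
#' @exportClass CropWindow
setClass("CropWindow",
  slots = c(widthX = "numeric", widthY = "numeric",
            centerX = "numeric", centerY = "numeric")
)

setValidity("CropWindow", function(object) {
  if (object@widthX <= 0 || object@widthY <= 0)
    return("crop widths must be > 0")
  TRUE
})

#' SensitivityMap: detection sensitivity by centered crop size
#'
#' `sensitivity[i, j]` is the fraction of reference-positive eyes still
#' detected inside a fovea-centered crop of size `sizesY[i] x sizesX[j]`
#' (rows = slow-axis size, cols = fast-axis size, both on a `stepUm` grid up
#' to the full field of view). The full-size entry is 1 by construction.
#'
#' @slot sensitivity numeric matrix in `[0, 1]`, dimnames = sizes in um
#' @slot stepUm crop size increment, micrometres
#' @slot biomarker biomarker name
#' @slot nPositiveReference denominator: reference-positive eyes
#' @exportClass SensitivityMap
setClass("SensitivityMap",
  slots = c(sensitivity = "matrix", stepUm = "numeric", biomarker = "character",
            nPositiveReference = "integer")
)

setValidity("SensitivityMap", function(object) {
  s <- object@sensitivity
  if (any(s < -1e-12) || any(s > 1 + 1e-12))
    return("sensitivities must lie in [0, 1]")
  if (object@nPositiveReference < 1L)
    return("nPositiveReference must be >= 1")
  nr <- nrow(s); nc <- ncol(s)
  if (abs(s[nr, nc] - 1) > 1e-12)
    return("entry at full size must be 1.0")
  TRUE
})

#' DiseasePreset: statistical description of a synthetic disease cohort
#'
#' Per-biomarker presence probabilities, the population spatial model of
#' lesion centers (isotropic Gaussian about `spatialMu`, truncated to the
#' field of view), and lesion size ranges.
#'
#' @slot name preset name, `"AMD"` or `"RVO"` (free-form allowed)
#' @slot prevalence named probabilities for `IRF`, `SRF`, `PED`
#' @slot spatialMu length-2 `(x, y)` population mean of lesion centers, um
#' @slot spatialSigma named per-biomarker population spread sigma_pop, um
#' @slot lesionCountMean Poisson mean of extra lesions per positive eye
#' @slot lesionRadiusRange `(min, max)` en-face semi-axis, um
#' @slot lesionHeightRange `(min, max)` axial semi-axis, um
#' @exportClass DiseasePreset
setClass("DiseasePreset",
  slots = c(name = "character", prevalence = "numeric", spatialMu = "numeric",
            spatialSigma = "numeric", lesionCountMean = "numeric",
            lesionRadiusRange = "numeric", lesionHeightRange = "numeric")
)

setValidity("DiseasePreset", function(object) {
  msgs <- character()
  need <- c("IRF", "SRF", "PED")
  if (!all(need %in% names(object@prevalence)))
    msgs <- c(msgs, "prevalence must name IRF, SRF and PED")
  else if (any(object@prevalence < 0) || any(object@prevalence > 1))
    msgs <- c(msgs, "prevalences must lie in [0, 1]")
  if (length(object@spatialMu) != 2L)
    msgs <- c(msgs, "spatialMu must be length 2 (x, y)")
  if (!all(need %in% names(object@spatialSigma)))
    msgs <- c(msgs, "spatialSigma must name IRF, SRF and PED")
  else if (any(object@spatialSigma <= 0))
    msgs <- c(msgs, "spatialSigma must be > 0")
  if (object@lesionCountMean < 0)
    msgs <- c(msgs, "lesionCountMean must be >= 0")
  for (nm in c("lesionRadiusRange", "lesionHeightRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
      msgs <- c(msgs, paste(nm, "must be an ordered positive (min, max) pair"))
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortConfig: reproducible synthetic-cohort specification
#'
#' @slot nEyes number of eyes to generate
#' @slot preset a [DiseasePreset-class]
#' @slot geometry a [ScanGeometry-class]
#' @slot seed master integer seed; per-eye substreams derive from it
#' @slot leftEyeFraction probability an eye is a left eye
#' @exportClass CohortConfig
setClass("CohortConfig",
  slots = c(nEyes = "integer", preset = "DiseasePreset",
            geometry = "ScanGeometry", seed = "integer",
            leftEyeFraction = "numeric")
)

setValidity("CohortConfig", function(object) {
  if (object@nEyes < 1L) return("nEyes must be >= 1")
  if (is.na(object@seed)) return("seed must be a finite integer")
  if (object@leftEyeFraction < 0 || object@leftEyeFraction > 1)
    return("leftEyeFraction must lie in [0, 1]")
  TRUE
})
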