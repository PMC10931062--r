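#' Construct a scan geometry
#'
#' Defaults reproduce the Spectralis-style macular protocol used throughout:
#' a 6 x 6 mm field of view covered by 49 B-scans at 125 um interscan
#' distance. 480 A-scans give an exact in-plane pixel pitch of 12.5 um, so a
#' 250 um crop step is exactly 20 pixels.
#'
#' @param fovX,fovY en-face physical extent in micrometres
#' @param isd interscan distance in micrometres; must satisfy
#'   `(nBscans - 1) * isd == fovY`
#' @param nBscans,nAscans,nDepth voxel grid dimensions
#' @param depthScale axial micrometres per sample
#' @return a validated [ScanGeometry-class]
#' @examples
#' g <- scanGeometryNew()
#' pitchXum(g)   # 12.5
#' @export
scanGeometryNew <- function(fovX = 6000, fovY = 6000, isd = 125,
                            nBscans = 49L, nAscans = 480L, nDepth = 496L,
                            depthScale = 7) {
  new("ScanGeometry", fovX = as.numeric(fovX), fovY = as.numeric(fovY),
      isd = as.numeric(isd), nBscans = as.integer(nBscans),
      nAscans = as.integer(nAscans), nDepth = as.integer(nDepth),
      depthScale = as.numeric(depthScale))
}

#' Geometry helpers
#'
#' `pitchXum()` is the fast-axis pixel pitch `fovX / nAscans`; `isdUm()` the
#' interscan distance; `ascanPositionsUm()` / `bscanPositionsUm()` the
#' physical en-face coordinates of pixel index i (`i * pitch`, `i * isd`,
#' 0-based).
#'
#' @param g a [ScanGeometry-class]
#' @name geometry-helpers
NULL

#' @rdname geometry-helpers
#' @export
pitchXum <- function(g) g@fovX / g@nAscans

#' @rdname geometry-helpers
#' @export
isdUm <- function(g) g@isd

#' @rdname geometry-helpers
#' @export
ascanPositionsUm <- function(g) (seq_len(g@nAscans) - 1) * pitchXum(g)

#' @rdname geometry-helpers
#' @export
bscanPositionsUm <- function(g) (seq_len(g@nBscans) - 1) * g@isd

#' @rdname geometry-helpers
#' @export
nBscans <- function(g) g@nBscans

#' @rdname geometry-helpers
#' @export
nAscans <- function(g) g@nAscans

#' @rdname geometry-helpers
#' @export
nDepth <- function(g) g@nDepth

.sameGeometry <- function(a, b) {
  isTRUE(all.equal(a@fovX, b@fovX)) && isTRUE(all.equal(a@fovY, b@fovY)) &&
    isTRUE(all.equal(a@isd, b@isd)) && a@nBscans == b@nBscans &&
    a@nAscans == b@nAscans && a@nDepth == b@nDepth &&
    isTRUE(all.equal(a@depthScale, b@depthScale))
}

#' Construct a labeled segmentation volume
#'
#' @param labels 3D integer array `[bscan, depth, ascan]` with codes 0..4
#' @param geometry a [ScanGeometry-class] matching `dim(labels)`
#' @param eyeId identifier
#' @param laterality `"left"` or `"right"`
#' @param disease `"AMD"`, `"RVO"` or `"unknown"`
#' @param normalized whether the volume is already orientation-normalized
#' @return a validated [SegVolume-class]
#' @export
segVolumeNew <- function(labels, geometry, eyeId = "eye",
                         laterality = "right", disease = "unknown",
                         normalized = FALSE) {
  storage.mode(labels) <- "integer"
  new("SegVolume", labels = labels, geometry = geometry, eyeId = eyeId,
      laterality = laterality, disease = disease, normalized = normalized)
}
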