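#' Orientation normalization
#'
#' `mirrorIfLeft()` mirrors left eyes horizontally (along the A-scan axis)
#' so that the nasal portion always points to +x, marks the volume as
#' orientation-normalized, and is idempotent: a volume already normalized is
#' returned unchanged. Right eyes are only flagged. `mirrorX()` is the
#' underlying pure reflection (x index `i -> n - 1 - i`), an involution that
#' ignores laterality and flags.
#'
#' @param v a [SegVolume-class]
#' @return a [SegVolume-class]
#' @export
mirrorIfLeft <- function(v) {
  if (v@normalized) return(v)
  out <- if (v@laterality == "left") mirrorX(v) else v
  out@normalized <- TRUE
  out
}

#' @rdname mirrorIfLeft
#' @export
mirrorX <- function(v) {
  v@labels <- v@labels[, , v@geometry@nAscans:1L, drop = FALSE]
  v
}

#' Project a volume to per-column biomarker voxel counts
#'
#' Sums the biomarker's label occurrences along depth (the en-face view):
#' `counts[y, x]` is the number of axial samples in column `(y, x)` carrying
#' the label. The pooled biomarker `"IRF_SRF"` counts voxels labeled IRF or
#' SRF; `"retina"` counts everything between ILM and Bruch's membrane
#' (labels retina, IRF, SRF).
#'
#' @param v an orientation-normalized [SegVolume-class]
#' @param biomarker one of `"IRF"`, `"SRF"`, `"IRF_SRF"`, `"PED"`,
#'   `"retina"`
#' @return a [ColumnCountMap-class]
#' @export
projectColumns <- function(v, biomarker) {
  codes <- .biomarkerCodes(biomarker)
  hit <- .hitArray(v@labels, codes)
  # sum over depth (dim 2): move depth first, then column-sum per (y, x)
  cnt <- colSums(aperm(hit, c(2L, 1L, 3L)))
  storage.mode(cnt) <- "integer"
  new("ColumnCountMap", counts = cnt, biomarker = biomarker,
      eyeId = v@eyeId, geometry = v@geometry)
}

#' Binarize a column count map to a presence map
#'
#' `presence[y, x] = 1` iff `counts[y, x] >= minColumnVoxels`; the default
#' threshold of one voxel encodes presence-only binarization with no
#' minimum-size filter.
#'
#' @param m a [ColumnCountMap-class]
#' @param minColumnVoxels minimum voxels per column to count as present
#' @return an [EnFaceMap-class]
#' @export
binarize <- function(m, minColumnVoxels = 1L) {
  pres <- (m@counts >= minColumnVoxels) * 1L
  new("EnFaceMap", presence = pres, biomarker = m@biomarker,
      eyeId = m@eyeId, geometry = m@geometry)
}

#' @rdname binarize
#' @param v a [SegVolume-class]
#' @param biomarker biomarker name
#' @description `enfaceMap()` is the composition
#'   `binarize(projectColumns(v, biomarker))`.
#' @export
enfaceMap <- function(v, biomarker, minColumnVoxels = 1L) {
  binarize(projectColumns(v, biomarker), minColumnVoxels)
}
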