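#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers; user code should
#' use these rather than reaching into slots.
#'
#' @param x an octscan S4 object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))

#' @rdname accessors
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @rdname accessors
#' @export
setGeneric("biomarker", function(x) standardGeneric("biomarker"))

#' @rdname accessors
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))

#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' @rdname accessors
#' @export
setGeneric("disease", function(x) standardGeneric("disease"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname accessors
#' @export
setGeneric("columnCounts", function(x) standardGeneric("columnCounts"))

#' @rdname accessors
#' @export
setGeneric("fractionMap", function(x) standardGeneric("fractionMap"))

#' @rdname accessors
#' @export
setGeneric("nEyes", function(x) standardGeneric("nEyes"))

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

setMethod("scanGeometry", "SegVolume", function(x) x@geometry)
setMethod("scanGeometry", "ColumnCountMap", function(x) x@geometry)
setMethod("scanGeometry", "EnFaceMap", function(x) x@geometry)
setMethod("scanGeometry", "PopulationHeatmap", function(x) x@geometry)
setMethod("scanGeometry", "CohortConfig", function(x) x@geometry)

setMethod("eyeId", "SegVolume", function(x) x@eyeId)
setMethod("eyeId", "ColumnCountMap", function(x) x@eyeId)
setMethod("eyeId", "EnFaceMap", function(x) x@eyeId)

setMethod("biomarker", "ColumnCountMap", function(x) x@biomarker)
setMethod("biomarker", "EnFaceMap", function(x) x@biomarker)
setMethod("biomarker", "PopulationHeatmap", function(x) x@biomarker)
setMethod("biomarker", "SensitivityMap", function(x) x@biomarker)

setMethod("segLabels", "SegVolume", function(x) x@labels)
setMethod("laterality", "SegVolume", function(x) x@laterality)
setMethod("disease", "SegVolume", function(x) x@disease)
setMethod("isNormalized", "SegVolume", function(x) x@normalized)

setMethod("presence", "EnFaceMap", function(x) x@presence)
setMethod("columnCounts", "ColumnCountMap", function(x) x@counts)
setMethod("fractionMap", "PopulationHeatmap", function(x) x@fraction)
setMethod("nEyes", "PopulationHeatmap", function(x) x@nEyes)
setMethod("sensitivity", "SensitivityMap", function(x) x@sensitivity)

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry: %g x %g um FOV, %d B-scans @ %g um ISD, %d x %d A-scan grid, depth scale %g um\n",
    object@fovX, object@fovY, object@nBscans, object@isd,
    object@nDepth, object@nAscans, object@depthScale))
})

setMethod("show", "SegVolume", function(object) {
  g <- object@geometry
  tab <- table(factor(object@labels, levels = 0:4,
                      labels = names(.LABELS)))
  cat(sprintf("SegVolume '%s' (%s eye, %s%s)\n", object@eyeId,
              object@laterality, object@disease,
              if (object@normalized) ", orientation-normalized" else ""))
  cat(sprintf("  %d x %d x %d voxels [bscan, depth, ascan]\n",
              g@nBscans, g@nDepth, g@nAscans))
  cat("  voxels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = " "), "\n")
})

setMethod("show", "EnFaceMap", function(object) {
  cat(sprintf("EnFaceMap '%s' [%s]: %d / %d columns positive\n",
              object@eyeId, object@biomarker,
              sum(object@presence), length(object@presence)))
})

setMethod("show", "ColumnCountMap", function(object) {
  cat(sprintf("ColumnCountMap '%s' [%s]: total %d foreground voxels\n",
              object@eyeId, object@biomarker, sum(object@counts)))
})

setMethod("show", "PopulationHeatmap", function(object) {
  cat(sprintf("PopulationHeatmap [%s]: %d eyes, max fraction %.3f\n",
              object@biomarker, object@nEyes, max(object@fraction)))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: A=%.4f, mu=(%.1f, %.1f) um, sigma=%.1f um, R^2=%.4f%s\n",
    object@amplitude, object@muX, object@muY, object@sigma, object@rSquared,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SensitivityMap", function(object) {
  cat(sprintf(
    "SensitivityMap [%s]: %d x %d crop sizes (step %g um), %d reference-positive eyes\n",
    object@biomarker, nrow(object@sensitivity), ncol(object@sensitivity),
    object@stepUm, object@nPositiveReference))
})

setMethod("show", "DiseasePreset", function(object) {
  p <- object@prevalence
  cat(sprintf("DiseasePreset '%s': IRF %.0f%%, SRF %.0f%%, PED %.0f%%\n",
              object@name, 100 * p[["IRF"]], 100 * p[["SRF"]],
              100 * p[["PED"]]))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d eyes, preset '%s', seed %d\n",
              object@nEyes, object@preset@name, object@seed))
})
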