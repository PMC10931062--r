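#' Drop every second B-scan (repeatedly)
#'
#' Simulates acquisition at an increased interscan distance by keeping
#' B-scans at indices `{0, f, 2f, ..., nBscans - 1}` (0-based). Both border
#' scans are always retained — the only phase consistent with
#' border-half-weighted volume estimation, which needs scans at the volume
#' edges. The geometry is updated (`isd * f`, adjusted `nBscans`); retained
#' slices are bit-identical to the source.
#'
#' @param v a [SegVolume-class]
#' @param factor decimation factor, a power of two dividing `nBscans - 1`
#'   (for 49 scans: 1, 2, 4, 8 giving 49, 25, 13, 7 scans)
#' @return a [SegVolume-class] at the coarser sampling
#' @export
decimate <- function(v, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L || bitwAnd(factor, factor - 1L) != 0L)
    stop("decimation factor must be a power of two >= 1, got ", factor)
  g <- v@geometry
  if ((g@nBscans - 1L) %% factor != 0L)
    stop("factor ", factor, " does not divide nBscans - 1 = ", g@nBscans - 1L)
  if (factor == 1L) return(v)
  kept <- seq(1L, g@nBscans, by = factor)
  g2 <- scanGeometryNew(fovX = g@fovX, fovY = g@fovY, isd = g@isd * factor,
                        nBscans = length(kept), nAscans = g@nAscans,
                        nDepth = g@nDepth, depthScale = g@depthScale)
  segVolumeNew(v@labels[kept, , , drop = FALSE], g2, eyeId = v@eyeId,
               laterality = v@laterality, disease = v@disease,
               normalized = v@normalized)
}

#' Border-corrected B-scan weights
#'
#' Each interior B-scan represents one interscan distance of slow-axis
#' extent; the first and last B-scan, sitting on the volume border, get half
#' weight. The weights therefore sum exactly to `fovY` at every valid
#' decimation factor, keeping the overall analyzed volume constant
#' regardless of ISD.
#'
#' @param g a [ScanGeometry-class]
#' @return numeric vector of length `nBscans(g)`, micrometres
#' @export
scanWeights <- function(g) {
  w <- rep(g@isd, g@nBscans)
  w[c(1L, g@nBscans)] <- g@isd / 2
  w
}

## Per-B-scan voxel counts for every label code in one pass: bin each voxel
## by (code, B-scan) and tabulate. Returns an nBscans x 5 matrix with
## columns code 0..4.
.perScanCountMatrix <- function(v) {
  nb <- v@geometry@nBscans
  lab <- as.vector(v@labels)                 # B-scan index cycles fastest
  bins <- lab * nb + rep_len(seq_len(nb), length(lab))
  matrix(tabulate(bins, nbins = 5L * nb), nrow = nb)
}

## Per-column voxel counts for every label code in one pass: returns an
## (nBscans, nAscans, 5) array, third dimension = code 0..4. Summing over
## A-scans gives per-B-scan counts; thresholding gives en-face presence.
.columnCountArray <- function(v) {
  g <- v@geometry
  nb <- g@nBscans; nd <- g@nDepth; nx <- g@nAscans
  lab <- as.vector(v@labels)                 # b fastest, then d, then x
  colIdx <- rep_len(seq_len(nb), length(lab)) +
    rep(0:(nx - 1L), each = nb * nd) * nb
  bins <- lab * (nb * nx) + colIdx
  array(tabulate(bins, nbins = 5L * nb * nx), dim = c(nb, nx, 5L))
}

## Per-B-scan biomarker voxel counts; all ISD quantities derive from this.
.perScanCounts <- function(v, biomarker) {
  codes <- .biomarkerCodes(biomarker)
  m <- .perScanCountMatrix(v)[, codes + 1L, drop = FALSE]
  as.vector(rowSums(m))
}

.volumeFromCounts <- function(counts, g) {
  area <- counts * pitchXum(g) * g@depthScale   # per-scan cross-section, um^2
  sum(area * scanWeights(g))
}

#' Approximate a biomarker volume from B-scan cross-sections
#'
#' The per-B-scan cross-sectional area (voxel count times in-plane voxel
#' area, `pitchX * depthScale`) is multiplied by the interscan distance,
#' with the border scans half-weighted (see [scanWeights()]). Works at any
#' decimation level: a decimated volume carries its effective ISD in its
#' geometry.
#'
#' @param v a [SegVolume-class]
#' @param biomarker biomarker name (`"retina"` gives total retinal volume,
#'   ILM to Bruch's membrane, i.e. labels retina + IRF + SRF)
#' @return estimated volume in cubic micrometres
#' @export
estimateVolume <- function(v, biomarker) {
  .volumeFromCounts(.perScanCounts(v, biomarker), v@geometry)
}

#' @rdname estimateVolume
#' @export
totalRetinaVolume <- function(v) estimateVolume(v, "retina")

#' Any biomarker voxel present?
#'
#' @param v a [SegVolume-class]
#' @param biomarker biomarker name
#' @return logical scalar
#' @export
biomarkerPresent <- function(v, biomarker) {
  any(.perScanCounts(v, biomarker) > 0L)
}

.asVolumeSource <- function(volumes, nEyes = NULL) {
  if (is.function(volumes)) {
    if (is.null(nEyes)) stop("nEyes must be given with a generator function")
    list(n = as.integer(nEyes), get = volumes)
  } else {
    list(n = length(volumes), get = function(i) volumes[[i]])
  }
}

#' Detection sensitivity and volumes under increasing interscan distance
#'
#' For each decimation factor, `sensitivityByIsd()` reports the fraction of
#' reference-positive eyes (any biomarker voxel in the full volume) whose
#' decimated volume still contains at least one biomarker voxel.
#' `volumesByIsd()` reports per-eye border-corrected volume estimates for
#' each factor and biomarker. Both accept either a list of [SegVolume-class]
#' or, to keep memory flat on large cohorts, a generator `function(i)`
#' returning eye `i` together with `nEyes`.
#'
#' Each eye is read once: per-B-scan voxel counts are precomputed and every
#' factor's presence and volume derive from the counts of the retained
#' scans, which is algebraically identical to decimating first and
#' recounting.
#'
#' @param volumes list of volumes, or `function(i)` with `nEyes`
#' @param biomarker biomarker name
#' @param factors decimation factors (powers of two)
#' @param nEyes cohort size when `volumes` is a function
#' @return named numeric vector of sensitivities, one per factor
#' @export
sensitivityByIsd <- function(volumes, biomarker, factors = c(1L, 2L, 4L, 8L),
                             nEyes = NULL) {
  src <- .asVolumeSource(volumes, nEyes)
  hits <- stats::setNames(numeric(length(factors)), factors)
  nPos <- 0L
  for (i in seq_len(src$n)) {
    v <- src$get(i)
    cnt <- .perScanCounts(v, biomarker)
    if (!any(cnt > 0L)) next
    nPos <- nPos + 1L
    nb <- v@geometry@nBscans
    for (k in seq_along(factors)) {
      f <- as.integer(factors[k])
      if (bitwAnd(f, f - 1L) != 0L || (nb - 1L) %% f != 0L)
        stop("invalid decimation factor ", f, " for ", nb, " B-scans")
      kept <- seq(1L, nb, by = f)
      hits[k] <- hits[k] + any(cnt[kept] > 0L)
    }
  }
  if (nPos == 0L)
    stop("no reference-positive eyes for biomarker '", biomarker,
         "': ISD sensitivity undefined")
  hits / nPos
}

#' @rdname sensitivityByIsd
#' @param biomarkers biomarker names for `volumesByIsd()`
#' @return `volumesByIsd()`: data.frame with columns `eyeId`, `biomarker`,
#'   `factor`, `effectiveIsdUm`, `volumeUm3`
#' @export
volumesByIsd <- function(volumes, biomarkers = .ALL_BIOMARKERS,
                         factors = c(1L, 2L, 4L, 8L), nEyes = NULL) {
  src <- .asVolumeSource(volumes, nEyes)
  out <- list()
  for (i in seq_len(src$n)) {
    v <- src$get(i)
    g <- v@geometry
    for (b in biomarkers) {
      cnt <- .perScanCounts(v, b)
      for (f in as.integer(factors)) {
        kept <- seq(1L, g@nBscans, by = f)
        g2 <- scanGeometryNew(fovX = g@fovX, fovY = g@fovY, isd = g@isd * f,
                              nBscans = length(kept), nAscans = g@nAscans,
                              nDepth = g@nDepth, depthScale = g@depthScale)
        out[[length(out) + 1L]] <- data.frame(
          eyeId = v@eyeId, biomarker = b, factor = f,
          effectiveIsdUm = g@isd * f,
          volumeUm3 = .volumeFromCounts(cnt[kept], g2))
      }
    }
  }
  do.call(rbind, out)
}

#' Mean absolute percentage error between paired volume estimates
#'
#' `MAPE = 100/n * sum(|reference_t - reduced_t| / reference_t)` over pairs
#' with a nonzero reference. Pairs with `reference == 0` are excluded from
#' both the sum and `n` (the percentage error is undefined there); the
#' number of excluded pairs is attached as attribute `"nExcluded"`, the
#' number used as `"n"`.
#'
#' @param reference,reduced paired numeric vectors of volumes
#' @return MAPE in percent, with attributes `n` and `nExcluded`
#' @examples
#' mape(100, 90)               # 10
#' mape(c(100, 200), c(110, 150))  # 17.5
#' @export
mape <- function(reference, reduced) {
  if (length(reference) != length(reduced))
    stop("reference and reduced must be paired (equal length)")
  keep <- reference > 0
  if (!any(keep))
    stop("all reference volumes are zero: MAPE undefined")
  val <- 100 * mean(abs(reference[keep] - reduced[keep]) / reference[keep])
  structure(val, n = sum(keep), nExcluded = sum(!keep))
}

#' MAPE table by ISD level
#'
#' Table-style summary of [mape()] from a [volumesByIsd()] data.frame: rows
#' are decimation factors (> 1), columns biomarkers. Biomarkers with no
#' reference-positive eye get `NA` (rendered "n/a" in reports).
#'
#' @param volDf output of [volumesByIsd()]
#' @return data.frame with columns `factor`, `effectiveIsdUm`, then one
#'   column per biomarker (MAPE in percent)
#' @export
mapeTable <- function(volDf) {
  biomarkers <- unique(volDf$biomarker)
  factors <- sort(unique(volDf$factor))
  factors <- factors[factors > 1L]
  baseIsd <- min(volDf$effectiveIsdUm)
  out <- data.frame(factor = factors, effectiveIsdUm = baseIsd * factors)
  for (b in biomarkers) {
    col <- numeric(length(factors))
    for (k in seq_along(factors)) {
      refd <- volDf[volDf$biomarker == b & volDf$factor == 1L, ]
      redd <- volDf[volDf$biomarker == b & volDf$factor == factors[k], ]
      redd <- redd[match(refd$eyeId, redd$eyeId), ]
      col[k] <- if (!any(refd$volumeUm3 > 0)) NA_real_ else
        as.numeric(mape(refd$volumeUm3, redd$volumeUm3))
    }
    out[[b]] <- col
  }
  out
}
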