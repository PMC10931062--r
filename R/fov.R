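#' Construct a crop window
#'
#' @param widthX,widthY physical crop size (micrometres)
#' @param centerX,centerY crop center (micrometres); `NA` means the
#'   field-of-view center of the map the window is applied to
#' @return a [CropWindow-class]
#' @export
cropWindow <- function(widthX, widthY, centerX = NA_real_,
                       centerY = NA_real_) {
  new("CropWindow", widthX = as.numeric(widthX), widthY = as.numeric(widthY),
      centerX = as.numeric(centerX), centerY = as.numeric(centerY))
}

.resolveWindow <- function(w, g) {
  cx <- if (is.na(w@centerX)) g@fovX / 2 else w@centerX
  cy <- if (is.na(w@centerY)) g@fovY / 2 else w@centerY
  lo <- c(cx - w@widthX / 2, cy - w@widthY / 2)
  hi <- c(cx + w@widthX / 2, cy + w@widthY / 2)
  if (lo[1L] < -1e-9 || lo[2L] < -1e-9 ||
      hi[1L] > g@fovX + 1e-9 || hi[2L] > g@fovY + 1e-9)
    stop(sprintf(
      "crop window [%g, %g] x [%g, %g] um extends outside the %g x %g um FOV",
      lo[1L], hi[1L], lo[2L], hi[2L], g@fovX, g@fovY))
  list(cx = cx, cy = cy)
}

#' Is a biomarker present inside a crop window?
#'
#' `TRUE` iff any presence pixel's physical position lies in the closed
#' rectangle `[cx - wx/2, cx + wx/2] x [cy - wy/2, cy + wy/2]`. Pixel
#' positions are `(x_index * pitch, y_index * isd)` (0-based); boundary ties
#' are included.
#'
#' @param m an [EnFaceMap-class]
#' @param w a [CropWindow-class] lying within the FOV
#' @return logical scalar
#' @export
cropPresence <- function(m, w) {
  g <- m@geometry
  ctr <- .resolveWindow(w, g)
  pos <- which(m@presence == 1L, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(FALSE)
  x <- ascanPositionsUm(g)[pos[, 2L]]
  y <- bscanPositionsUm(g)[pos[, 1L]]
  any(abs(x - ctr$cx) <= w@widthX / 2 & abs(y - ctr$cy) <= w@widthY / 2)
}

#' Detection sensitivity under centered field-of-view crops
#'
#' For every crop size `(wx, wy)` on a `stepUm` grid up to the full field of
#' view (all crops centered on the FOV center, i.e. the fovea of a
#' macula-centered scan), computes the fraction of reference-positive eyes
#' in which the biomarker is still present inside the crop. The reference is
#' the full 6 x 6 mm volume, so the full-size entry is 1 by construction,
#' and eyes negative in the reference never enter the denominator.
#'
#' Internally each eye is reduced to the per-axis distances of its positive
#' pixels from the center, from which detection for all crop sizes follows;
#' this is exactly equivalent to re-scanning every pixel per window.
#'
#' @param maps list of [EnFaceMap-class] for one biomarker and geometry
#' @param stepUm crop size increment (micrometres), default 250
#' @return a [SensitivityMap-class]; `sensitivity(x)` is indexed
#'   `[size_y, size_x]` with sizes as dimnames
#' @export
sensitivityMap <- function(maps, stepUm = 250) {
  if (!length(maps)) stop("empty cohort")
  g <- maps[[1L]]@geometry
  b <- maps[[1L]]@biomarker
  for (m in maps) {
    if (!identical(m@biomarker, b) || !.sameGeometry(m@geometry, g))
      stop("maps must share biomarker and geometry")
  }
  sizesX <- seq(stepUm, g@fovX, by = stepUm)
  if (max(sizesX) < g@fovX) sizesX <- c(sizesX, g@fovX)
  sizesY <- seq(stepUm, g@fovY, by = stepUm)
  if (max(sizesY) < g@fovY) sizesY <- c(sizesY, g@fovY)
  cx <- g@fovX / 2; cy <- g@fovY / 2
  xs <- ascanPositionsUm(g); ys <- bscanPositionsUm(g)
  det <- matrix(0, nrow = length(sizesY), ncol = length(sizesX))
  nPos <- 0L
  for (m in maps) {
    pos <- which(m@presence == 1L, arr.ind = TRUE)
    if (nrow(pos) == 0L) next      # reference-negative: excluded entirely
    nPos <- nPos + 1L
    dx <- abs(xs[pos[, 2L]] - cx)
    dy <- abs(ys[pos[, 1L]] - cy)
    # smallest x-width detecting this eye, per y-size
    minW <- vapply(sizesY, function(wy) {
      el <- dy <= wy / 2
      if (any(el)) 2 * min(dx[el]) else Inf
    }, numeric(1L))
    det <- det + outer(minW, sizesX, `<=`)
  }
  if (nPos == 0L)
    stop("no reference-positive eyes for biomarker '", b,
         "': sensitivity undefined")
  sens <- det / nPos
  dimnames(sens) <- list(sizeY_um = sizesY, sizeX_um = sizesX)
  new("SensitivityMap", sensitivity = sens, stepUm = stepUm, biomarker = b,
      nPositiveReference = nPos)
}

#' Exemplary sensitivities at standard reduced fields of view
#'
#' Pulls the 3 x 3, 2 x 2 and 1 x 1 mm values (plus the full-FOV reference)
#' out of a sensitivity map, the sizes conventionally highlighted when
#' discussing reduced-FOV scanning.
#'
#' @param map a [SensitivityMap-class]
#' @return data.frame with columns `fov`, `sizeUm`, `sensitivity`
#' @export
exemplarySensitivities <- function(map) {
  s <- map@sensitivity
  sizesY <- as.numeric(rownames(s))
  sizesX <- as.numeric(colnames(s))
  pick <- function(um) {
    iy <- match(um, sizesY); ix <- match(um, sizesX)
    if (is.na(iy) || is.na(ix)) NA_real_ else s[iy, ix]
  }
  full <- s[length(sizesY), length(sizesX)]
  data.frame(
    fov = c("full", "3x3 mm", "2x2 mm", "1x1 mm"),
    sizeUm = c(max(sizesX), 3000, 2000, 1000),
    sensitivity = c(full, pick(3000), pick(2000), pick(1000)))
}
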