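#' Aggregate per-eye presence maps into a population heatmap
#'
#' Elementwise mean of the cohort's binarized presence maps, i.e. the
#' fraction of eyes (0..1) in which the biomarker occurs at each en-face
#' location. The denominator is the number of aggregated eyes (the
#' aggregation unit), including biomarker-negative eyes.
#'
#' @param maps non-empty list of [EnFaceMap-class] sharing biomarker and
#'   geometry
#' @return a [PopulationHeatmap-class]
#' @export
aggregateHeatmap <- function(maps) {
  if (!length(maps)) stop("cannot aggregate an empty list of maps")
  b <- maps[[1L]]@biomarker
  g <- maps[[1L]]@geometry
  for (m in maps) {
    if (!identical(m@biomarker, b))
      stop("mixed biomarkers in aggregation: ", b, " vs ", m@biomarker)
    if (!.sameGeometry(m@geometry, g))
      stop("mixed geometries in aggregation (eye ", m@eyeId, ")")
  }
  total <- Reduce(`+`, lapply(maps, slot, "presence"))
  new("PopulationHeatmap", fraction = total / length(maps),
      nEyes = length(maps), biomarker = b, geometry = g)
}

#' Isotropic 2D Gaussian surface
#'
#' Evaluates `A * exp(-((x - muX)^2 + (y - muY)^2) / (2 * sigma^2))`, the
#' model fitted to population heatmaps.
#'
#' @param x,y coordinates (micrometres); recycled as usual
#' @param amplitude amplitude A
#' @param muX,muY center (micrometres)
#' @param sigma isotropic standard deviation (micrometres), > 0
#' @return numeric values of the surface
#' @export
gaussian2d <- function(x, y, amplitude, muX, muY, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  amplitude * exp(-((x - muX)^2 + (y - muY)^2) / (2 * sigma^2))
}

## Intensity-weighted first and second moments of a heatmap in physical
## coordinates; also the initialization of the nonlinear fit. The isotropic
## sigma is the weighted RMS radius divided by sqrt(2) (each axis
## contributes sigma^2 to the radial second moment).
.heatmapMoments <- function(h) {
  fr <- h@fraction
  g <- h@geometry
  x <- ascanPositionsUm(g)[col(fr)]
  y <- bscanPositionsUm(g)[row(fr)]
  w <- as.vector(fr)
  W <- sum(w)
  if (W <= 0) return(list(muX = NA_real_, muY = NA_real_, sigma = NA_real_))
  muX <- sum(w * x) / W
  muY <- sum(w * y) / W
  sigma <- sqrt(sum(w * ((x - muX)^2 + (y - muY)^2)) / (2 * W))
  list(muX = muX, muY = muY, sigma = sigma)
}

#' Moment summary of a population heatmap
#'
#' Intensity-weighted centroid and isotropic spread (weighted RMS radius /
#' sqrt(2)) of a heatmap in physical micrometre coordinates. This is a
#' closed-form, optimizer-free counterpart to [fitGaussian()], useful for
#' initialization and sanity checks.
#'
#' @param h a [PopulationHeatmap-class]
#' @return list with `muX`, `muY`, `sigma` (micrometres)
#' @export
heatmapMoments <- function(h) .heatmapMoments(h)

#' Fit an isotropic 2D Gaussian to a population heatmap
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [gaussian2d()] over all
#' grid points in physical micrometre coordinates, with the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` (SS_tot about the heatmap
#' mean). Initialization is parameter-free: amplitude from the maximum,
#' center from the weighted centroid, sigma from the weighted RMS radius.
#' Bounds `A in [0, 1.5]`, `sigma in (0, max FOV]`, `mu` within the FOV
#' extended by the initial sigma keep the optimizer off degenerate
#' plateaus.
#'
#' A constant heatmap has `SS_tot = 0`; the fit is then degenerate and is
#' reported with `rSquared = NaN` and `converged = FALSE`. An identically
#' zero heatmap is an error (the fit is undefined).
#'
#' @param h a [PopulationHeatmap-class]
#' @param areaWeighted weight pixels by their physical area instead of
#'   equally; on the regular acquisition grid all pixels share one area, so
#'   this has no effect there (flag kept for irregular-grid extensions)
#' @param maxIter maximum Levenberg-Marquardt iterations
#' @return a [GaussianFit-class]
#' @export
fitGaussian <- function(h, areaWeighted = FALSE, maxIter = 200L) {
  fr <- h@fraction
  if (all(fr == 0))
    stop("cannot fit a Gaussian to an identically zero heatmap")
  g <- h@geometry
  df <- data.frame(
    f = as.vector(fr),
    x = ascanPositionsUm(g)[col(fr)],
    y = bscanPositionsUm(g)[row(fr)])
  mom <- .heatmapMoments(h)
  a0 <- max(fr)
  s0 <- max(mom$sigma, pitchXum(g))
  sstot <- sum((df$f - mean(df$f))^2)
  if (sstot == 0) {
    return(new("GaussianFit", amplitude = a0, muX = mom$muX, muY = mom$muY,
               sigma = mom$sigma, rSquared = NaN, converged = FALSE))
  }
  w <- if (areaWeighted) rep(pitchXum(g) * g@isd, nrow(df)) else
    rep(1, nrow(df))
  start <- list(A = a0, muX = mom$muX, muY = mom$muY, sigma = s0)
  lower <- c(A = 0, muX = 0 - s0, muY = 0 - s0, sigma = 1e-3)
  upper <- c(A = 1.5, muX = g@fovX + s0, muY = g@fovY + s0,
             sigma = max(g@fovX, g@fovY))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ A * exp(-((x - muX)^2 + (y - muY)^2) / (2 * sigma^2)),
      data = df, start = start, lower = lower, upper = upper, weights = w,
      control = minpack.lm::nls.lm.control(
        maxiter = maxIter, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- gaussian2d(df$x, df$y, a0, mom$muX, mom$muY, s0)
    r2 <- 1 - sum((df$f - pred)^2) / sstot
    return(new("GaussianFit", amplitude = a0, muX = mom$muX, muY = mom$muY,
               sigma = s0, rSquared = r2, converged = FALSE))
  }
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sstot
  new("GaussianFit", amplitude = unname(cf[["A"]]), muX = unname(cf[["muX"]]),
      muY = unname(cf[["muY"]]), sigma = unname(cf[["sigma"]]),
      rSquared = r2, converged = isTRUE(fit$convInfo$isConv))
}
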