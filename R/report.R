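#' Run configuration for the full analysis
#'
#' @param manifest path to a cohort manifest CSV (see [readManifest()])
#' @param biomarkers fluid biomarkers to analyze
#' @param fovStepUm crop-size increment for the FOV sensitivity map
#' @param isdFactors decimation factors (powers of two)
#' @param outDir output directory, or `NULL` for an in-memory run
#' @param seed seed recorded in the summary (the analysis itself is
#'   deterministic; the seed documents provenance of synthetic inputs)
#' @param logLevel `"info"` or `"quiet"`
#' @return a list of class `octscanRunConfig`
#' @export
runConfig <- function(manifest, biomarkers = .FLUID_BIOMARKERS,
                      fovStepUm = 250, isdFactors = c(1L, 2L, 4L, 8L),
                      outDir = NULL, seed = NA_integer_,
                      logLevel = c("info", "quiet")) {
  structure(list(manifest = manifest, biomarkers = biomarkers,
                 fovStepUm = fovStepUm, isdFactors = as.integer(isdFactors),
                 outDir = outDir, seed = seed,
                 logLevel = match.arg(logLevel)),
            class = "octscanRunConfig")
}

#' @rdname runConfig
#' @param path YAML file mirroring the `runConfig()` arguments
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  runConfig(manifest = y$manifest,
            biomarkers = y$biomarkers %||% .FLUID_BIOMARKERS,
            fovStepUm = y$fov_step_um %||% 250,
            isdFactors = y$isd_factors %||% c(1L, 2L, 4L, 8L),
            outDir = y$out_dir,
            seed = y$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(cfg, ...) {
  if (identical(cfg$logLevel, "info"))
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

.fitAsList <- function(fit) {
  list(amplitude = fit@amplitude, muX_um = fit@muX, muY_um = fit@muY,
       sigma_um = fit@sigma, rSquared = fit@rSquared,
       converged = fit@converged)
}

#' Run the complete scanning-parameter analysis over a cohort
#'
#' Orchestrates the four analyses over a manifest in one streaming pass
#' (each volume is read, orientation-normalized and summarized once): per
#' biomarker, prevalence counts; the population heatmap with its Gaussian
#' fit; the centered-crop FOV sensitivity map with exemplary 3/2/1 mm
#' values; and the ISD ladder (per-factor detection sensitivity, per-eye
#' border-corrected volumes, MAPE table including total retina). Biomarkers
#' with zero reference-positive eyes are marked `"n/a"` rather than
#' erroring. The run is deterministic given manifest plus config.
#'
#' When `outDir` is set, writes `summary.json`, per-biomarker heatmap CSVs,
#' FOV sensitivity CSVs, a per-eye volume CSV and the MAPE table CSV.
#'
#' @param config an `octscanRunConfig` from [runConfig()], or a manifest
#'   path (then default config applies)
#' @return (invisibly) a list with elements `summary` (plain-list summary,
#'   what `summary.json` contains), `heatmaps`, `fovMaps`, `volumes`,
#'   `mape`, `maps`
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- runConfig(config)
  manifest <- if (is.data.frame(config$manifest)) config$manifest else
    readManifest(config$manifest)
  n <- nrow(manifest)
  if (n < 1L) stop("empty manifest")
  biomarkers <- config$biomarkers
  allB <- unique(c(biomarkers, "retina"))
  factors <- config$isdFactors

  maps <- stats::setNames(
    lapply(biomarkers, function(b) vector("list", n)), biomarkers)
  counts <- stats::setNames(
    lapply(allB, function(b) vector("list", n)), allB)
  geom <- NULL
  offenders <- character()
  .log(config, "reading ", n, " volumes")
  for (i in seq_len(n)) {
    v <- mirrorIfLeft(readVolume(manifest$path[i]))
    if (is.null(geom)) geom <- v@geometry
    else if (!.sameGeometry(v@geometry, geom))
      offenders <- c(offenders, manifest$eye_id[i])
    cca <- .columnCountArray(v)             # one pass for all biomarkers
    for (b in biomarkers) {
      codes <- .biomarkerCodes(b)
      cc <- rowSums(cca[, , codes + 1L, drop = FALSE], dims = 2L)
      storage.mode(cc) <- "integer"
      maps[[b]][[i]] <- binarize(new("ColumnCountMap", counts = cc,
                                     biomarker = b, eyeId = v@eyeId,
                                     geometry = v@geometry))
    }
    for (b in allB) {
      codes <- .biomarkerCodes(b)
      counts[[b]][[i]] <-
        as.vector(rowSums(cca[, , codes + 1L, drop = FALSE], dims = 1L))
    }
  }
  if (length(offenders))
    stop("cohort is not geometrically homogeneous; offending eyes: ",
         paste(offenders, collapse = ", "))
  for (f in factors) {
    if (bitwAnd(f, f - 1L) != 0L || (geom@nBscans - 1L) %% f != 0L)
      stop("factor ", f, " invalid for ", geom@nBscans, " B-scans")
  }

  .log(config, "prevalence and heatmaps")
  prevalence <- lapply(maps, function(ms) {
    k <- sum(vapply(ms, function(m) any(m@presence == 1L), logical(1L)))
    list(nPositive = k, nEyes = n, percent = 100 * k / n)
  })
  heatmaps <- lapply(maps, aggregateHeatmap)
  fits <- lapply(heatmaps, function(h) {
    if (all(h@fraction == 0)) NULL else fitGaussian(h)
  })

  .log(config, "FOV sensitivity maps")
  fovMaps <- lapply(maps, function(ms) {
    pos <- vapply(ms, function(m) any(m@presence == 1L), logical(1L))
    if (!any(pos)) NULL else sensitivityMap(ms, stepUm = config$fovStepUm)
  })

  .log(config, "ISD analysis")
  isdSens <- lapply(biomarkers, function(b) {
    anyPos <- any(vapply(counts[[b]], function(cc) any(cc > 0L), logical(1L)))
    if (!anyPos) return(NULL)
    hits <- stats::setNames(numeric(length(factors)), factors)
    nPos <- 0L
    for (cc in counts[[b]]) {
      if (!any(cc > 0L)) next
      nPos <- nPos + 1L
      for (k in seq_along(factors)) {
        kept <- seq(1L, geom@nBscans, by = factors[k])
        hits[k] <- hits[k] + any(cc[kept] > 0L)
      }
    }
    hits / nPos
  })
  names(isdSens) <- biomarkers

  volRows <- list()
  for (b in allB) {
    for (i in seq_len(n)) {
      cc <- counts[[b]][[i]]
      for (f in factors) {
        kept <- seq(1L, geom@nBscans, by = f)
        g2 <- scanGeometryNew(fovX = geom@fovX, fovY = geom@fovY,
                              isd = geom@isd * f, nBscans = length(kept),
                              nAscans = geom@nAscans, nDepth = geom@nDepth,
                              depthScale = geom@depthScale)
        volRows[[length(volRows) + 1L]] <- data.frame(
          eyeId = manifest$eye_id[i], biomarker = b, factor = f,
          effectiveIsdUm = geom@isd * f,
          volumeUm3 = .volumeFromCounts(cc[kept], g2))
      }
    }
  }
  volumes <- do.call(rbind, volRows)
  mapeTab <- mapeTable(volumes)

  summary <- list(
    nEyes = n,
    geometry = list(fov_x_um = geom@fovX, fov_y_um = geom@fovY,
                    isd_um = geom@isd, n_bscans = geom@nBscans,
                    n_ascans = geom@nAscans, n_depth = geom@nDepth,
                    depth_scale_um = geom@depthScale),
    prevalence = prevalence,
    heatmapFit = lapply(fits, function(f)
      if (is.null(f)) "n/a" else .fitAsList(f)),
    fov = lapply(fovMaps, function(sm) {
      if (is.null(sm)) return("n/a")
      ex <- exemplarySensitivities(sm)
      list(nPositiveReference = sm@nPositiveReference,
           exemplary = stats::setNames(as.list(ex$sensitivity), ex$fov))
    }),
    isd = list(
      factors = factors,
      effectiveIsdUm = geom@isd * factors,
      sensitivity = lapply(isdSens, function(s)
        if (is.null(s)) "n/a" else as.list(s)),
      mape = lapply(stats::setNames(nm = setdiff(names(mapeTab),
                                                 c("factor", "effectiveIsdUm"))),
                    function(b) {
        vals <- mapeTab[[b]]
        stats::setNames(lapply(vals, function(x)
          if (is.na(x)) "n/a" else x), mapeTab$effectiveIsdUm)
      })
    ))

  bundle <- list(summary = summary, heatmaps = heatmaps, fovMaps = fovMaps,
                 volumes = volumes, mape = mapeTab, maps = maps,
                 geometry = geom)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    for (b in biomarkers) {
      utils::write.csv(heatmaps[[b]]@fraction,
                       file.path(config$outDir, paste0("heatmap_", b, ".csv")),
                       row.names = FALSE)
      if (!is.null(fovMaps[[b]]))
        utils::write.csv(fovMaps[[b]]@sensitivity,
                         file.path(config$outDir, paste0("fov_", b, ".csv")),
                         row.names = FALSE)
    }
    utils::write.csv(volumes, file.path(config$outDir, "volumes.csv"),
                     row.names = FALSE)
    mt <- mapeTab
    for (nm in setdiff(names(mt), c("factor", "effectiveIsdUm")))
      mt[[nm]] <- ifelse(is.na(mt[[nm]]), "n/a", format(mt[[nm]]))
    utils::write.csv(mt, file.path(config$outDir, "mape.csv"),
                     row.names = FALSE)
    .log(config, "wrote outputs to ", config$outDir)
  }
  invisible(bundle)
}

.etdrsCircles <- function(cx, cy) {
  th <- seq(0, 2 * pi, length.out = 181L)
  do.call(rbind, lapply(c(500, 1500, 3000), function(r)
    data.frame(ring = r, x = cx + r * cos(th), y = cy + r * sin(th))))
}

#' Render figures for a run bundle
#'
#' Writes, per biomarker: the population heatmap with an ETDRS grid overlay
#' (1/3/6 mm circles centered on the fovea; each biomarker gets its own
#' color scale spanning `[0, max fraction]`), the FOV sensitivity map with
#' red exemplar squares at 3/2/1 mm, the ISD sensitivity line, and relative
#' volume boxplots (reduced / reference, reference-positive eyes). Sections
#' with no positive eyes are skipped with a log notice; individual figure
#' failures are logged and non-fatal.
#'
#' @param bundle result of [runAll()]
#' @param dir output directory for PNG files
#' @return (invisibly) character vector of files written
#' @export
renderFigures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- bundle$geometry
  written <- character()
  emit <- function(name, plot, width = 6, height = 5) {
    f <- file.path(dir, paste0(name, ".png"))
    tryCatch({
      ggplot2::ggsave(f, plot, width = width, height = height, dpi = 120)
      written <<- c(written, f)
    }, error = function(e)
      message("figure '", name, "' failed (non-fatal): ",
              conditionMessage(e)))
  }
  for (b in names(bundle$heatmaps)) {
    h <- bundle$heatmaps[[b]]
    if (all(h@fraction == 0)) {
      message("heatmap figure skipped for ", b, ": no positive eyes")
      next
    }
    df <- data.frame(x = ascanPositionsUm(g)[col(h@fraction)],
                     y = bscanPositionsUm(g)[row(h@fraction)],
                     f = as.vector(h@fraction))
    rings <- .etdrsCircles(g@fovX / 2, g@fovY / 2)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$f)) +
      ggplot2::geom_path(data = rings,
                         ggplot2::aes(group = .data$ring), color = "white",
                         linewidth = 0.4) +
      ggplot2::scale_fill_viridis_c(limits = c(0, max(h@fraction)),
                                    name = "fraction") +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = paste0(b, " occurrence heatmap (n=", h@nEyes,
                                   " eyes)"),
                    x = "x (um, +x nasal)", y = "y (um)")
    emit(paste0("heatmap_", b), p)
  }
  for (b in names(bundle$fovMaps)) {
    sm <- bundle$fovMaps[[b]]
    if (is.null(sm)) next
    s <- sm@sensitivity
    df <- data.frame(
      wx = as.numeric(colnames(s))[col(s)],
      wy = as.numeric(rownames(s))[row(s)],
      sens = as.vector(s))
    sq <- data.frame(w = c(3000, 2000, 1000))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wx, y = .data$wy)) +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$sens)) +
      ggplot2::geom_point(data = sq,
                          ggplot2::aes(x = .data$w, y = .data$w),
                          color = "red", shape = 0, size = 3, stroke = 1.2) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "sensitivity") +
      ggplot2::labs(title = paste0(b, " detection sensitivity by crop size"),
                    x = "crop width x (um)", y = "crop width y (um)")
    emit(paste0("fov_", b), p)
  }
  sens <- bundle$summary$isd$sensitivity
  isdUm <- bundle$summary$isd$effectiveIsdUm
  for (b in names(sens)) {
    if (identical(sens[[b]], "n/a")) next
    sdf <- data.frame(isd = isdUm, sens = unlist(sens[[b]]))
    vb <- bundle$volumes[bundle$volumes$biomarker == b, ]
    ref <- vb[vb$factor == 1L, c("eyeId", "volumeUm3")]
    names(ref)[2L] <- "refVol"
    vb <- merge(vb, ref, by = "eyeId")
    vb <- vb[vb$refVol > 0, ]
    vb$rel <- vb$volumeUm3 / vb$refVol
    p <- ggplot2::ggplot(vb, ggplot2::aes(x = factor(.data$effectiveIsdUm),
                                          y = .data$rel)) +
      ggplot2::geom_boxplot(outlier.color = "grey40",
                            color = "grey20",
                            fill = "grey90",
                            fatten = 1.5) +
      ggplot2::geom_line(data = sdf,
                         ggplot2::aes(x = factor(.data$isd), y = .data$sens,
                                      group = 1), color = "black") +
      ggplot2::geom_point(data = sdf,
                          ggplot2::aes(x = factor(.data$isd),
                                       y = .data$sens), color = "black") +
      ggplot2::labs(title = paste0(b, ": sensitivity and relative volume vs ISD"),
                    x = "interscan distance (um)",
                    y = "sensitivity / relative volume")
    emit(paste0("isd_", b), p)
  }
  invisible(written)
}
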