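## Container I/O. Geometry always comes from the JSON sidecar, never from
## container headers (exporters disagree about header conventions); the
## container carries only the label voxels.

.SIDE_FIELDS <- c("fov_x_um", "fov_y_um", "isd_um", "n_bscans", "n_ascans",
                  "n_depth", "depth_scale_um", "laterality", "disease",
                  "eye_id")

.volumeStem <- function(path) {
  sub("\\.(nii\\.gz|nii|tiff|tif)$", "", path, ignore.case = TRUE)
}

.containerKind <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("unsupported container '", path,
       "': expected .nii, .nii.gz, .tif or .tiff")
}

.sidecarPath <- function(path) paste0(.volumeStem(path), ".json")

#' Read a labeled OCT volume
#'
#' Reads a NIfTI (`.nii`, `.nii.gz`) or multipage TIFF label volume together
#' with its mandatory JSON sidecar `<stem>.json`, which carries the scan
#' geometry and eye metadata. The function fails rather than guessing
#' missing geometry, and validates that the stored array matches the
#' declared grid and label set.
#'
#' @param path path to the container file
#' @return a [SegVolume-class]
#' @seealso [writeVolume()] for the exact inverse
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop("missing JSON sidecar '", side,
         "'; geometry is never inferred from container headers")
  meta <- jsonlite::fromJSON(side)
  missing <- setdiff(.SIDE_FIELDS, names(meta))
  if (length(missing))
    stop("sidecar ", side, " lacks required fields: ",
         paste(missing, collapse = ", "))
  g <- scanGeometryNew(fovX = meta$fov_x_um, fovY = meta$fov_y_um,
                       isd = meta$isd_um, nBscans = meta$n_bscans,
                       nAscans = meta$n_ascans, nDepth = meta$n_depth,
                       depthScale = meta$depth_scale_um)
  labels <- switch(.containerKind(path),
    nifti = {
      arr <- RNifti::readNifti(path)
      a <- array(as.integer(arr), dim = dim(arr))
      a
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      arr <- array(0L, dim = c(length(pages), dim(pages[[1L]])))
      for (i in seq_along(pages))
        arr[i, , ] <- as.integer(round(pages[[i]] * 255))
      arr
    })
  if (!identical(dim(labels), c(g@nBscans, g@nDepth, g@nAscans)))
    stop("container shape (", paste(dim(labels), collapse = ", "),
         ") does not match sidecar geometry (",
         paste(c(g@nBscans, g@nDepth, g@nAscans), collapse = ", "), ")")
  if (any(labels < 0L) || any(labels > 4L))
    stop("unknown label code in ", path, ": labels must be in {0,1,2,3,4}")
  segVolumeNew(labels, g, eyeId = meta$eye_id, laterality = meta$laterality,
               disease = meta$disease)
}

#' Write a labeled OCT volume
#'
#' Writes the container plus a JSON sidecar such that [readVolume()] inverts
#' it bit-exactly for the labels and exactly for the geometry fields.
#' Laterality is recorded unchanged; orientation normalization is never
#' applied at I/O time.
#'
#' @param v a [SegVolume-class]
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`
#' @return `path`, invisibly
#' @export
writeVolume <- function(v, path) {
  validObject(v)
  g <- v@geometry
  kind <- .containerKind(path)
  if (kind == "nifti") {
    RNifti::writeNifti(v@labels, path, datatype = "int16")
  } else {
    pages <- lapply(seq_len(g@nBscans),
                    function(i) v@labels[i, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  }
  meta <- list(fov_x_um = g@fovX, fov_y_um = g@fovY, isd_um = g@isd,
               n_bscans = g@nBscans, n_ascans = g@nAscans,
               n_depth = g@nDepth, depth_scale_um = g@depthScale,
               laterality = v@laterality, disease = v@disease,
               eye_id = v@eyeId)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest is a plain CSV with header `eye_id,path,laterality,disease`;
#' relative paths are resolved against the manifest's directory. A companion
#' `<manifest>.json` (optional) carries free-text provenance and, for
#' synthetic cohorts, the generation seed; when present they are attached as
#' attributes `provenance` and `seed`.
#'
#' @param path manifest CSV path
#' @return a data.frame with columns `eye_id`, `path`, `laterality`,
#'   `disease`
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "path", "laterality", "disease")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(m$eye_id))
    stop("manifest eye_ids must be unique")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    attr(m, "provenance") <- meta$provenance
    attr(m, "seed") <- meta$seed
  }
  m
}

#' @rdname readManifest
#' @param manifest data.frame with the manifest columns
#' @param provenance free-text source note
#' @param seed generation seed for synthetic cohorts (or `NULL`)
#' @export
writeManifest <- function(manifest, path, provenance = "unspecified",
                          seed = NULL) {
  if (anyDuplicated(manifest$eye_id))
    stop("manifest eye_ids must be unique")
  utils::write.csv(
    manifest[, c("eye_id", "path", "laterality", "disease")],
    path, row.names = FALSE, quote = FALSE)
  meta <- list(provenance = provenance)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta,
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
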