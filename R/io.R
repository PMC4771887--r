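#' Write / read projection sets
#'
#' Two on-disk layouts:
#' * `"rds"` (default): a single R serialization file; lossless for
#'   intensities, geometry, and flat-field metadata.
#' * `"tiff"`: a multi-page 32-bit float TIFF (one page per view) whose
#'   samples are intensities divided by a scale factor, plus a JSON
#'   sidecar `<path>.json` carrying the geometry, the flat-field
#'   intensity, and the scale.  Interoperable, but limited to float32
#'   precision.
#'
#' @param proj A [projection_set()].
#' @param path Output path (`.rds` or `.tif`/`.tiff`).
#' @param format `"rds"` or `"tiff"`; inferred from the extension when
#'   missing.
#' @return `read_projections` returns a [projection_set()].
#' @export
write_projections <- function(proj, path, format = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  format <- format %||% infer_format(path)
  if (format == "rds") {
    saveRDS(proj, path)
  } else if (format == "tiff") {
    scale <- max(proj$intensity, 1e-12)
    pages <- lapply(seq_len(n_views(proj)),
                    function(v) proj$intensity[, , v] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(i0 = proj$i0, kind = proj$kind, scale = scale,
                 geometry = unclass(proj$geometry))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("unknown format: ", format)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such projection file: ", path)
  format <- format %||% infer_format(path)
  if (format == "rds") {
    proj <- tryCatch(readRDS(path),
                     error = function(e) stop("corrupted projection file: ",
                                              path, " (", conditionMessage(e),
                                              ")"))
    if (!inherits(proj, "projection_set"))
      stop("file does not contain a projection set: ", path)
    return(proj)
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar (flat-field intensity, geometry): ",
         meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$i0))
    stop("metadata sidecar lacks the flat-field intensity i0: ", meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (v in seq_along(pages)) arr[, , v] <- pages[[v]] * meta$scale
  g <- meta$geometry
  geom <- acquisition_geometry(g$dso, g$dsd, g$pitch, g$det_rows,
                               g$det_cols, angles_deg = g$angles_deg)
  projection_set(arr, geom, meta$i0, kind = meta$kind %||% "measured")
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") "rds"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("cannot infer projection format from extension: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
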