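#' Raster file input/output
#'
#' Single-band rasters are written as 32-bit float TIFF. Georeferencing (an
#' affine transform and a CRS tag) plus a value scale/offset are carried in a
#' JSON sidecar (`<path>.aux.json`): the TIFF container stores samples in
#' [0, 1], so values are min-max normalised on write and restored exactly (at
#' float32 precision) on read. Round-trips preserve values, dimensions, and
#' georeference.
#'
#' @name raster_io
NULL

#' Write a layer (or raster) to a float32 TIFF + sidecar
#'
#' @param layer a `gl_layer` or `gl_raster`.
#' @param path output path (`.tif`).
#' @param georef optional list(transform = c(x0, dx, y0, dy), crs = "tag").
#' @export
write_raster_tiff <- function(layer, path, georef = NULL) {
  r <- if (inherits(layer, "gl_layer")) layer$raster else gl_raster(layer)
  rng <- range(r)
  scale <- if (diff(rng) == 0) 1 else diff(rng)
  norm <- (unclass(r) - rng[1]) / scale
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  aux <- list(offset = rng[1], scale = scale,
              nrows = nrow(r), ncols = ncol(r),
              name = if (inherits(layer, "gl_layer")) layer$name else "raster",
              georef = georef)
  jsonlite::write_json(aux, paste0(path, ".aux.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a float32 TIFF (+ sidecar) back into a layer
#'
#' @param path TIFF path written by [write_raster_tiff()].
#' @param roles roles to assign the layer.
#' @return a `gl_layer` with attribute `"georef"` when present.
#' @export
read_raster_tiff <- function(path, roles = character()) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  norm <- tiff::readTIFF(path)
  if (length(dim(norm)) == 3) norm <- norm[, , 1]
  aux_path <- paste0(path, ".aux.json")
  offset <- 0; scale <- 1; nm <- "raster"; georef <- NULL
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
    offset <- aux$offset; scale <- aux$scale
    nm <- aux$name
    if (!is.null(aux$georef) && length(aux$georef)) georef <- aux$georef
  }
  lyr <- gl_layer(gl_raster(norm * scale + offset), name = nm, roles = roles)
  attr(lyr, "georef") <- georef
  lyr
}

#' Attach a file-based layer to a landscape
#'
#' @param landscape a `gl_landscape`.
#' @param path raster file path.
#' @param roles roles for the new layer.
#' @export
attach_raster_layer <- function(landscape, path, roles = character()) {
  lyr <- read_raster_tiff(path, roles = roles)
  if (!all(dim(lyr$raster) == landscape$dims)) {
    stop(sprintf("raster dims (%d x %d) do not match landscape dims (%d x %d)",
                 nrow(lyr$raster), ncol(lyr$raster),
                 landscape$dims[1], landscape$dims[2]))
  }
  landscape$layers[[lyr$name]] <- lyr
  landscape
}
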