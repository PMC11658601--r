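#' Read and write reflectance rasters as TIFF
#'
#' Rasters are stored as 32-bit multi-page TIFF files (one page per
#' band). The TIFF backend stores samples in \[0, 1\], so each band is
#' affinely mapped into \[0.1, 1\] (missing pixels encoded as 0) with the
#' per-band offset/scale, the geotransform and the band names recorded
#' in a JSON sidecar (`<path>.json`); reading inverts the map. Values
#' round-trip to 32-bit float precision. The in-memory row order (row 1
#' = field origin, y increasing) is flipped to image order on disk.
#'
#' @param raster an [ms_raster()].
#' @param path output TIFF path.
#' @return `write_ms_raster` returns `path` invisibly; `read_ms_raster`
#'   an [ms_raster()].
#' @export
write_ms_raster <- function(raster, path) {
  stopifnot(inherits(raster, "ms_raster"))
  d <- dim(raster$bands[[1]])
  offset <- scale <- numeric(length(raster$bands))
  pages <- vector("list", length(raster$bands))
  for (i in seq_along(raster$bands)) {
    m <- raster$bands[[i]][d[1]:1, , drop = FALSE]
    rng <- range(m, na.rm = TRUE, finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    offset[i] <- rng[1]
    scale[i] <- max(rng[2] - rng[1], 1e-12)
    enc <- 0.1 + 0.9 * (m - offset[i]) / scale[i]
    enc[enc > 1] <- 1            # guard float round-off at the range maximum
    enc[is.na(enc)] <- 0
    pages[[i]] <- enc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(bands = names(raster$bands), x0 = raster$x0, y0 = raster$y0,
         res = raster$res, offset = offset, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ms_raster
#' @export
read_ms_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  bands <- list()
  for (i in seq_along(meta$bands)) {
    enc <- pages[[i]]
    m <- meta$offset[i] + (enc - 0.1) / 0.9 * meta$scale[i]
    m[enc < 0.05] <- NA
    bands[[meta$bands[i]]] <- m[nrow(m):1, , drop = FALSE]
  }
  ms_raster(bands, meta$x0, meta$y0, meta$res)
}
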