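#' Multispectral raster container
#'
#' A five-band reflectance raster in the field coordinate frame. Bands
#' are matrices (rows = y cells from the field origin upward, cols = x
#' cells); the geotransform maps pixel (row, col) centers to meters:
#' x = x0 + (col - 0.5) * res, y = y0 + (row - 0.5) * res. Reflectances
#' lie in \[0, 1\]; missing pixels are NA.
#'
#' @param bands named list of equal-shaped matrices; names must be
#'   blue, green, red, red_edge, nir for a full stack (a single-band
#'   raster, e.g. a computed index, is also accepted).
#' @param x0,y0 field coordinates of the raster's lower-left corner (m).
#' @param res pixel edge in meters (> 0).
#' @return An object of class `ms_raster`.
#' @export
ms_raster <- function(bands, x0 = 0, y0 = 0, res = 0.05) {
  if (res <= 0) stop("resolution must be > 0", call. = FALSE)
  dims <- vapply(bands, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("band shapes must be equal", call. = FALSE)
  structure(list(bands = bands, x0 = x0, y0 = y0, res = res),
            class = "ms_raster")
}

MS_BANDS <- c("blue", "green", "red", "red_edge", "nir")

#' @export
print.ms_raster <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("Raster: %d x %d px at %.3g m (%s)\n", d[1], d[2], x$res,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Canopy optics configuration
#'
#' Maps the generator's per-plot nitrogen status (a unitless score in
#' \[0, 1\]) to canopy band reflectances through affine responses that are
#' monotone in status: NIR and red-edge reflectance rise with nitrogen
#' status while red reflectance falls (healthy, nitrogen-rich canopies
#' absorb more red and scatter more NIR). Pixels outside plots take the
#' soil spectrum. Gaussian pixel noise is added per band and the result
#' clamped to \[0, 1\].
#'
#' @param soil named reflectances of bare soil.
#' @param canopy_base,canopy_gain named vectors: canopy reflectance in
#'   band b is `canopy_base[b] + canopy_gain[b] * status`.
#' @param noise_sd pixel noise SD (reflectance units).
#' @param res pixel size in meters.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(
    soil = c(blue = 0.08, green = 0.12, red = 0.18, red_edge = 0.22, nir = 0.25),
    canopy_base = c(blue = 0.05, green = 0.10, red = 0.18, red_edge = 0.28, nir = 0.25),
    canopy_gain = c(blue = 0.00, green = 0.06, red = -0.10, red_edge = 0.20, nir = 0.30),
    noise_sd = 0.01, res = 0.05) {
  if (res <= 0) stop("resolution must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  stopifnot(all(MS_BANDS %in% names(soil)),
            all(MS_BANDS %in% names(canopy_base)),
            all(MS_BANDS %in% names(canopy_gain)))
  if (any(canopy_gain[c("nir", "red_edge")] < 0) || canopy_gain["red"] > 0)
    stop("optics must be monotone: NIR/red-edge gains >= 0, red gain <= 0",
         call. = FALSE)
  structure(list(soil = soil, canopy_base = canopy_base,
                 canopy_gain = canopy_gain, noise_sd = noise_sd, res = res),
            class = "optics_config")
}

#' Generate a five-band multispectral raster for one acquisition day
#'
#' @param layout a `field_layout`.
#' @param traits_at_day data.frame with plot_id and nitrogen_status
#'   covering every plot (one day of a `true_trait_table`).
#' @param optics an [optics_config()].
#' @param seed integer seed.
#' @return An [ms_raster()] with the five standard bands.
#' @export
generate_multispectral_raster <- function(layout, traits_at_day,
                                          optics = optics_config(), seed = 1L) {
  stopifnot(inherits(layout, "field_layout"), inherits(optics, "optics_config"))
  i <- match(layout$plots$plot_id, traits_at_day$plot_id)
  if (anyNA(i)) stop("traits_at_day must cover every plot", call. = FALSE)
  status <- traits_at_day$nitrogen_status[i]
  set.seed(as.integer(seed))
  ext <- layout$extent
  nx <- ceiling((ext["xmax"] - ext["xmin"]) / optics$res)
  ny <- ceiling((ext["ymax"] - ext["ymin"]) / optics$res)
  xc <- ext["xmin"] + (seq_len(nx) - 0.5) * optics$res
  yc <- ext["ymin"] + (seq_len(ny) - 0.5) * optics$res
  bands <- list()
  plots <- layout$plots
  # pixel-center membership per plot (half-open rectangles)
  masks <- lapply(seq_len(nrow(plots)), function(p) {
    cols <- which(xc >= plots$xmin[p] & xc < plots$xmax[p])
    rows <- which(yc >= plots$ymin[p] & yc < plots$ymax[p])
    as.vector(outer(rows, (cols - 1L) * ny, `+`))
  })
  for (b in MS_BANDS) {
    m <- matrix(optics$soil[b], ny, nx)
    for (p in seq_len(nrow(plots)))
      m[masks[[p]]] <- optics$canopy_base[b] + optics$canopy_gain[b] * status[p]
    if (optics$noise_sd > 0)
      m <- m + matrix(stats::rnorm(ny * nx, 0, optics$noise_sd), ny, nx)
    m[m < 0] <- 0; m[m > 1] <- 1
    bands[[b]] <- m
  }
  ms_raster(bands, x0 = unname(ext["xmin"]), y0 = unname(ext["ymin"]),
            res = optics$res)
}

#' Vegetation-index parameters
#'
#' `ndre_min`/`ndre_max` are the fixed endpoints of the affine map from
#' NDRE to CCCI (defaults 0.24 and 0.61). `ndre_band` selects the band
#' used in the NDRE numerator/denominator against NIR: `"red"` follows
#' the formulation used for the CCCI here, `"red_edge"` the conventional
#' red-edge definition. `clip_ccci` optionally clips CCCI into \[0, 1\];
#' the default leaves it unclipped so seasonal dynamics outside the
#' calibration range survive for curve fitting.
#'
#' @param ndre_min,ndre_max CCCI calibration endpoints, `ndre_min <
#'   ndre_max`.
#' @param ndre_band `"red"` or `"red_edge"`.
#' @param clip_ccci logical.
#' @return An object of class `vi_params`.
#' @export
vi_params <- function(ndre_min = 0.24, ndre_max = 0.61,
                      ndre_band = c("red", "red_edge"), clip_ccci = FALSE) {
  if (!(ndre_min < ndre_max)) stop("ndre_min must be < ndre_max", call. = FALSE)
  structure(list(ndre_min = ndre_min, ndre_max = ndre_max,
                 ndre_band = match.arg(ndre_band), clip_ccci = clip_ccci),
            class = "vi_params")
}

#' Map NDRE values to CCCI
#'
#' CCCI = (NDRE - NDRE_min) / (NDRE_max - NDRE_min) with the fixed
#' calibration endpoints of [vi_params()].
#'
#' @param ndre numeric NDRE values.
#' @param params a [vi_params()].
#' @return CCCI values (clipped to \[0, 1\] when `params$clip_ccci`).
#' @export
ccci_from_ndre <- function(ndre, params = vi_params()) {
  v <- (ndre - params$ndre_min) / (params$ndre_max - params$ndre_min)
  if (params$clip_ccci) {
    v[v < 0] <- 0
    v[v > 1] <- 1
  }
  v
}

#' Compute a vegetation index raster
#'
#' Pixelwise evaluation of one of the supported indices on a five-band
#' reflectance raster:
#' * `NDRE  = (R_nir - R_b) / (R_nir + R_b)` with b the configured NDRE
#'   band (red by default);
#' * `CCCI  = (NDRE - NDRE_min) / (NDRE_max - NDRE_min)`;
#' * `MSAVI = (2 R_nir + 1 - sqrt((2 R_nir + 1)^2 - 8 (R_nir - R_red))) / 2`;
#' * `RVI_1 = R_nir / R_red`; `RVI_2 = R_nir / R_green`.
#'
#' NA pixels propagate; zero denominators (RVI) and NIR + band = 0
#' (NDRE/CCCI) yield NA. The MSAVI discriminant is asserted non-negative
#' (it always is for reflectances in \[0, 1\]).
#'
#' @param raster an [ms_raster()] with the required bands.
#' @param index one of `"NDRE"`, `"CCCI"`, `"MSAVI"`, `"RVI_1"`, `"RVI_2"`.
#' @param params a [vi_params()].
#' @return A single-band [ms_raster()] named after the index.
#' @export
compute_vi <- function(raster, index, params = vi_params()) {
  stopifnot(inherits(raster, "ms_raster"))
  index <- toupper(index)
  need <- function(b) {
    if (is.null(raster$bands[[b]])) stop("raster lacks band: ", b, call. = FALSE)
    raster$bands[[b]]
  }
  v <- switch(index,
    NDRE = , CCCI = {
      nir <- need("nir"); bb <- need(params$ndre_band)
      den <- nir + bb
      ndre <- ifelse(den == 0, NA_real_, (nir - bb) / den)
      if (index == "CCCI") ccci_from_ndre(ndre, params) else ndre
    },
    MSAVI = {
      nir <- need("nir"); red <- need("red")
      disc <- (2 * nir + 1)^2 - 8 * (nir - red)
      if (any(disc < 0, na.rm = TRUE))
        stop("MSAVI discriminant negative; reflectances outside [0, 1]?",
             call. = FALSE)
      (2 * nir + 1 - sqrt(disc)) / 2
    },
    RVI_1 = {
      nir <- need("nir"); red <- need("red")
      ifelse(red == 0, NA_real_, nir / red)
    },
    RVI_2 = {
      nir <- need("nir"); green <- need("green")
      ifelse(green == 0, NA_real_, nir / green)
    },
    stop("unknown vegetation index: ", index, call. = FALSE)
  )
  out <- list()
  out[[index]] <- v
  ms_raster(out, raster$x0, raster$y0, raster$res)
}

#' Build edge-buffered plot pixel masks
#'
#' For each plot, collects the linear pixel indices whose centers fall
#' inside the plot rectangle shrunk by `buffer_m` on all sides (removing
#' marginal pixels contaminated by aisle soil and neighbor overhang).
#' Masks of distinct plots are disjoint by construction.
#'
#' @param layout a `field_layout`.
#' @param raster an [ms_raster()] (supplies geotransform and shape).
#' @param buffer_m non-negative edge buffer in meters (default 0.1).
#' @return A named list of integer pixel-index vectors, one per plot_id;
#'   plots whose buffered rectangle holds no pixel center get an empty
#'   mask with a warning.
#' @export
build_plot_masks <- function(layout, raster, buffer_m = 0.1) {
  stopifnot(inherits(layout, "field_layout"), inherits(raster, "ms_raster"))
  if (buffer_m < 0) stop("buffer_m must be >= 0", call. = FALSE)
  d <- dim(raster$bands[[1]])
  ny <- d[1]; nx <- d[2]
  xc <- raster$x0 + (seq_len(nx) - 0.5) * raster$res
  yc <- raster$y0 + (seq_len(ny) - 0.5) * raster$res
  plots <- layout$plots
  masks <- stats::setNames(vector("list", nrow(plots)), plots$plot_id)
  for (p in seq_len(nrow(plots))) {
    cols <- which(xc >= plots$xmin[p] + buffer_m & xc < plots$xmax[p] - buffer_m)
    rows <- which(yc >= plots$ymin[p] + buffer_m & yc < plots$ymax[p] - buffer_m)
    masks[[p]] <- as.integer(as.vector(outer(rows, (cols - 1L) * ny, `+`)))
    if (length(masks[[p]]) == 0)
      warning("buffer empties plot ", plots$plot_id[p], call. = FALSE)
  }
  attr(masks, "buffer_m") <- buffer_m
  masks
}

#' Plot-level mean of a vegetation index
#'
#' @param vi_raster a single-band [ms_raster()] from [compute_vi()].
#' @param masks plot masks from [build_plot_masks()] built on the same
#'   geotransform.
#' @param day acquisition day recorded in the output.
#' @return data.frame (plot_id, day, index, mean_value, n_pixels); plots
#'   whose mask is empty or all-NA report `NA` with `n_pixels = 0`.
#' @export
plot_mean_vi <- function(vi_raster, masks, day = NA_real_) {
  stopifnot(inherits(vi_raster, "ms_raster"), length(vi_raster$bands) == 1)
  v <- vi_raster$bands[[1]]
  index <- names(vi_raster$bands)
  res <- data.frame(plot_id = names(masks), day = day, index = index,
                    mean_value = NA_real_, n_pixels = 0L,
                    stringsAsFactors = FALSE)
  for (p in seq_along(masks)) {
    px <- v[masks[[p]]]
    px <- px[!is.na(px)]
    res$n_pixels[p] <- length(px)
    if (length(px) > 0) res$mean_value[p] <- mean(px)
  }
  res
}
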