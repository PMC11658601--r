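#' Construct a labeled point cloud
#'
#' The basic container for 3D field scans: an N x 3 coordinate matrix in
#' meters (right-handed, z = elevation), optional per-point RGB colors in
#' [0, 1] and optional per-point class labels (0 = ground, 1 = canopy).
#'
#' @param points numeric N x 3 matrix of finite coordinates.
#' @param colors optional N x 3 matrix in [0, 1].
#' @param labels optional integer vector of length N with values 0/1.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an N x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("point coordinates must be finite", call. = FALSE)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == nrow(points), ncol(colors) == 3)
    dimnames(colors) <- NULL
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(points))
      stop("labels must have one entry per point", call. = FALSE)
  }
  structure(list(points = points, colors = colors, labels = labels),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points%s%s\n", nrow(x$points),
              if (!is.null(x$colors)) ", with colors" else "",
              if (!is.null(x$labels))
                sprintf(", labeled (%d ground / %d canopy)",
                        sum(x$labels == 0L), sum(x$labels == 1L)) else ""))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              if (!is.null(cloud$labels)) cloud$labels[idx])
}

#' Point-cloud generation settings
#'
#' Controls the synthetic scanner: how many canopy points each plot
#' contributes, the areal density of ground returns, vertical spread of
#' the canopy surface around the true height, ground plane tilt and
#' roughness, and a small fraction of tall "weed" outliers that belong to
#' the ground class (mirroring field practice, where weeds and signs are
#' folded into the ground class during annotation).
#'
#' @param canopy_points_per_plot canopy returns per plot.
#' @param ground_density ground returns per square meter (>= 0).
#' @param canopy_spread_m SD of canopy elevation about the true height (m).
#' @param ground_roughness_m SD of ground micro-relief (m).
#' @param ground_tilt slope of the ground plane, (dz/dx, dz/dy).
#' @param weed_fraction fraction of ground points re-emitted as tall
#'   outliers (labeled ground) in [0, 0.2].
#' @param row_jitter_m SD of canopy point placement across the sown row (m).
#' @return An object of class `cloud_config`.
#' @export
cloud_config <- function(canopy_points_per_plot = 400,
                         ground_density = 150,
                         canopy_spread_m = 0.05,
                         ground_roughness_m = 0.01,
                         ground_tilt = c(0, 0),
                         weed_fraction = 0.005,
                         row_jitter_m = 0.04) {
  if (ground_density < 0 || canopy_points_per_plot < 0)
    stop("point densities must be non-negative", call. = FALSE)
  if (canopy_spread_m < 0 || ground_roughness_m < 0)
    stop("spreads must be non-negative", call. = FALSE)
  if (weed_fraction < 0 || weed_fraction > 0.2)
    stop("weed_fraction must lie in [0, 0.2]", call. = FALSE)
  structure(list(canopy_points_per_plot = as.integer(canopy_points_per_plot),
                 ground_density = ground_density,
                 canopy_spread_m = canopy_spread_m,
                 ground_roughness_m = ground_roughness_m,
                 ground_tilt = ground_tilt,
                 weed_fraction = weed_fraction,
                 row_jitter_m = row_jitter_m),
            class = "cloud_config")
}

ground_plane_z <- function(cfg, x, y) cfg$ground_tilt[1] * x + cfg$ground_tilt[2] * y

#' Generate a labeled field point cloud for one acquisition day
#'
#' Emits ground returns over the whole field (a tilted plane plus
#' roughness; between-row soil is visible to the scanner even inside
#' plots), canopy returns confined to plot rectangles and concentrated
#' around the sown rows with elevation ground + true height + vertical
#' spread (truncated below at the ground), and optionally sparse tall
#' weed outliers labeled ground. Ground color is a brown soil spectrum,
#' canopy a green one; both carry per-point color noise.
#'
#' @param layout a `field_layout`.
#' @param traits_at_day data.frame with columns plot_id and true_height_cm
#'   covering every plot (e.g. one day of a `true_trait_table`).
#' @param cfg a [cloud_config()].
#' @param seed integer seed.
#' @return A labeled [point_cloud()] with attribute `"plot_of_point"`, the
#'   plot_id each canopy point was drawn for (NA for ground).
#' @export
generate_field_cloud <- function(layout, traits_at_day, cfg = cloud_config(),
                                 seed = 1L) {
  stopifnot(inherits(layout, "field_layout"), inherits(cfg, "cloud_config"))
  plots <- layout$plots
  i <- match(plots$plot_id, traits_at_day$plot_id)
  if (anyNA(i)) stop("traits_at_day must cover every plot in the layout", call. = FALSE)
  h_m <- traits_at_day$true_height_cm[i] / 100
  set.seed(as.integer(seed))

  ext <- layout$extent
  area <- (ext["xmax"] - ext["xmin"]) * (ext["ymax"] - ext["ymin"])
  n_ground <- as.integer(round(cfg$ground_density * area))
  gx <- stats::runif(n_ground, ext["xmin"], ext["xmax"])
  gy <- stats::runif(n_ground, ext["ymin"], ext["ymax"])
  gz <- ground_plane_z(cfg, gx, gy) + stats::rnorm(n_ground, 0, cfg$ground_roughness_m)

  npp <- cfg$canopy_points_per_plot
  rows_y <- function(p) {
    # canopy mass sits on the sown rows, spaced across the plot width
    k <- layout$design$n_rows_per_plot
    sp <- layout$design$row_spacing_m
    y0 <- (plots$ymin[p] + plots$ymax[p]) / 2 - sp * (k - 1) / 2
    y0 + sp * (sample.int(k, npp, replace = TRUE) - 1)
  }
  cx <- cy <- cz <- numeric(0)
  plot_of <- character(0)
  for (p in seq_len(nrow(plots))) {
    x <- stats::runif(npp, plots$xmin[p], plots$xmax[p])
    y <- rows_y(p) + stats::rnorm(npp, 0, cfg$row_jitter_m)
    y <- pmin(pmax(y, plots$ymin[p]), plots$ymax[p] - 1e-9)
    gz0 <- ground_plane_z(cfg, x, y)
    dz <- h_m[p] + stats::rnorm(npp, 0, cfg$canopy_spread_m)
    dz <- pmax(dz, 0)
    cx <- c(cx, x); cy <- c(cy, y); cz <- c(cz, gz0 + dz)
    plot_of <- c(plot_of, rep(plots$plot_id[p], npp))
  }

  n_weed <- as.integer(round(cfg$weed_fraction * n_ground))
  wx <- stats::runif(n_weed, ext["xmin"], ext["xmax"])
  wy <- stats::runif(n_weed, ext["ymin"], ext["ymax"])
  wz <- ground_plane_z(cfg, wx, wy) + stats::runif(n_weed, 0.15, 0.8)

  pts <- cbind(c(gx, cx, wx), c(gy, cy, wy), c(gz, cz, wz))
  labels <- c(rep(0L, n_ground), rep(1L, length(cx)), rep(0L, n_weed))
  soil <- c(0.45, 0.36, 0.25); leaf <- c(0.20, 0.45, 0.18)
  base <- matrix(soil, nrow(pts), 3, byrow = TRUE)
  base[labels == 1L, ] <- matrix(leaf, sum(labels == 1L), 3, byrow = TRUE)
  cols <- base + matrix(stats::rnorm(3 * nrow(pts), 0, 0.04), ncol = 3)
  cols[cols < 0] <- 0; cols[cols > 1] <- 1
  cloud <- point_cloud(pts, cols, labels)
  attr(cloud, "plot_of_point") <- c(rep(NA_character_, n_ground), plot_of,
                                    rep(NA_character_, n_weed))
  cloud
}
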