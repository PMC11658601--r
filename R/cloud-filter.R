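#' Remove statistical outliers from a point cloud
#'
#' Classic statistical outlier removal: for each point the mean distance
#' to its `k_neighbors` nearest neighbors is computed; points whose mean
#' distance exceeds the global mean plus `sigma_mult` standard deviations
#' of that statistic are dropped. Survivor order is preserved.
#'
#' @param cloud a [point_cloud()].
#' @param k_neighbors neighbors per point (>= 1, < number of points).
#' @param sigma_mult positive SD multiplier.
#' @return The filtered [point_cloud()] with attribute `"removed"`, the
#'   indices of removed points.
#' @export
statistical_outlier_removal <- function(cloud, k_neighbors = 8, sigma_mult = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (k_neighbors < 1 || sigma_mult <= 0)
    stop("k_neighbors must be >= 1 and sigma_mult > 0", call. = FALSE)
  if (n <= k_neighbors)
    stop("cloud must contain more than k_neighbors points", call. = FALSE)
  d <- knn_avg_dist(cloud$points, as.integer(k_neighbors))
  keep <- d <= mean(d) + sigma_mult * stats::sd(d)
  out <- subset_cloud(cloud, which(keep))
  attr(out, "removed") <- which(!keep)
  out
}

#' Estimate a ground elevation model from a point cloud
#'
#' The cloud's XY extent is divided into square cells; each nonempty
#' cell's ground elevation is the given low percentile of point
#' elevations within it (soil returns dominate the low tail even under
#' canopy). Empty cells inherit the elevation of the nearest nonempty
#' cell center. This low-percentile grid plays the role a cloth
#' simulation filter plays in interactive tools and matches it on gently
#' varying terrain.
#'
#' @param cloud a [point_cloud()] with at least one point.
#' @param cell_size cell edge in meters (> 0).
#' @param percentile percentile of z used per cell, in (0, 50].
#' @return A `ground_model`: elevation matrix (rows = y cells, cols = x
#'   cells) plus grid origin and cell size.
#' @export
estimate_ground <- function(cloud, cell_size = 0.25, percentile = 5) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("cannot estimate ground from an empty cloud", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (percentile <= 0 || percentile > 50)
    stop("percentile must lie in (0, 50]", call. = FALSE)
  p <- cloud$points
  x0 <- min(p[, 1]); y0 <- min(p[, 2])
  nx <- max(1L, ceiling((max(p[, 1]) - x0) / cell_size + 1e-9))
  ny <- max(1L, ceiling((max(p[, 2]) - y0) / cell_size + 1e-9))
  ix <- pmin(nx, floor((p[, 1] - x0) / cell_size) + 1L)
  iy <- pmin(ny, floor((p[, 2] - y0) / cell_size) + 1L)
  cell <- (ix - 1L) * ny + iy
  elev <- matrix(NA_real_, ny, nx)
  q <- tapply(p[, 3], cell, stats::quantile, probs = percentile / 100,
              names = FALSE, type = 7)
  elev[as.integer(names(q))] <- q
  # nearest-cell fill for empty cells
  if (anyNA(elev)) {
    filled <- which(!is.na(elev), arr.ind = TRUE)
    empty <- which(is.na(elev), arr.ind = TRUE)
    near <- knn_query_cpp(cbind(filled[, 2], filled[, 1], 0),
                          cbind(empty[, 2], empty[, 1], 0), 1L)
    elev[empty] <- elev[filled[near$idx[, 1], , drop = FALSE]]
  }
  structure(list(elevation = elev, x0 = x0, y0 = y0, cell_size = cell_size),
            class = "ground_model")
}

#' Look up ground elevation under given XY positions
#'
#' @param ground a `ground_model` from [estimate_ground()].
#' @param x,y coordinates in meters.
#' @return Ground elevations in meters (positions outside the grid clamp
#'   to the nearest cell).
#' @export
ground_elevation <- function(ground, x, y) {
  stopifnot(inherits(ground, "ground_model"))
  nx <- ncol(ground$elevation); ny <- nrow(ground$elevation)
  ix <- pmin(nx, pmax(1L, floor((x - ground$x0) / ground$cell_size) + 1L))
  iy <- pmin(ny, pmax(1L, floor((y - ground$y0) / ground$cell_size) + 1L))
  ground$elevation[cbind(iy, ix)]
}

#' Geometric ground/canopy segmentation by height threshold
#'
#' The deterministic baseline segmenter: a point is canopy iff its
#' elevation above the local ground model exceeds `height_threshold_m`.
#'
#' @param cloud a [point_cloud()].
#' @param ground a `ground_model` covering the cloud.
#' @param height_threshold_m threshold in meters (default 0.10).
#' @return Integer labels (0 = ground, 1 = canopy), one per point.
#' @export
segment_geometric <- function(cloud, ground, height_threshold_m = 0.10) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(ground, "ground_model"))
  gz <- ground_elevation(ground, cloud$points[, 1], cloud$points[, 2])
  as.integer(cloud$points[, 3] - gz > height_threshold_m)
}
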