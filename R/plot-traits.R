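#' Crop a point cloud to a plot rectangle
#'
#' Keeps points whose xy position falls inside the plot rectangle shrunk
#' by `margin_m` on all sides, using the half-open convention
#' \[xmin, xmax) x \[ymin, ymax) so adjacent plots never share a point.
#'
#' @param cloud a [point_cloud()].
#' @param plot_rect numeric with names xmin, xmax, ymin, ymax (or a
#'   one-row data.frame with those columns).
#' @param margin_m non-negative shrink margin in meters.
#' @return The cropped [point_cloud()] (possibly empty).
#' @export
crop_to_plot <- function(cloud, plot_rect, margin_m = 0) {
  stopifnot(inherits(cloud, "point_cloud"), margin_m >= 0)
  r <- as.list(plot_rect)
  if (r$xmin > r$xmax || r$ymin > r$ymax)
    stop("invalid plot rectangle", call. = FALSE)
  x <- cloud$points[, 1]; y <- cloud$points[, 2]
  keep <- x >= r$xmin + margin_m & x < r$xmax - margin_m &
    y >= r$ymin + margin_m & y < r$ymax - margin_m
  subset_cloud(cloud, which(keep))
}

#' Per-plot 3D canopy height
#'
#' Aggregates the elevation of canopy-labeled points above the local
#' ground model. The default aggregator is the mean (the plot's average
#' canopy surface height); `"percentile_p"` (e.g. `"percentile_90"`)
#' gives a sorted quantile, more robust to residual soil points.
#'
#' @param plot_cloud a labeled [point_cloud()] cropped to one plot.
#' @param ground a `ground_model` covering the plot.
#' @param aggregator `"mean"` or `"percentile_<p>"`.
#' @return Height in centimeters, or `NA` (with a warning) when the plot
#'   has no canopy-labeled point.
#' @export
canopy_height <- function(plot_cloud, ground, aggregator = "mean") {
  stopifnot(inherits(plot_cloud, "point_cloud"), inherits(ground, "ground_model"))
  can <- !is.null(plot_cloud$labels) & plot_cloud$labels == 1L
  if (!any(can)) {
    warning("plot has no canopy-labeled points; returning NA", call. = FALSE)
    return(NA_real_)
  }
  p <- plot_cloud$points[can, , drop = FALSE]
  h <- p[, 3] - ground_elevation(ground, p[, 1], p[, 2])
  v <- if (identical(aggregator, "mean")) {
    mean(h)
  } else if (grepl("^percentile_[0-9.]+$", aggregator)) {
    pr <- as.numeric(sub("percentile_", "", aggregator))
    stats::quantile(h, pr / 100, names = FALSE)
  } else stop("unknown aggregator: ", aggregator, call. = FALSE)
  100 * v
}

#' Canopy heights for every plot of a layout
#'
#' Convenience wrapper: crops the labeled cloud to each plot rectangle
#' and applies [canopy_height()].
#'
#' @param cloud a labeled [point_cloud()] of the whole field.
#' @param layout a `field_layout`.
#' @param ground a `ground_model`; estimated from the cloud when `NULL`.
#' @param day acquisition day recorded in the output.
#' @param aggregator passed to [canopy_height()].
#' @param margin_m crop margin passed to [crop_to_plot()].
#' @return data.frame (plot_id, day, n_canopy_points, height_cm,
#'   aggregator).
#' @export
plot_heights <- function(cloud, layout, ground = NULL, day = NA_real_,
                         aggregator = "mean", margin_m = 0) {
  stopifnot(inherits(layout, "field_layout"))
  if (is.null(ground)) ground <- estimate_ground(cloud)
  plots <- layout$plots
  out <- data.frame(plot_id = plots$plot_id, day = day,
                    n_canopy_points = 0L, height_cm = NA_real_,
                    aggregator = aggregator, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(plots))) {
    pc <- crop_to_plot(cloud, plots[i, c("xmin", "xmax", "ymin", "ymax")],
                       margin_m)
    out$n_canopy_points[i] <- sum(pc$labels == 1L)
    if (out$n_canopy_points[i] > 0)
      out$height_cm[i] <- canopy_height(pc, ground, aggregator)
    else
      warning("plot ", plots$plot_id[i], " has no canopy points", call. = FALSE)
  }
  out
}

#' Agreement between estimated and reference heights
#'
#' Squared Pearson correlation and root mean square error between paired
#' height vectors; pairs with a missing member are dropped and counted.
#'
#' @param estimated,truth equal-length numeric vectors in cm.
#' @return List with `r2`, `rmse_cm`, `n_used`, `n_dropped`.
#' @export
height_agreement <- function(estimated, truth) {
  if (length(estimated) != length(truth))
    stop("estimated and truth must have equal length", call. = FALSE)
  ok <- is.finite(estimated) & is.finite(truth)
  e <- estimated[ok]; t <- truth[ok]
  if (length(e) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(e) == 0 || stats::sd(t) == 0)
    stop("zero variance in heights; correlation undefined", call. = FALSE)
  list(r2 = stats::cor(e, t)^2,
       rmse_cm = sqrt(mean((e - t)^2)),
       n_used = length(e), n_dropped = sum(!ok))
}
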