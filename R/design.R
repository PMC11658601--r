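#' Define a field trial design
#'
#' A trial design describes the factorial structure and plot geometry of a
#' replicated nitrogen trial: varieties crossed with nitrogen treatments and
#' replicates, fixed rectangular plots sown in parallel rows, and the days
#' after sowing (DAS) at which aerial acquisitions take place.
#'
#' Defaults describe a season-long trial of 160 varieties under three
#' nitrogen levels (N0/N180/N240, applied at 0/180/240 kg N per hectare)
#' with two replicates, 1.5 x 1 m plots holding 5 rows at 20 cm spacing,
#' and 10 acquisition timepoints between early tillering and late grain
#' filling.
#'
#' @param n_varieties number of varieties (>= 1).
#' @param treatments named numeric vector: names are treatment labels,
#'   values the applied nitrogen rate in kg N ha^-1. Labels must be unique.
#' @param n_replicates replicates per variety x treatment combination.
#' @param plot_length_m,plot_width_m plot dimensions in meters.
#' @param n_rows_per_plot number of sown rows per plot.
#' @param row_spacing_m spacing between rows in meters.
#' @param timepoints strictly increasing acquisition days (DAS).
#' @param aisle_m gap between adjacent plots in meters.
#' @param rng_seed integer seed stored with the design.
#'
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_varieties = 160,
                         treatments = c(N0 = 0, N180 = 180, N240 = 240),
                         n_replicates = 2,
                         plot_length_m = 1.5,
                         plot_width_m = 1.0,
                         n_rows_per_plot = 5,
                         row_spacing_m = 0.20,
                         timepoints = c(20, 40, 60, 80, 100, 120, 135, 150, 165, 185),
                         aisle_m = 0.5,
                         rng_seed = 1L) {
  if (n_varieties < 1 || n_replicates < 1 || n_rows_per_plot < 1)
    stop("invalid design: all counts must be >= 1", call. = FALSE)
  if (plot_length_m <= 0 || plot_width_m <= 0 || row_spacing_m <= 0 || aisle_m < 0)
    stop("invalid design: plot dimensions must be positive", call. = FALSE)
  if (length(timepoints) < 1 || any(diff(timepoints) <= 0))
    stop("invalid design: timepoints must be strictly increasing", call. = FALSE)
  if (is.null(names(treatments)) || anyDuplicated(names(treatments)))
    stop("invalid design: treatment labels must be unique and named", call. = FALSE)
  structure(list(
    n_varieties = as.integer(n_varieties),
    treatments = treatments,
    n_replicates = as.integer(n_replicates),
    plot_length_m = plot_length_m,
    plot_width_m = plot_width_m,
    n_rows_per_plot = as.integer(n_rows_per_plot),
    row_spacing_m = row_spacing_m,
    timepoints = as.numeric(timepoints),
    aisle_m = aisle_m,
    rng_seed = as.integer(rng_seed)
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d varieties x %d treatments (%s) x %d reps = %d plots\n",
              x$n_varieties, length(x$treatments),
              paste(names(x$treatments), collapse = "/"),
              x$n_replicates,
              x$n_varieties * length(x$treatments) * x$n_replicates))
  cat(sprintf("  plots %.2f x %.2f m, %d rows at %.2f m; %d timepoints (%g-%g DAS)\n",
              x$plot_length_m, x$plot_width_m, x$n_rows_per_plot, x$row_spacing_m,
              length(x$timepoints), min(x$timepoints), max(x$timepoints)))
  invisible(x)
}

#' Lay out plots of a trial design on a rectangular field
#'
#' Every variety x treatment x replicate combination receives exactly one
#' axis-aligned rectangular plot. Placement is deterministic row-major:
#' plots are enumerated variety-fastest within treatment within replicate
#' and placed left-to-right, bottom-to-top on a near-square grid with fixed
#' aisle gaps.
#'
#' @param design a [trial_design()].
#' @return A `field_layout`: list with `plots` (data.frame with columns
#'   plot_id, variety_id, treatment, replicate, xmin, xmax, ymin, ymax),
#'   `extent` (xmin, xmax, ymin, ymax of the whole field) and the design.
#' @export
generate_layout <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  trts <- names(design$treatments)
  combos <- expand.grid(
    variety_id = sprintf("V%03d", seq_len(design$n_varieties)),
    treatment = trts,
    replicate = seq_len(design$n_replicates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(combos)
  ncol_grid <- ceiling(sqrt(n * design$plot_width_m / design$plot_length_m))
  col <- (seq_len(n) - 1L) %% ncol_grid
  row <- (seq_len(n) - 1L) %/% ncol_grid
  pitch_x <- design$plot_length_m + design$aisle_m
  pitch_y <- design$plot_width_m + design$aisle_m
  plots <- data.frame(
    plot_id = sprintf("P%04d", seq_len(n)),
    combos,
    xmin = col * pitch_x,
    xmax = col * pitch_x + design$plot_length_m,
    ymin = row * pitch_y,
    ymax = row * pitch_y + design$plot_width_m,
    stringsAsFactors = FALSE
  )
  structure(list(
    plots = plots,
    extent = c(xmin = 0, xmax = max(plots$xmax) + design$aisle_m,
               ymin = 0, ymax = max(plots$ymax) + design$aisle_m),
    design = design
  ), class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("Field layout: %d plots over %.1f x %.1f m\n",
              nrow(x$plots), x$extent["xmax"], x$extent["ymax"]))
  invisible(x)
}
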