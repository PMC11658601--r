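#' Fit a Gaussian-plus-baseline growth curve
#'
#' Fits f(t) = c + a * exp(-(t - mu)^2 / (2 sigma^2)) to a time series by
#' bounded nonlinear least squares (Levenberg-Marquardt). The Gaussian
#' bump captures the rise of the signal through the season, its peak at
#' mu and the post-peak decline along the falling limb; c is the
#' baseline the signal relaxes to far from the peak.
#'
#' Automatic initialization uses c = min value, a = range, mu = argmax
#' time, sigma = span / 4. Bounds: a > 0, sigma in \[min time step,
#' 5 x span\], mu in \[t_first - span, t_last + span\]. On
#' non-convergence, five jittered restarts (fixed seed) are tried before
#' erroring with the best iterate attached. A series with (numerically)
#' zero variance is returned as a degenerate flat fit rather than
#' fitted.
#'
#' @param times strictly increasing observation days (DAS).
#' @param values observed signal; pairs with NA in either are dropped.
#' @param init `"auto"` or a named list/vector with a, mu, sigma, c.
#' @return An object of class `fitted_curve`: a, mu, sigma, c,
#'   residual_sse, n_obs, converged, degenerate.
#' @export
fit_gaussian_curve <- function(times, values, init = "auto") {
  ok <- is.finite(times) & is.finite(values)
  t <- times[ok]; v <- values[ok]
  if (length(t) < 4)
    stop("insufficient data: need >= 4 non-missing observations", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  span <- diff(range(t))
  if (stats::sd(v) < 1e-10) {
    return(structure(list(a = 0, mu = mean(t), sigma = span / 4, c = mean(v),
                          residual_sse = sum((v - mean(v))^2), n_obs = length(t),
                          converged = TRUE, degenerate = TRUE),
                     class = "fitted_curve"))
  }
  lower <- c(a = 1e-9, mu = min(t) - span, sigma = min(diff(t)), c = -Inf)
  upper <- c(a = Inf, mu = max(t) + span, sigma = 5 * span, c = Inf)
  clamp <- function(s) pmin(pmax(s, lower + 1e-12), c(1e6, upper[2:3], 1e6))
  start0 <- if (identical(init, "auto")) {
    c(a = max(v) - min(v), mu = t[which.max(v)], sigma = span / 4, c = min(v))
  } else unlist(init)[c("a", "mu", "sigma", "c")]
  df <- data.frame(t = t, v = v)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(v ~ c + a * exp(-(t - mu)^2 / (2 * sigma^2)),
                        data = df, start = as.list(clamp(start)),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(start0)
  if (is.null(fit)) {
    set.seed(20260101L)
    for (r in 1:5) {
      jit <- start0 * stats::runif(4, 0.6, 1.4)
      fit <- try_fit(jit)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    stop("Gaussian fit did not converge; best starting values: ",
         paste(sprintf("%s=%.3g", names(start0), start0), collapse = ", "),
         call. = FALSE)
  p <- stats::coef(fit)
  degen <- p["a"] <= 1e-8 * max(1, abs(p["c"]))
  structure(list(a = unname(p["a"]), mu = unname(p["mu"]),
                 sigma = unname(p["sigma"]), c = unname(p["c"]),
                 residual_sse = sum(stats::resid(fit)^2), n_obs = length(t),
                 converged = TRUE, degenerate = unname(degen)),
            class = "fitted_curve")
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf("Gaussian curve: a=%.3f mu=%.2f sigma=%.2f c=%.3f (SSE %.4g, n=%d%s)\n",
              x$a, x$mu, x$sigma, x$c, x$residual_sse, x$n_obs,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Evaluate a fitted curve and its derivative
#'
#' Closed forms: f(t) = c + a exp(-(t - mu)^2 / (2 sigma^2)) and
#' f'(t) = -a (t - mu) / sigma^2 * exp(-(t - mu)^2 / (2 sigma^2)).
#'
#' @param curve a `fitted_curve`.
#' @param t days (DAS).
#' @return Signal units (`curve_value`) or signal units per day
#'   (`curve_derivative`).
#' @export
curve_value <- function(curve, t) {
  curve$c + curve$a * exp(-(t - curve$mu)^2 / (2 * curve$sigma^2))
}

#' @rdname curve_value
#' @export
curve_derivative <- function(curve, t) {
  -curve$a * (t - curve$mu) / curve$sigma^2 *
    exp(-(t - curve$mu)^2 / (2 * curve$sigma^2))
}

# roots x1 <= 1 <= x2 of x * exp(-x^2 / 2) = theta * exp(-1 / 2), by bisection
rapid_phase_roots <- function(theta, tol = 1e-12) {
  target <- theta * exp(-0.5)
  g <- function(x) x * exp(-x^2 / 2) - target
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  c(x1 = bisect(1e-12, 1), x2 = bisect(1, hi))
}

#' Extract the six dynamic traits from a fitted curve
#'
#' The traits summarize the fitted seasonal curve:
#' * `v_max` — peak signal value, c + a;
#' * `v_md` — day of the peak, mu (clipped into the observed window,
#'   with `clipped = TRUE` when that happens);
#' * `v_srg`, `v_erg` — start and end of the rapid-change phase: the
#'   two days on the rising limb where the growth rate f'(t) equals
#'   `theta` times its maximum r* = (a / sigma) exp(-1/2) (attained at
#'   mu - sigma), found by bisection to 1e-8 days;
#' * `v_drg` — duration v_erg - v_srg in days;
#' * `v_gr` — mean rate over the rapid phase, (f(v_erg) - f(v_srg)) /
#'   v_drg (`rate = "peak"` reports r* instead).
#'
#' @param curve a `fitted_curve`.
#' @param theta rapid-phase threshold in (0, 1); default 0.5.
#' @param t_domain observed window c(t_first, t_last) used to clip v_md;
#'   `NULL` leaves v_md unclipped.
#' @param rate `"secant"` (default) or `"peak"`.
#' @return An object of class `dynamic_traits` (all NA for a degenerate
#'   flat curve).
#' @export
extract_dynamic_traits <- function(curve, theta = 0.5, t_domain = NULL,
                                   rate = c("secant", "peak")) {
  rate <- match.arg(rate)
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)", call. = FALSE)
  if (isTRUE(curve$degenerate)) {
    return(structure(list(v_max = NA_real_, v_md = NA_real_, v_srg = NA_real_,
                          v_erg = NA_real_, v_drg = NA_real_, v_gr = NA_real_,
                          theta = theta, clipped = FALSE, degenerate = TRUE),
                     class = "dynamic_traits"))
  }
  x <- rapid_phase_roots(theta)
  v_srg <- curve$mu - curve$sigma * x["x2"]
  v_erg <- curve$mu - curve$sigma * x["x1"]
  v_drg <- unname(v_erg - v_srg)
  v_md <- curve$mu
  clipped <- FALSE
  if (!is.null(t_domain)) {
    lo <- min(t_domain); hi <- max(t_domain)
    if (v_md < lo || v_md > hi) {
      v_md <- min(max(v_md, lo), hi)
      clipped <- TRUE
    }
  }
  rstar <- curve$a / curve$sigma * exp(-0.5)
  v_gr <- if (rate == "peak") rstar else
    (curve_value(curve, v_erg) - curve_value(curve, v_srg)) / v_drg
  structure(list(v_max = curve$c + curve$a, v_md = v_md,
                 v_srg = unname(v_srg), v_erg = unname(v_erg),
                 v_drg = v_drg, v_gr = unname(v_gr),
                 theta = theta, clipped = clipped, degenerate = FALSE),
            class = "dynamic_traits")
}

#' @export
print.dynamic_traits <- function(x, ...) {
  cat(sprintf("max %.3f at %.1f DAS; rapid phase %.1f-%.1f (%.1f d) at rate %.3f/d\n",
              x$v_max, x$v_md, x$v_srg, x$v_erg, x$v_drg, x$v_gr))
  invisible(x)
}

#' Batch dynamic-trait extraction over a long series table
#'
#' Groups a long table of per-plot observations, optionally averages
#' replicate series, fits one Gaussian curve per group and signal, and
#' extracts the six dynamic traits. Groups whose fit fails carry NA
#' traits and a reason code.
#'
#' @param series data.frame with columns `day`, `value`, a grouping
#'   identity (see `grouping`) and optionally `signal` (default signal
#'   name `"value"`).
#' @param grouping `"plot"` (one fit per plot_id), `"variety_treatment"`
#'   (replicate series averaged per variety x treatment per day before
#'   fitting) or `"treatment"` (one mean series per treatment).
#' @param theta,rate passed to [extract_dynamic_traits()].
#' @return data.frame with one row per group x signal: group columns,
#'   signal, the six traits (v_max, v_md, v_srg, v_erg, v_drg, v_gr) and
#'   `fit_flag` (`"ok"`, `"degenerate"`, `"insufficient-data"`,
#'   `"no-convergence"`).
#' @export
trait_table <- function(series, grouping = c("plot", "variety_treatment",
                                             "treatment"),
                        theta = 0.5, rate = "secant") {
  grouping <- match.arg(grouping)
  if (nrow(series) == 0) stop("empty series table", call. = FALSE)
  if (!"signal" %in% names(series)) series$signal <- "value"
  keys <- switch(grouping,
                 plot = "plot_id",
                 variety_treatment = c("variety_id", "treatment"),
                 treatment = "treatment")
  if (!all(keys %in% names(series)))
    stop("series lacks grouping columns: ", paste(keys, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(series$value,
                          by = c(series[c(keys, "signal")], list(day = series$day)),
                          FUN = mean, na.rm = TRUE)
  names(agg)[ncol(agg)] <- "value"
  groups <- unique(agg[c(keys, "signal")])
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(agg))
    for (k in c(keys, "signal")) sel <- sel & agg[[k]] == groups[[k]][i]
    g <- agg[sel, ]
    g <- g[order(g$day), ]
    row <- groups[i, , drop = FALSE]
    tr <- list(v_max = NA_real_, v_md = NA_real_, v_srg = NA_real_,
               v_erg = NA_real_, v_drg = NA_real_, v_gr = NA_real_)
    flag <- "ok"
    fit <- tryCatch(fit_gaussian_curve(g$day, g$value), error = function(e) e)
    if (inherits(fit, "error")) {
      flag <- if (grepl("insufficient", conditionMessage(fit)))
        "insufficient-data" else "no-convergence"
    } else if (fit$degenerate) {
      flag <- "degenerate"
    } else {
      dt <- extract_dynamic_traits(fit, theta, range(g$day), rate)
      tr <- dt[c("v_max", "v_md", "v_srg", "v_erg", "v_drg", "v_gr")]
    }
    rows[[i]] <- cbind(row, as.data.frame(tr), fit_flag = flag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
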