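#' Growth-curve configuration for trajectory simulation
#'
#' Canopy height over the season is modeled as a Gaussian bump on a
#' baseline, f(t) = c + a * exp(-(t - mu)^2 / (2 sigma^2)) with t in days
#' after sowing (DAS): height rises through stem elongation, peaks at mu,
#' and declines slightly during grain filling along the falling limb.
#' Each treatment has its own mean curve parameters; varieties perturb
#' them through additive random effects drawn once per variety, and each
#' observation receives independent measurement noise.
#'
#' The default treatment curves encode the seasonal anatomy of a
#' three-level nitrogen trial: all treatments peak at 160 DAS; the
#' fertilized treatments (N180/N240) reach a maximum about 15 cm above the
#' unfertilized control, stand near 50 cm at 65 DAS against about 42 cm
#' for the control, and all treatments shed roughly 5 cm of mean canopy
#' height between the peak and the final acquisition at 185 DAS. The
#' parameter values below are the exact solution of those constraints for
#' the Gaussian family.
#'
#' `nitrogen_status` maps treatment to a unitless canopy nitrogen status
#' in [0, 1] that drives the reflectance simulator.
#'
#' @param treatment_params data.frame with columns treatment, a, mu,
#'   sigma, c (cm, DAS, days, cm).
#' @param variety_sd named numeric: SDs of variety random effects on each
#'   parameter (names a, mu, sigma, c).
#' @param noise_sd measurement noise SD in cm (>= 0).
#' @param nitrogen_status named numeric in [0, 1] per treatment.
#' @param family curve family used by the generator; `"gaussian"`
#'   (default, same family the fitter assumes) or `"logis_decline"`, a
#'   logistic rise followed by a linear decline, provided to probe
#'   robustness to model misspecification.
#'
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(
    treatment_params = data.frame(
      treatment = c("N0", "N180", "N240"),
      a     = c(47.54, 66.00, 66.25),
      mu    = c(160, 160, 160),
      sigma = c(53, 63, 63),
      c     = c(32.46, 28.75, 28.75)
    ),
    variety_sd = c(a = 4, mu = 3, sigma = 3, c = 2),
    noise_sd = 2,
    nitrogen_status = c(N0 = 0.30, N180 = 0.75, N240 = 0.90),
    family = c("gaussian", "logis_decline")) {
  family <- match.arg(family)
  if (any(treatment_params$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (any(nitrogen_status < 0 | nitrogen_status > 1))
    stop("nitrogen status must lie in [0, 1]", call. = FALSE)
  stopifnot(all(c("a", "mu", "sigma", "c") %in% names(variety_sd)))
  structure(list(
    treatment_params = treatment_params,
    variety_sd = variety_sd,
    noise_sd = noise_sd,
    nitrogen_status = nitrogen_status,
    family = family
  ), class = "growth_config")
}

gaussian_height <- function(t, a, mu, sigma, c) {
  c + a * exp(-(t - mu)^2 / (2 * sigma^2))
}

logis_decline_height <- function(t, a, mu, sigma, c) {
  # logistic rise to c + a centered ~1 sigma before mu, then linear decline
  rise <- c + a / (1 + exp(-(t - (mu - sigma)) / (sigma / 4)))
  decline <- pmax(0, t - mu) * (0.05 * a / sigma)
  rise - decline
}

#' Simulate per-plot growth trajectories
#'
#' Draws one set of curve parameters per plot (treatment means + variety
#' random effects + optional per-variety QTL effects), evaluates the curve
#' at every design timepoint and adds independent measurement noise.
#' Heights are truncated at zero. The per-treatment nitrogen status is
#' carried along for the reflectance simulator, modulated over the season
#' by canopy development (scaled by f(t)/max f so early canopies read
#' lower).
#'
#' @param layout a `field_layout` from [generate_layout()].
#' @param growth a [growth_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param variety_effects optional data.frame (variety_id, d_a, d_mu,
#'   d_sigma, d_c) of additive shifts applied on top of the random
#'   effects, e.g. from [qtl_variety_effects()].
#' @return A `true_trait_table`: data.frame with one row per plot per
#'   timepoint (plot_id, variety_id, treatment, replicate, day,
#'   true_height_cm, nitrogen_status) plus attribute `"params"`, the
#'   per-plot generative curve parameters.
#' @export
simulate_trajectories <- function(layout, growth, seed = 1L,
                                  variety_effects = NULL) {
  stopifnot(inherits(layout, "field_layout"), inherits(growth, "growth_config"))
  tp <- layout$design$timepoints
  if (length(tp) == 0) stop("design has no timepoints", call. = FALSE)
  plots <- layout$plots
  set.seed(as.integer(seed))

  varieties <- unique(plots$variety_id)
  re <- data.frame(
    variety_id = varieties,
    r_a = stats::rnorm(length(varieties), 0, growth$variety_sd["a"]),
    r_mu = stats::rnorm(length(varieties), 0, growth$variety_sd["mu"]),
    r_sigma = stats::rnorm(length(varieties), 0, growth$variety_sd["sigma"]),
    r_c = stats::rnorm(length(varieties), 0, growth$variety_sd["c"])
  )
  if (!is.null(variety_effects)) {
    i <- match(re$variety_id, variety_effects$variety_id)
    re$r_a <- re$r_a + ifelse(is.na(i), 0, variety_effects$d_a[i])
    re$r_mu <- re$r_mu + ifelse(is.na(i), 0, variety_effects$d_mu[i])
    re$r_sigma <- re$r_sigma + ifelse(is.na(i), 0, variety_effects$d_sigma[i])
    re$r_c <- re$r_c + ifelse(is.na(i), 0, variety_effects$d_c[i])
  }

  tpar <- growth$treatment_params
  it <- match(plots$treatment, tpar$treatment)
  if (anyNA(it)) stop("layout contains treatments missing from growth config", call. = FALSE)
  iv <- match(plots$variety_id, re$variety_id)
  params <- data.frame(
    plot_id = plots$plot_id,
    a = pmax(0.1, tpar$a[it] + re$r_a[iv]),
    mu = tpar$mu[it] + re$r_mu[iv],
    sigma = pmax(5, tpar$sigma[it] + re$r_sigma[iv]),
    c = pmax(0, tpar$c[it] + re$r_c[iv])
  )

  fam <- if (growth$family == "gaussian") gaussian_height else logis_decline_height
  n <- nrow(plots)
  out <- data.frame(
    plot_id = rep(plots$plot_id, each = length(tp)),
    variety_id = rep(plots$variety_id, each = length(tp)),
    treatment = rep(plots$treatment, each = length(tp)),
    replicate = rep(plots$replicate, each = length(tp)),
    day = rep(tp, times = n),
    stringsAsFactors = FALSE
  )
  ip <- rep(seq_len(n), each = length(tp))
  mu_h <- fam(out$day, params$a[ip], params$mu[ip], params$sigma[ip], params$c[ip])
  out$true_height_cm <- pmax(0, mu_h + stats::rnorm(nrow(out), 0, growth$noise_sd))

  status <- growth$nitrogen_status[out$treatment]
  peak <- fam(params$mu[ip], params$a[ip], params$mu[ip], params$sigma[ip], params$c[ip])
  out$nitrogen_status <- pmin(1, pmax(0, status * (0.4 + 0.6 * mu_h / peak)))
  attr(out, "params") <- params
  class(out) <- c("true_trait_table", "data.frame")
  out
}
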