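tp10 <- c(20, 40, 60, 80, 100, 120, 135, 150, 165, 185)

test_that("Gaussian fitting recovers noiseless parameters to 1e-6 relative", {
  cases <- list(c(a = 50, mu = 160, sigma = 40, c = 10),
                c(a = 12, mu = 100, sigma = 25, c = 3),
                c(a = 80, mu = 140, sigma = 60, c = 30))
  for (p in cases) {
    v <- p["c"] + p["a"] * exp(-(tp10 - p["mu"])^2 / (2 * p["sigma"]^2))
    f <- fit_gaussian_curve(tp10, v)
    expect_lt(abs(f$a - p["a"]) / p["a"], 1e-6)
    expect_lt(abs(f$mu - p["mu"]) / p["mu"], 1e-6)
    expect_lt(abs(f$sigma - p["sigma"]) / p["sigma"], 1e-6)
    expect_lt(abs(f$c - p["c"]) / max(1, p["c"]), 1e-6)
    expect_false(f$degenerate)
  }
  expect_error(fit_gaussian_curve(c(1, 2, 3), c(1, 2, 3)), "insufficient")
  expect_error(fit_gaussian_curve(c(1, 1, 2, 3), c(1, 2, 3, 4)), "increasing")

  flat <- fit_gaussian_curve(tp10, rep(7, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$c, 7)
})

test_that("noisy fits recover the peak day on average (Monte Carlo)", {
  set.seed(19)
  n_rep <- 200
  mu_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    v <- 10 + 50 * exp(-(tp10 - 160)^2 / (2 * 40^2)) + rnorm(10, 0, 2)
    mu_hat[r] <- fit_gaussian_curve(tp10, v)$mu
  }
  se <- sd(mu_hat) / sqrt(n_rep)
  expect_lt(abs(mean(mu_hat) - 160), 3 * se + 0.5)
})

test_that("curve value and derivative satisfy the closed-form identities", {
  f <- structure(list(a = 50, mu = 160, sigma = 40, c = 10, degenerate = FALSE),
                 class = "fitted_curve")
  expect_equal(curve_value(f, 160), 60)
  expect_equal(curve_derivative(f, 160), 0)
  # maximum rising-limb rate at mu - sigma
  expect_equal(curve_derivative(f, 160 - 40), 50 / 40 * exp(-0.5),
               tolerance = 1e-12)
  # symmetry about the peak
  expect_equal(curve_value(f, 160 - 17), curve_value(f, 160 + 17))
})

test_that("rapid-phase endpoints solve the derivative-threshold equation", {
  f <- structure(list(a = 1, mu = 100, sigma = 20, c = 0, degenerate = FALSE),
                 class = "fitted_curve")
  tr <- extract_dynamic_traits(f, theta = 0.5)
  rstar <- 1 / 20 * exp(-0.5)
  expect_equal(curve_derivative(f, tr$v_srg), 0.5 * rstar, tolerance = 1e-7)
  expect_equal(curve_derivative(f, tr$v_erg), 0.5 * rstar, tolerance = 1e-7)
  expect_lt(tr$v_srg, 100 - 20)
  expect_gt(tr$v_erg, 100 - 20)
  expect_equal(tr$v_drg, tr$v_erg - tr$v_srg)
  expect_equal(tr$v_max, 1)
  expect_equal(tr$v_md, 100)

  # fine-grid scan oracle for the dimensionless roots
  roots <- grid_rapid_roots(0.5)
  expect_equal(tr$v_srg, 100 - 20 * roots["x2"], ignore_attr = TRUE,
               tolerance = 1e-5)
  expect_equal(tr$v_erg, 100 - 20 * roots["x1"], ignore_attr = TRUE,
               tolerance = 1e-5)

  # theta -> 1: the window collapses onto mu - sigma
  tr99 <- extract_dynamic_traits(f, theta = 0.999)
  expect_lt(tr99$v_drg, 2)
  expect_error(extract_dynamic_traits(f, theta = 1.2), "theta")

  degen <- structure(list(a = 0, mu = 1, sigma = 1, c = 5, degenerate = TRUE),
                     class = "fitted_curve")
  expect_true(all(is.na(unlist(extract_dynamic_traits(degen)[1:6]))))
})

test_that("traits shift and rescale as the signal and clock do", {
  v <- 10 + 50 * exp(-(tp10 - 160)^2 / (2 * 40^2))
  t0 <- extract_dynamic_traits(fit_gaussian_curve(tp10, v), 0.5, range(tp10))
  # additive signal shift: only v_max moves
  t1 <- extract_dynamic_traits(fit_gaussian_curve(tp10, v + 7), 0.5, range(tp10))
  expect_equal(t1$v_max, t0$v_max + 7, tolerance = 1e-6)
  expect_equal(t1$v_md, t0$v_md, tolerance = 1e-6)
  expect_equal(t1$v_drg, t0$v_drg, tolerance = 1e-6)
  expect_equal(t1$v_gr, t0$v_gr, tolerance = 1e-6)
  # time dilation t -> 2t: durations double, rates halve
  t2 <- extract_dynamic_traits(fit_gaussian_curve(2 * tp10, v), 0.5,
                               range(2 * tp10))
  expect_equal(t2$v_drg, 2 * t0$v_drg, tolerance = 1e-6)
  expect_equal(t2$v_gr, t0$v_gr / 2, tolerance = 1e-6)
  expect_equal(t2$v_md, 2 * t0$v_md, tolerance = 1e-6)
})

test_that("trait_table batches fits with reason codes and honest grouping", {
  mk <- function(pid, a) data.frame(plot_id = pid, variety_id = "V001",
                                    treatment = "N0", day = tp10,
                                    value = 5 + a * exp(-(tp10 - 150)^2 / (2 * 35^2)))
  tab <- rbind(mk("P1", 40), mk("P2", 60))
  tt <- trait_table(tab, grouping = "plot")
  expect_equal(nrow(tt), 2)
  expect_equal(tt$v_max, c(45, 65), tolerance = 1e-5)
  expect_true(all(c("v_max", "v_md", "v_srg", "v_erg", "v_drg", "v_gr")
                  %in% names(tt)))

  short <- data.frame(plot_id = "P3", variety_id = "V001", treatment = "N0",
                      day = c(10, 20, 30), value = c(1, 2, 3))
  tt2 <- trait_table(rbind(tab, short), grouping = "plot")
  expect_equal(tt2$fit_flag[tt2$plot_id == "P3"], "insufficient-data")
  expect_true(is.na(tt2$v_max[tt2$plot_id == "P3"]))

  # variety x treatment grouping equals fitting the independently averaged series
  rep1 <- mk("P1", 40); rep2 <- mk("P2", 60)
  tt3 <- trait_table(rbind(rep1, rep2), grouping = "variety_treatment")
  expect_equal(nrow(tt3), 1)
  mean_series <- (rep1$value + rep2$value) / 2
  direct <- extract_dynamic_traits(fit_gaussian_curve(tp10, mean_series), 0.5,
                                   range(tp10))
  expect_equal(tt3$v_max, direct$v_max, tolerance = 1e-8)
  expect_equal(tt3$v_md, direct$v_md, tolerance = 1e-8)

  expect_error(trait_table(tab[0, ]), "empty")
})
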