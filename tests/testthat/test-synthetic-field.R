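test_that("layout places one plot per variety x treatment x replicate", {
  lay <- generate_layout(trial_design(n_varieties = 2))
  expect_equal(nrow(lay$plots), 2 * 3 * 2)
  combo <- with(lay$plots, paste(variety_id, treatment, replicate))
  expect_equal(anyDuplicated(combo), 0L)

  lay160 <- generate_layout(trial_design())
  expect_equal(nrow(lay160$plots), 960)

  expect_error(trial_design(plot_width_m = 0), "positive")
  expect_error(trial_design(timepoints = c(10, 10)), "increasing")
  expect_error(trial_design(n_varieties = 0), "counts")
})

test_that("plot rectangles are pairwise non-overlapping and correctly sized", {
  d <- trial_design(n_varieties = 3)
  lay <- generate_layout(d)
  p <- lay$plots
  expect_true(all(abs(p$xmax - p$xmin - d$plot_length_m) < 1e-12))
  expect_true(all(abs(p$ymax - p$ymin - d$plot_width_m) < 1e-12))
  for (i in seq_len(nrow(p) - 1)) {
    for (j in seq(i + 1, nrow(p))) {
      overlap <- p$xmin[i] < p$xmax[j] && p$xmax[i] > p$xmin[j] &&
        p$ymin[i] < p$ymax[j] && p$ymax[i] > p$ymin[j]
      expect_false(overlap)
    }
  }
})

test_that("trajectories follow the Gaussian family exactly when noise is zero", {
  d <- trial_design(n_varieties = 1, treatments = c(N0 = 0), n_replicates = 1,
                    timepoints = c(60, 110, 160, 185))
  lay <- generate_layout(d)
  g <- growth_config(
    treatment_params = data.frame(treatment = "N0", a = 50, mu = 160,
                                  sigma = 40, c = 10),
    variety_sd = c(a = 0, mu = 0, sigma = 0, c = 0), noise_sd = 0)
  tr <- simulate_trajectories(lay, g, seed = 1)
  expect_equal(tr$true_height_cm[tr$day == 160], 60)            # peak = c + a
  expect_equal(tr$true_height_cm[tr$day == 60],
               10 + 50 * exp(-100^2 / (2 * 40^2)))
  expect_error(generate_layout(trial_design(timepoints = numeric(0))))
})

test_that("treatment contrast in simulated heights matches the configured curves", {
  lay <- generate_layout(trial_design(n_varieties = 40))
  gc <- growth_config()
  tr <- simulate_trajectories(lay, gc, seed = 11)
  at_peak <- tr[tr$day == 165, ]   # nearest timepoint to the 160 DAS peak
  m <- tapply(at_peak$true_height_cm, at_peak$treatment, mean)
  tp <- gc$treatment_params
  expected <- function(trt) {
    r <- tp[tp$treatment == trt, ]
    r$c + r$a * exp(-(165 - r$mu)^2 / (2 * r$sigma^2))
  }
  # Monte-Carlo error of a treatment mean over 80 plots is well under 2 cm
  expect_lt(abs((m["N240"] - m["N0"]) - (expected("N240") - expected("N0"))), 3)
  expect_lt(abs(m["N240"] - expected("N240")), 2)
})

test_that("trajectory simulation is reproducible and seed-sensitive", {
  lay <- small_layout()
  gc <- growth_config()
  expect_identical(simulate_trajectories(lay, gc, seed = 5),
                   simulate_trajectories(lay, gc, seed = 5))
  expect_false(identical(simulate_trajectories(lay, gc, seed = 5)$true_height_cm,
                         simulate_trajectories(lay, gc, seed = 6)$true_height_cm))
})

test_that("field clouds respect labels, geometry and the CLT height bound", {
  lay <- small_layout()
  tr <- simulate_trajectories(lay, growth_config(), seed = 2)
  td <- tr[tr$day == 100, ]
  cfg <- cloud_config(weed_fraction = 0)
  cl <- generate_field_cloud(lay, td, cfg, seed = 3)

  # labels partition the cloud
  expect_equal(sum(cl$labels == 0L) + sum(cl$labels == 1L), nrow(cl$points))

  # every canopy point inside exactly one plot rectangle (half-open)
  can <- cl$points[cl$labels == 1L, , drop = FALSE]
  p <- lay$plots
  n_in <- rep(0, nrow(can))
  for (i in seq_len(nrow(p))) {
    n_in <- n_in + (can[, 1] >= p$xmin[i] & can[, 1] < p$xmax[i] &
                      can[, 2] >= p$ymin[i] & can[, 2] < p$ymax[i])
  }
  expect_true(all(n_in == 1))

  # per-plot mean canopy elevation near the true height (3 spread / sqrt(n))
  of <- attr(cl, "plot_of_point")
  for (pid in p$plot_id[1:4]) {
    z <- cl$points[!is.na(of) & of == pid, 3]
    h <- td$true_height_cm[td$plot_id == pid] / 100
    expect_lt(abs(mean(z) - h), 3 * cfg$canopy_spread_m / sqrt(length(z)) + 1e-3)
  }

  # degenerate spread: all canopy z exactly at the true height
  cfg0 <- cloud_config(canopy_spread_m = 0, ground_roughness_m = 0,
                       weed_fraction = 0)
  cl0 <- generate_field_cloud(lay, td, cfg0, seed = 4)
  of0 <- attr(cl0, "plot_of_point")
  pid <- p$plot_id[1]
  expect_equal(unique(round(cl0$points[!is.na(of0) & of0 == pid, 3], 10)),
               round(td$true_height_cm[td$plot_id == pid] / 100, 10))

  expect_identical(generate_field_cloud(lay, td, cfg, seed = 3)$points, cl$points)
  expect_error(cloud_config(ground_density = -1), "non-negative")
})

test_that("multispectral rasters encode nitrogen status monotonically", {
  lay <- small_layout()
  tr <- simulate_trajectories(lay, growth_config(), seed = 2)
  td <- tr[tr$day == 100, ]
  noise0 <- optics_config(noise_sd = 0)
  ra <- generate_multispectral_raster(lay, td, noise0, seed = 1)
  expect_true(all(vapply(ra$bands, function(b) all(b >= 0 & b <= 1), logical(1))))

  # raising status never lowers NIR (noise 0)
  td_hi <- td; td_hi$nitrogen_status <- pmin(1, td$nitrogen_status + 0.2)
  ra_hi <- generate_multispectral_raster(lay, td_hi, noise0, seed = 1)
  expect_true(all(ra_hi$bands$nir - ra$bands$nir >= -1e-12))

  # all-soil field: no plots, soil spectrum everywhere
  lay1 <- lay; lay1$plots <- lay$plots[0, ]
  ra_soil <- generate_multispectral_raster(lay1, td, noise0, seed = 1)
  expect_true(all(abs(ra_soil$bands$red - noise0$soil["red"]) < 1e-12))

  expect_error(optics_config(res = 0), "resolution")
})

test_that("genotype simulation honors missingness, MAF bounds and QTL planting", {
  g <- generate_genotypes(100, 200, missing_rate = 0, seed = 1)
  expect_false(anyNA(g$genotypes$dosage))
  expect_equal(nrow(g$qtl_map), 0)

  rate <- 0.1
  g2 <- generate_genotypes(100, 200, missing_rate = rate, seed = 2)
  obs <- mean(is.na(g2$genotypes$dosage))
  n <- 100 * 200
  expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / n))

  g0 <- generate_genotypes(10, 0, seed = 3)
  expect_equal(ncol(g0$genotypes$dosage), 0)
  expect_equal(nrow(g0$qtl_map), 0)

  expect_error(generate_genotypes(10, 10, maf_low = 0.6), "maf")

  gq <- generate_genotypes(50, 100, missing_rate = 0, seed = 4,
                           qtl_spec = data.frame(parameter = "a", effect = 4))
  expect_equal(nrow(gq$qtl_map), 1)
  ve <- qtl_variety_effects(gq$genotypes, gq$qtl_map)
  dos <- gq$genotypes$dosage[, gq$qtl_map$snp_index]
  expect_equal(ve$d_a, 4 * (dos - mean(dos)), ignore_attr = TRUE)
  expect_equal(ve$d_mu, rep(0, 50))
})
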