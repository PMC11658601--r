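one_pixel <- function(nir, red = 0.1, green = 0.2, blue = 0.05, red_edge = 0.3) {
  ms_raster(list(blue = matrix(blue), green = matrix(green), red = matrix(red),
                 red_edge = matrix(red_edge), nir = matrix(nir)))
}

vi_at <- function(raster, index, ...) compute_vi(raster, index, ...)$bands[[index]][1, 1]

test_that("vegetation-index formulas match hand evaluation", {
  px <- one_pixel(nir = 0.5, red = 0.1)
  expect_equal(vi_at(px, "NDRE"), 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(vi_at(px, "MSAVI"), (2 - sqrt(0.8)) / 2, tolerance = 1e-12)
  expect_equal(vi_at(px, "RVI_1"), 5)
  expect_equal(vi_at(one_pixel(nir = 0.4, green = 0.2), "RVI_2"), 2)

  # the CCCI calibration endpoints map NDRE 0.61 -> 1 and 0.24 -> 0
  expect_equal(ccci_from_ndre(0.61), 1)
  expect_equal(ccci_from_ndre(0.24), 0)

  # NDRE band override: red-edge variant
  p <- vi_params(ndre_band = "red_edge")
  expect_equal(vi_at(one_pixel(nir = 0.5, red_edge = 0.3), "NDRE", params = p),
               0.2 / 0.8, tolerance = 1e-12)

  expect_error(compute_vi(px, "EVI"), "unknown")
  expect_error(vi_params(ndre_min = 0.7), "ndre_min")
})

test_that("CCCI is the affine image of NDRE, unclipped by default", {
  set.seed(17)
  n <- 20
  ra <- ms_raster(list(blue = matrix(runif(n), 4), green = matrix(runif(n), 4),
                       red = matrix(runif(n, 0.05, 0.3), 4),
                       red_edge = matrix(runif(n), 4),
                       nir = matrix(runif(n, 0.2, 0.9), 4)))
  ndre <- compute_vi(ra, "NDRE")$bands$NDRE
  ccci <- compute_vi(ra, "CCCI")$bands$CCCI
  expect_equal(ccci, (ndre - 0.24) / (0.61 - 0.24), tolerance = 1e-12)
  clipped <- compute_vi(ra, "CCCI", vi_params(clip_ccci = TRUE))$bands$CCCI
  expect_true(all(clipped >= 0 & clipped <= 1))

  # MSAVI discriminant is non-negative for any reflectances in [0, 1]
  expect_true(all(is.finite(compute_vi(ra, "MSAVI")$bands$MSAVI)))

  # zero denominators propagate as NA
  z <- one_pixel(nir = 0, red = 0)
  expect_true(is.na(vi_at(z, "NDRE")))
  expect_true(is.na(vi_at(z, "RVI_1")))
})

test_that("plot masks count pixel centers inside buffered rectangles", {
  d <- trial_design(n_varieties = 1, treatments = c(N0 = 0), n_replicates = 1,
                    plot_length_m = 1, plot_width_m = 1, aisle_m = 0.5)
  lay <- generate_layout(d)
  shape <- c(ceiling(lay$extent["ymax"] / 0.1), ceiling(lay$extent["xmax"] / 0.1))
  blank <- ms_raster(list(v = matrix(0.5, shape[1], shape[2])), res = 0.1)
  masks <- build_plot_masks(lay, blank, buffer_m = 0)
  expect_length(masks[[1]], 100)               # 10 x 10 pixels of 0.1 m

  expect_warning(empty <- build_plot_masks(lay, blank, buffer_m = 0.5),
                 "empties")
  expect_length(empty[[1]], 0)

  # adjacent plots never share pixels
  lay2 <- small_layout()
  shape2 <- c(ceiling(lay2$extent["ymax"] / 0.1), ceiling(lay2$extent["xmax"] / 0.1))
  blank2 <- ms_raster(list(v = matrix(0.5, shape2[1], shape2[2])), res = 0.1)
  m2 <- build_plot_masks(lay2, blank2, buffer_m = 0)
  all_px <- unlist(m2)
  expect_equal(anyDuplicated(all_px), 0L)
  expect_error(build_plot_masks(lay2, blank2, buffer_m = -1), "buffer_m")
})

test_that("plot means respect nodata and empty masks", {
  d <- trial_design(n_varieties = 1, treatments = c(N0 = 0), n_replicates = 1,
                    plot_length_m = 1, plot_width_m = 1, aisle_m = 0.5)
  lay <- generate_layout(d)
  m <- matrix(2.5, 20, 20)
  vir <- ms_raster(list(CCCI = m), res = 0.1)
  masks <- build_plot_masks(lay, vir, buffer_m = 0)
  tab <- plot_mean_vi(vir, masks, day = 60)
  expect_equal(tab$mean_value, 2.5)
  expect_equal(tab$n_pixels, 100L)

  # half the pixels nodata: mean over the rest, count halved
  m2 <- m
  m2[masks[[1]][1:50]] <- NA
  m2[masks[[1]][51:100]] <- 4
  tab2 <- plot_mean_vi(ms_raster(list(CCCI = m2), res = 0.1), masks)
  expect_equal(tab2$mean_value, 4)
  expect_equal(tab2$n_pixels, 50L)

  masks_empty <- masks
  masks_empty[[1]] <- integer(0)
  tab3 <- plot_mean_vi(vir, masks_empty)
  expect_true(is.na(tab3$mean_value))
})

test_that("plot-mean CCCI increases with generator nitrogen status", {
  lay <- small_layout()
  tr <- simulate_trajectories(lay, growth_config(), seed = 2)
  td <- tr[tr$day == 120, ]
  ra <- generate_multispectral_raster(lay, td, optics_config(noise_sd = 0),
                                      seed = 1)
  masks <- build_plot_masks(lay, ra)
  tab <- plot_mean_vi(compute_vi(ra, "CCCI"), masks)
  i <- match(tab$plot_id, td$plot_id)
  ord <- order(td$nitrogen_status[i])
  expect_true(all(diff(tab$mean_value[ord]) > -1e-9))
})

test_that("raster TIFF round trip preserves values and georeferencing", {
  set.seed(18)
  bands <- lapply(setNames(1:5, c("blue", "green", "red", "red_edge", "nir")),
                  function(i) matrix(runif(48), 6, 8))
  bands$nir[2, 3] <- NA
  ra <- ms_raster(bands, x0 = 1.5, y0 = -2, res = 0.25)
  f <- withr::local_tempfile(fileext = ".tif")
  write_ms_raster(ra, f)
  back <- read_ms_raster(f)
  expect_equal(back$bands, ra$bands, tolerance = 1e-6)
  expect_equal(back$res, 0.25)
  expect_equal(back$x0, 1.5)
})
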