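test_that("configuration validation enforces the axis invariants", {
  expect_error(stim_config(image_size = -4), "positive")
  expect_error(stim_config(n_views = 1), ">= 2")
  expect_error(stim_config(image_size = 64, blur_sigmas = c(1, 2, 3, 4, 5)),
               "first entry 0")
  expect_error(stim_config(image_size = 64,
                           disarray_amplitudes = c(0, 3, 2, 4, 5)),
               "nondecreasing")
  expect_error(stim_config(image_size = 64, blur_sigmas = c(0, 1)),
               "one entry per")
  cfg <- stim_config(image_size = 64, n_views = 2)
  expect_s3_class(cfg, "stim_config")
  expect_identical(cfg$blur_sigmas[1], 0)
  expect_identical(cfg$disarray_amplitudes[1], 0)
})

test_that("base images are deterministic, nonnegative and mask-limited", {
  cfg <- small_config()
  img1 <- make_base_image(7L, cfg)
  img2 <- make_base_image(7L, cfg)
  expect_identical(img1$pixels, img2$pixels)
  img3 <- make_base_image(8L, cfg)
  expect_false(identical(img1$pixels, img3$pixels))
  expect_true(all(is.finite(img1$pixels)))
  expect_true(all(img1$pixels >= 0))
  expect_true(all(img1$pixels[!img1$object_mask] == 0))
  expect_true(all(img1$pixels[img1$object_mask] >= cfg$luminance_floor))
  expect_identical(dim(img1$pixels), c(96L, 96L))
})

test_that("neutral skew setting leaves in-mask luminance unskewed", {
  cfg <- small_config(luminance_skew = 1)
  skews <- vapply(1:10, function(s) {
    img <- make_base_image(s, cfg)
    metalsim:::population_skewness(img$pixels[img$object_mask])
  }, numeric(1))
  expect_lt(mean(abs(skews)), 0.2)
  # the default skew exponent produces clearly positive skew
  cfg2 <- small_config()
  img <- make_base_image(1L, cfg2)
  expect_gt(metalsim:::population_skewness(img$pixels[img$object_mask]), 0.5)
})

test_that("base-image spectra follow the naturalistic power-law band", {
  cfg <- stim_config(image_size = 256, n_views = 2, master_seed = 5)
  slopes <- vapply(1:10, function(s) {
    loglog_slope(radial_power_spectrum(make_base_image(s, cfg)))
  }, numeric(1))
  expect_true(all(slopes > -2.6 & slopes < -1.4))
})

test_that("smoothness transform is a masked blur with identity at zero", {
  cfg <- small_config()
  img <- make_base_image(3L, cfg)
  expect_identical(apply_smoothness(img, 0)$pixels, img$pixels)
  expect_error(apply_smoothness(img, -1), ">= 0")
  blurred <- apply_smoothness(img, 4)
  expect_true(all(blurred$pixels[!blurred$object_mask] == 0))
  # blur strictly removes high-frequency band power
  expect_lt(band_mean_power(radial_power_spectrum(blurred)),
            band_mean_power(radial_power_spectrum(img)))
  # constant in-mask content is unchanged away from the boundary
  flat <- img
  flat$pixels[flat$object_mask] <- 0.7
  fb <- apply_smoothness(flat, 2)
  interior <- EBImage::erode(matrix(as.numeric(flat$object_mask), 96),
                             EBImage::makeBrush(15, "disc")) > 0.5
  expect_equal(fb$pixels[interior], flat$pixels[interior], tolerance = 1e-4)
})

test_that("bumpiness transform is a masked warp with identity at zero", {
  cfg <- small_config()
  img <- make_base_image(3L, cfg)
  expect_identical(apply_bumpiness(img, 0, 2, 1L)$pixels, img$pixels)
  expect_error(apply_bumpiness(img, -1, 2, 1L), ">= 0")
  expect_error(apply_bumpiness(img, 1, 0, 1L), "> 0")
  w1 <- apply_bumpiness(img, 6, 2, 9L)
  w2 <- apply_bumpiness(img, 6, 2, 9L)
  expect_identical(w1$pixels, w2$pixels)
  w3 <- apply_bumpiness(img, 6, 2, 10L)
  expect_false(identical(w1$pixels, w3$pixels))
  expect_true(all(w1$pixels[!w1$object_mask] == 0))
  expect_true(all(w1$pixels >= 0))
})

test_that("disarray raises the fine/coarse activation difference", {
  cfg <- small_config()
  for (v in 1:4) {
    img <- make_base_image(100L + v, cfg)
    plain <- bumpiness_statistic(img)
    warped <- bumpiness_statistic(apply_bumpiness(img, 6, 2, 200L + v))
    expect_gt(warped, plain)
  }
})

test_that("condition rendering composes the transforms deterministically", {
  cfg <- small_config()
  expect_error(render_condition(0, 1, 1, cfg), "out of range")
  expect_error(render_condition(1, 4, 1, cfg), "out of range")
  expect_error(render_condition(1, 1, 5, cfg), "out of range")
  base <- render_condition(1, 1, 2, cfg)
  direct <- make_base_image(derive_seed(cfg$master_seed, "view", 2), cfg)
  expect_identical(base$pixels, direct$pixels)
  again <- render_condition(3, 2, 4, cfg)
  expect_identical(again$pixels, render_condition(3, 2, 4, cfg)$pixels)
  expect_identical(again$smoothness_index, 3L)
  expect_identical(again$bumpiness_index, 2L)
  expect_identical(again$view_index, 4L)
})

test_that("the grids have the experiment's stimulus counts", {
  cfg <- small_config()
  expect_length(render_grid(cfg), 3 * 3 * 4)
  # at the reference configuration the counts are 200 and 176
  ref <- stim_config()
  expect_identical(ref$n_smoothness_levels * ref$n_bumpiness_levels *
                     ref$n_views, 200L)
  expect_identical(2L * 11L * ref$n_views, 176L)
  sets <- render_mlds_sets(cfg, n_levels = 5)
  expect_length(sets$smoothness, 5 * 4)
  expect_length(sets$bumpiness, 5 * 4)
  expect_identical(sets$smoothness[[1]]$bumpiness_index, 1L)
  expect_identical(sets$bumpiness[[1]]$smoothness_index, 1L)
})

test_that("warping approximately preserves the in-mask mean (separability)", {
  # checked at the resolution the default axes are calibrated for
  cfg <- stim_config(image_size = 256, n_views = 4, master_seed = 42)
  for (v in 1:4) {
    img <- render_condition(1, 1, v, cfg)
    warped <- render_condition(1, 5, v, cfg)
    m0 <- mean(img$pixels[img$object_mask])
    m1 <- mean(warped$pixels[warped$object_mask])
    expect_lt(abs(m1 - m0) / m0, 0.05)
  }
})
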