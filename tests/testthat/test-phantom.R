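test_that("noiseless sharp phantom takes exactly the specified HU values", {
  sp <- small_phantom_spec(noise_sd = 0, blur_fwhm = 0,
                           thrombus_hu_ncct = 50, contrast_hu = 300,
                           thrombus_uptake_frac = 0.25)
  ph <- generate_phantom(sp, seed = 1)
  # CTA voxel at the thrombus centre: 50 + 0.25 * (300 - 50) = 112.5
  y_mid <- ph$centerline$points[1, 2] + sp$thrombus_start + sp$thrombus_length / 2
  expect_equal(interp_volume(ph$cta, c(sp$vessel_offset_mm, y_mid, 0)), 112.5)
  expect_equal(ph$truth$true_delta_t, 62.5)
  # finitely many levels only
  lv_cta <- sort(unique(as.numeric(ph$cta$values)))
  expect_true(all(lv_cta %in% c(35, 45, 112.5, 300)))
  lv_ncct <- sort(unique(as.numeric(ph$ncct$values)))
  expect_true(all(lv_ncct %in% c(35, 45, 50)))
})

test_that("impermeable clot shows no CTA enhancement", {
  sp <- small_phantom_spec(noise_sd = 0, blur_fwhm = 0,
                           thrombus_uptake_frac = 0)
  ph <- generate_phantom(sp, seed = 1)
  y_mid <- ph$centerline$points[1, 2] + sp$thrombus_start + sp$thrombus_length / 2
  p <- c(sp$vessel_offset_mm, y_mid, 0)
  expect_equal(interp_volume(ph$cta, p), interp_volume(ph$ncct, p))
  expect_equal(ph$truth$true_void_fraction, 0)
})

test_that("phantoms are bit-identical under the same (spec, seed)", {
  sp <- small_phantom_spec()
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$cta$values, b$cta$values)
  expect_identical(a$ncct$values, b$ncct$values)
  c <- generate_phantom(sp, seed = 8)
  expect_false(identical(a$cta$values, c$cta$values))
})

test_that("noisy ROI mean stays within 3 SE of the noiseless value", {
  sp0 <- small_phantom_spec(noise_sd = 0)
  ph0 <- generate_phantom(sp0, seed = 1)
  y_mid <- ph0$centerline$points[1, 2] + sp0$thrombus_start +
    sp0$thrombus_length / 2
  roi <- structure(list(center_T = c(sp0$vessel_offset_mm, y_mid, 0),
                        center_C = c(-sp0$vessel_offset_mm, y_mid, 0),
                        radius = 1, plane_normal = c(0, 0, 1)),
                   class = "roi_pair")
  ref <- sample_mean_hu(ph0$cta, roi, "T", "CTA")
  sp <- small_phantom_spec(noise_sd = 10)
  means <- vapply(1:20, function(s) {
    sample_mean_hu(generate_phantom(sp, seed = s)$cta, roi, "T", "CTA")$mean_hu
  }, numeric(1))
  se <- 10 / sqrt(ref$voxel_count * 20)
  expect_lt(abs(mean(means) - ref$mean_hu), 3 * se)
})

test_that("ground-truth ledger is internally consistent", {
  set.seed(30)
  for (i in 1:10) {
    sp <- small_phantom_spec(thrombus_uptake_frac = runif(1),
                             thrombus_hu_ncct = runif(1, 40, 80),
                             contrast_hu = runif(1, 200, 400))
    tr <- generate_phantom(sp, seed = i)$truth
    expect_equal(tr$true_void_fraction, tr$true_delta_t / tr$true_delta_c)
    expect_equal(tr$true_delta_t,
                 sp$thrombus_uptake_frac * (sp$contrast_hu - sp$thrombus_hu_ncct))
  }
})

test_that("a vessel outside the volume raises a geometry error", {
  sp <- small_phantom_spec(vessel_offset_mm = 30)
  expect_error(generate_phantom(sp, seed = 1), class = "perv_geometry_error")
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(thrombus_uptake_frac = 1.2),
               class = "perv_input_error")
  expect_error(phantom_spec(contrast_hu = 30, background_hu = 35),
               class = "perv_input_error")
  expect_error(phantom_spec(thrombus_length = 0), class = "perv_input_error")
  expect_error(phantom_spec(noise_sd = -1), class = "perv_input_error")
})
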