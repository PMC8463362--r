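# centerline geometry, ROI placement, disc sampling, contrast-stop search

test_that("centerline arc length and interpolation are exact on lines", {
  path <- centerline_path(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 5, 0)))
  expect_equal(centerline_length(path), 15)
  expect_equal(centerline_point_at(path, 12), c(10, 2, 0))
  expect_error(centerline_point_at(path, 16), class = "perv_geometry_error")
  expect_error(centerline_path(rbind(c(0, 0, 0), c(0, 0, 0))),
               class = "perv_input_error")
})

test_that("place_rois follows the straight-line and mirror examples", {
  # straight centerline along +x, stop at (10,0,0), offset 1.5
  path <- centerline_path(rbind(c(0, 20, 0), c(30, 20, 0)),
                          mirror = rigid_transform(c(0, 180, 0)))
  roi <- place_rois(path, s_stop = 10, offset = 1.5, radius = 1)
  expect_equal(roi$center_T, c(11.5, 20, 0))
  # 180-degree rotation about y acts as reflection across x = 0 at z = 0
  expect_equal(roi$center_C, c(-11.5, 20, 0), tolerance = 1e-9)
  expect_error(place_rois(path, s_stop = 29, offset = 1.5),
               class = "perv_geometry_error")
})

test_that("ROI centre on a curved centerline matches the analytic circle", {
  # quarter circle of radius 20 in the xy plane, centred at the origin
  theta <- seq(0, pi / 2, length.out = 2001)
  pts <- cbind(20 * cos(theta), 20 * sin(theta), 0)
  path <- centerline_path(pts)
  s_stop <- 12
  roi <- place_rois(path, s_stop, offset = 1.5, radius = 1)
  phi <- (s_stop + 1.5) / 20
  expect_equal(roi$center_T, c(20 * cos(phi), 20 * sin(phi), 0),
               tolerance = 0.01)
})

test_that("mirrored centre snaps to a supplied contralateral centerline", {
  contra <- rbind(c(-12, 0, 0), c(-12, 40, 0))
  path <- centerline_path(rbind(c(10, 0, 0), c(10, 40, 0)),
                          mirror = rigid_transform(c(0, 180, 0)),
                          contralateral = contra)
  roi <- place_rois(path, s_stop = 20, offset = 1.5, radius = 1)
  expect_equal(roi$center_C, c(-12, 21.5, 0), tolerance = 1e-9)
})

test_that("disc sampling matches constants and the brute-force oracle", {
  vol <- ct_volume(array(42, c(20, 20, 10)), c(1, 1, 1), c(0, 0, 0))
  roi <- structure(list(center_T = c(10, 10, 5), center_C = c(5, 5, 5),
                        radius = 3, plane_normal = c(0, 0, 1)),
                   class = "roi_pair")
  s <- sample_mean_hu(vol, roi, "T", "CTA")
  expect_equal(s$mean_hu, 42)
  expect_equal(s$source, "CTA_T")

  # half-space volume: disc centred on the boundary, against voxel
  # enumeration
  hv <- array(0, c(30, 30, 6))
  yw <- (seq_len(30) - 1) * 0.7 - 10
  hv[, yw > 0, ] <- 100
  hvol <- ct_volume(hv, c(0.7, 0.7, 1.5), c(-10, -10, -4))
  roi2 <- structure(list(center_T = c(0, 0.05, 0), center_C = c(0, 0, 0),
                         radius = 4, plane_normal = c(0, 0, 1)),
                    class = "roi_pair")
  got <- sample_mean_hu(hvol, roi2, "T", "CTA")
  want <- oracle_disc_mean(hvol, roi2$center_T, roi2$radius)
  expect_equal(got$mean_hu, want$mean)
  expect_equal(got$voxel_count, want$count)

  # random ROIs against the oracle
  set.seed(14)
  rv <- ct_volume(array(rnorm(30 * 30 * 6, 50, 20), c(30, 30, 6)),
                  c(0.7, 0.7, 1.5), c(-10, -10, -4))
  for (i in 1:5) {
    ctr <- c(runif(2, -5, 5), runif(1, -2, 2))
    roi3 <- structure(list(center_T = ctr, center_C = ctr, radius = runif(1, 1, 4),
                           plane_normal = c(0, 0, 1)), class = "roi_pair")
    got <- sample_mean_hu(rv, roi3, "T", "NCCT")
    want <- oracle_disc_mean(rv, ctr, roi3$radius)
    expect_equal(got$mean_hu, want$mean, tolerance = 1e-12)
    expect_equal(got$voxel_count, want$count)
  }

  # ROI entirely outside -> sampling error
  roi4 <- structure(list(center_T = c(500, 500, 500), center_C = c(0, 0, 0),
                         radius = 1, plane_normal = c(0, 0, 1)),
                    class = "roi_pair")
  expect_error(sample_mean_hu(hvol, roi4, "T", "CTA"),
               class = "perv_sampling_error")
})

test_that("disc sampling on the noiseless phantom is exact", {
  sp <- small_phantom_spec(noise_sd = 0, blur_fwhm = 0)
  ph <- generate_phantom(sp, seed = 1)
  y_mid <- ph$centerline$points[1, 2] + sp$thrombus_start +
    sp$thrombus_length / 2
  roi <- structure(list(center_T = c(sp$vessel_offset_mm, y_mid, 0),
                        center_C = c(-sp$vessel_offset_mm, y_mid, 0),
                        radius = 1, plane_normal = c(0, 0, 1)),
                   class = "roi_pair")
  thr_cta <- sp$thrombus_hu_ncct +
    sp$thrombus_uptake_frac * (sp$contrast_hu - sp$thrombus_hu_ncct)
  expect_equal(sample_mean_hu(ph$cta, roi, "T", "CTA")$mean_hu, thr_cta)
  expect_equal(sample_mean_hu(ph$cta, roi, "C", "CTA")$mean_hu, sp$contrast_hu)
})

test_that("contrast stop is found on step profiles and errors otherwise", {
  # synthetic volume with a sharp 300 -> 55 step at y = 25 along a straight
  # centerline; no smoothing so the crossing is at the sample boundary
  vals <- array(55, c(12, 240, 8))
  yw <- (seq_len(240) - 1) * 0.25
  vals[, yw < 25, ] <- 300
  vol <- ct_volume(vals, c(1, 0.25, 1), c(0, 0, 0))
  path <- centerline_path(rbind(c(5, 0, 3), c(5, 55, 3)))
  cfg <- measure_config(stop_threshold = 100, stop_smooth_mm = 0)
  s <- locate_contrast_stop(vol, path, cfg)
  expect_lt(abs(as.numeric(s) - 25), 0.126)

  # fully patent vessel: no crossing
  patent <- ct_volume(array(300, c(12, 240, 8)), c(1, 0.25, 1), c(0, 0, 0))
  expect_error(locate_contrast_stop(patent, path, cfg),
               class = "perv_no_occlusion_error")

  # profile below threshold from the start: no patent proximal segment
  occl <- ct_volume(array(55, c(12, 240, 8)), c(1, 0.25, 1), c(0, 0, 0))
  expect_error(locate_contrast_stop(occl, path, cfg),
               class = "perv_no_proximal_error")
})

test_that("raising the threshold never moves the stop distally", {
  # monotonically decreasing profile along y
  vals <- array(0, c(12, 200, 8))
  yw <- (seq_len(200) - 1) * 0.25
  for (j in seq_len(200)) vals[, j, ] <- 300 - 5 * yw[j]
  vol <- ct_volume(vals, c(1, 0.25, 1), c(0, 0, 0))
  path <- centerline_path(rbind(c(5, 0, 3), c(5, 49, 3)))
  stops <- vapply(c(80, 120, 160, 200, 240), function(thr) {
    as.numeric(locate_contrast_stop(vol, path,
                                    measure_config(stop_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(stops) < 0))
})

test_that("auto threshold tracks the contrast stop across uptake levels", {
  for (up in c(0, 0.5)) {
    sp <- small_phantom_spec(thrombus_uptake_frac = up)
    ph <- generate_phantom(sp, seed = 4)
    s <- locate_contrast_stop(ph$cta, ph$centerline, measure_config())
    expect_lt(abs(as.numeric(s) - ph$truth$occlusion_arclength), 1.0)
  }
})

test_that("noisy stop localization stays within 1 mm over seeds", {
  sp <- small_phantom_spec()  # noise SD 8
  errs <- vapply(1:20, function(s) {
    ph <- generate_phantom(sp, seed = s)
    as.numeric(locate_contrast_stop(ph$cta, ph$centerline,
                                    measure_config())) -
      ph$truth$occlusion_arclength
  }, numeric(1))
  expect_lt(max(abs(errs)), 1.0)
})
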