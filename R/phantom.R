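#' Phantom specification
#'
#' Describes a paired NCCT/CTA digital phantom: a straight (or user-supplied
#' polyline) contrast-filled vessel with an occluding thrombus segment of
#' configurable baseline density and contrast uptake, plus its mirrored
#' contralateral patent vessel. The world frame is centred on the volume so
#' the midsagittal plane is x = 0 and the vessel plane is z = 0; the
#' left/right mirror is then the proper rotation of 180 degrees about y.
#'
#' Default HU values are plausible for 120-kV head CT: background (brain
#' parenchyma-ish) 35 HU, unenhanced blood 45 HU, red-cell-rich thrombus
#' 55 HU, opacified lumen 300 HU.
#'
#' @param volume_shape integer 3-vector of voxel counts.
#' @param spacing voxel spacing in mm; `spacing[3]` is slice thickness.
#' @param background_hu background tissue HU.
#' @param blood_hu unenhanced intraluminal blood HU (NCCT lumen, and the
#'   CTA value distal to the occlusion where no contrast arrives).
#' @param vessel_radius lumen radius in mm.
#' @param contrast_hu opacified (patent) lumen HU on CTA.
#' @param thrombus_hu_ncct baseline clot density on NCCT, HU.
#' @param thrombus_uptake_frac true contrast penetration fraction in `[0, 1]`;
#'   the thrombus CTA value is
#'   `thrombus_hu_ncct + uptake * (contrast_hu - thrombus_hu_ncct)`.
#' @param thrombus_start arc length (mm) from the proximal centerline end at
#'   which the thrombus begins (the true contrast stop).
#' @param thrombus_length thrombus extent along the centerline, mm (> 0).
#' @param noise_sd additive white Gaussian HU noise SD (after blurring).
#' @param blur_fwhm isotropic Gaussian blur FWHM in mm (scanner PSF stand-in).
#' @param vessel_offset_mm lateral distance of the vessel axis from the
#'   midsagittal plane, mm (used only for the default straight centerline).
#' @param centerline optional `centerline_path` overriding the default
#'   straight vessel (must include a mirror transform).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(96, 96, 24),
                         spacing = c(0.5, 0.5, 1.0),
                         background_hu = 35,
                         blood_hu = 45,
                         vessel_radius = 1.5,
                         contrast_hu = 300,
                         thrombus_hu_ncct = 55,
                         thrombus_uptake_frac = 0.25,
                         thrombus_start = 22,
                         thrombus_length = 10,
                         noise_sd = 8,
                         blur_fwhm = 0.8,
                         vessel_offset_mm = 10,
                         centerline = NULL) {
  check_num(volume_shape, "volume_shape", 3L, positive = TRUE)
  check_num(spacing, "spacing", 3L, positive = TRUE)
  check_num(thrombus_length, "thrombus_length", positive = TRUE)
  check_num(noise_sd, "noise_sd", nonneg = TRUE)
  check_num(blur_fwhm, "blur_fwhm", nonneg = TRUE)
  check_num(thrombus_uptake_frac, "thrombus_uptake_frac")
  if (thrombus_uptake_frac < 0 || thrombus_uptake_frac > 1) {
    perv_error("thrombus_uptake_frac must lie in [0, 1]", "perv_input_error")
  }
  if (contrast_hu <= background_hu) {
    perv_error("contrast_hu must exceed background_hu", "perv_input_error")
  }
  spec <- list(volume_shape = as.integer(volume_shape), spacing = spacing,
               background_hu = background_hu, blood_hu = blood_hu,
               vessel_radius = vessel_radius, contrast_hu = contrast_hu,
               thrombus_hu_ncct = thrombus_hu_ncct,
               thrombus_uptake_frac = thrombus_uptake_frac,
               thrombus_start = thrombus_start,
               thrombus_length = thrombus_length,
               noise_sd = noise_sd, blur_fwhm = blur_fwhm,
               vessel_offset_mm = vessel_offset_mm,
               centerline = centerline)
  class(spec) <- "phantom_spec"
  spec
}

# world origin placing the volume centre at (0, 0, 0)
phantom_origin <- function(spec) {
  -(spec$volume_shape - 1) / 2 * spec$spacing
}

# default straight centerline along +y at x = vessel_offset, z = 0,
# spanning most of the volume; mirror = 180 deg rotation about y
phantom_centerline <- function(spec) {
  if (!is.null(spec$centerline)) return(spec$centerline)
  ext <- (spec$volume_shape - 1) * spec$spacing
  half_y <- ext[2] / 2 - spec$vessel_radius - spec$spacing[2]
  occl <- rbind(c(spec$vessel_offset_mm, -half_y, 0),
                c(spec$vessel_offset_mm, half_y, 0))
  mirror <- rigid_transform(rotation_deg = c(0, 180, 0))
  contra <- apply_transform(mirror, occl)
  centerline_path(occl, mirror = mirror, contralateral = contra)
}

# distance to a polyline and arc length of the closest projection,
# vectorized over query points; polylines here have few segments
polyline_dist_arclen <- function(pts, arclen, q) {
  n <- nrow(q)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    t <- ((q[, 1] - a[1]) * ab[1] + (q[, 2] - a[2]) * ab[2] +
          (q[, 3] - a[3]) * ab[3]) / (len * len)
    t <- pmin(pmax(t, 0), 1)
    dx <- a[1] + t * ab[1] - q[, 1]
    dy <- a[2] + t * ab[2] - q[, 2]
    dz <- a[3] + t * ab[3] - q[, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- arclen[i] + t[upd] * len
  }
  list(dist = sqrt(best_d2), s = best_s)
}

#' Generate a paired NCCT/CTA phantom
#'
#' Builds piecewise-constant HU fields (patent lumen, thrombus segment,
#' unenhanced distal lumen, contralateral patent vessel, background), blurs
#' them with the point-spread FWHM and adds white HU noise. The same
#' `(spec, seed)` pair reproduces bit-identical volumes.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer RNG seed for the noise draws.
#' @return list with elements `ncct` and `cta` (`ct_volume`s), `centerline`
#'   (a `centerline_path`), and `truth` (a ground-truth ledger of class
#'   `phantom_truth` holding the noiseless HU values, deltas, void fraction,
#'   CTA-index and the occlusion arc length).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, blur_fwhm = 0), seed = 1)
#' ph$truth$true_void_fraction
#' @export
generate_phantom <- function(spec, seed = 1L) {
  if (!inherits(spec, "phantom_spec")) {
    perv_error("spec must be a phantom_spec", "perv_input_error")
  }
  path <- phantom_centerline(spec)
  origin <- phantom_origin(spec)
  d <- spec$volume_shape
  # geometry check: vessel tube must stay inside the voxel-centre extent
  bounds <- rbind(origin, origin + (d - 1) * spec$spacing)
  tube_lo <- apply(rbind(path$points, path$contralateral %||% path$points),
                   2, min) - spec$vessel_radius
  tube_hi <- apply(rbind(path$points, path$contralateral %||% path$points),
                   2, max) + spec$vessel_radius
  if (any(tube_lo < bounds[1, ] - 1e-9) || any(tube_hi > bounds[2, ] + 1e-9)) {
    perv_error("vessel leaves the volume bounds", "perv_geometry_error")
  }

  grid <- cbind(
    rep(origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1], times = d[2] * d[3]),
    rep(rep(origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2], each = d[1]),
        times = d[3]),
    rep(origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3], each = d[1] * d[2]))

  occl <- polyline_dist_arclen(path$points, path$arclen, grid)
  contra_pts <- path$contralateral %||% apply_transform(path$mirror, path$points)
  contra_arclen <- c(0, cumsum(sqrt(rowSums(
    (contra_pts[-1, , drop = FALSE] -
     contra_pts[-nrow(contra_pts), , drop = FALSE])^2))))
  contra <- polyline_dist_arclen(contra_pts, contra_arclen, grid)

  in_occl <- occl$dist <= spec$vessel_radius
  in_contra <- contra$dist <= spec$vessel_radius
  s0 <- spec$thrombus_start
  s1 <- spec$thrombus_start + spec$thrombus_length
  thr_cta <- spec$thrombus_hu_ncct +
    spec$thrombus_uptake_frac * (spec$contrast_hu - spec$thrombus_hu_ncct)

  cta <- rep(spec$background_hu, nrow(grid))
  ncct <- rep(spec$background_hu, nrow(grid))
  ncct[in_occl | in_contra] <- spec$blood_hu
  ncct[in_occl & occl$s >= s0 & occl$s <= s1] <- spec$thrombus_hu_ncct
  cta[in_contra] <- spec$contrast_hu
  cta[in_occl & occl$s < s0] <- spec$contrast_hu
  cta[in_occl & occl$s >= s0 & occl$s <= s1] <- thr_cta
  cta[in_occl & occl$s > s1] <- spec$blood_hu

  ncct_vol <- ct_volume(array(ncct, d), spec$spacing, origin)
  cta_vol <- ct_volume(array(cta, d), spec$spacing, origin)
  if (spec$blur_fwhm > 0) {
    ncct_vol <- blur_volume(ncct_vol, spec$blur_fwhm)
    cta_vol <- blur_volume(cta_vol, spec$blur_fwhm)
  }
  if (spec$noise_sd > 0) {
    with_seed(seed, {
      ncct_vol$values <- ncct_vol$values +
        array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
      cta_vol$values <- cta_vol$values +
        array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    })
  }

  truth <- structure(list(
    true_hu_t_cta = thr_cta,
    true_hu_c_cta = spec$contrast_hu,
    true_hu_t_ncct = spec$thrombus_hu_ncct,
    true_hu_c_ncct = spec$blood_hu,
    true_delta_t = thr_cta - spec$thrombus_hu_ncct,
    true_delta_c = spec$contrast_hu - spec$blood_hu,
    true_void_fraction = (thr_cta - spec$thrombus_hu_ncct) /
      (spec$contrast_hu - spec$blood_hu),
    true_cta_index = (thr_cta - spec$contrast_hu) /
      (thr_cta + spec$contrast_hu),
    occlusion_arclength = spec$thrombus_start
  ), class = "phantom_truth")

  list(ncct = ncct_vol, cta = cta_vol, centerline = path, truth = truth)
}
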