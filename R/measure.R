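#' Measurement configuration
#'
#' Tunable parameters of the image-measurement stage. The ROI radius default
#' (1.0 mm) is deliberately smaller than a proximal MCA lumen radius so the
#' disc avoids wall voxels; the ROI is placed `roi_offset` (1.5 mm) distal
#' of the detected contrast stop to dodge appositional thrombus growth at
#' the interface.
#'
#' @param roi_radius circular ROI radius, mm.
#' @param roi_offset distance distal of the contrast stop, mm.
#' @param plane_normal unit normal of the ROI plane (axial by default).
#' @param stop_threshold HU threshold for the contrast stop: a number for
#'   the absolute rule, or `"auto"` (default) for the two-pass midpoint rule
#'   (find a sustained drop below `auto_frac` of the proximal plateau, then
#'   re-threshold at the midpoint of the proximal and post-drop plateaus) —
#'   the absolute rule cannot see the stop when a pervious thrombus itself
#'   enhances past the threshold.
#' @param auto_frac fraction of the proximal plateau used by the coarse pass.
#' @param stop_persistence length (mm) the profile must stay below threshold.
#' @param stop_smooth_mm Gaussian smoothing sigma applied to the centerline
#'   HU profile, mm (0 disables).
#' @param stop_step profile sampling step along the centerline, mm.
#' @param register run rigid NCCT-to-CTA registration before sampling.
#' @param register_config a [register_config()].
#' @param axial_anchor re-anchor the NCCT thrombus ROI on the clot
#'   interface visible in the registered NCCT's own centerline profile.
#'   A straight vessel constrains a rigid registration only weakly along
#'   its own axis, so the residual axial error can exceed the ROI offset;
#'   the clot's proximal interface (clot typically a few HU denser than
#'   unenhanced blood) marks the same physical boundary as the CTA
#'   contrast stop and re-localizes the NCCT sampling site independently
#'   of that residual. Disabled automatically when the NCCT profile shows
#'   no usable contrast (see `anchor_min_contrast`).
#' @param anchor_min_contrast minimum NCCT profile range (HU) for the
#'   anchor to engage.
#' @param anchor_flag_mm axial shift (mm) beyond which the anchor raises a
#'   quality flag.
#' @return list of class `measure_config`.
#' @export
measure_config <- function(roi_radius = 1.0, roi_offset = 1.5,
                           plane_normal = c(0, 0, 1),
                           stop_threshold = "auto", auto_frac = 0.7,
                           stop_persistence = 1.0, stop_smooth_mm = 1.0,
                           stop_step = 0.25,
                           register = TRUE,
                           register_config = thromboperv::register_config(),
                           axial_anchor = TRUE,
                           anchor_min_contrast = 4,
                           anchor_flag_mm = 2) {
  check_num(roi_radius, "roi_radius", positive = TRUE)
  check_num(roi_offset, "roi_offset", nonneg = TRUE)
  structure(list(roi_radius = roi_radius, roi_offset = roi_offset,
                 plane_normal = plane_normal / sqrt(sum(plane_normal^2)),
                 stop_threshold = stop_threshold, auto_frac = auto_frac,
                 stop_persistence = stop_persistence,
                 stop_smooth_mm = stop_smooth_mm, stop_step = stop_step,
                 register = register, register_config = register_config,
                 axial_anchor = axial_anchor,
                 anchor_min_contrast = anchor_min_contrast,
                 anchor_flag_mm = anchor_flag_mm),
            class = "measure_config")
}

# smooth a regularly sampled profile with a Gaussian (replicated edges)
smooth_profile <- function(vals, sigma_steps) {
  if (sigma_steps < 1e-9) return(vals)
  w <- gauss_kernel(sigma_steps)
  r <- (length(w) - 1L) / 2L
  n <- length(vals)
  out <- numeric(n)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    out <- out + w[o + r + 1L] * vals[idx]
  }
  out
}

# first index at which vals stays below thr for >= persist_steps samples;
# 0 if never
first_sustained_below <- function(vals, thr, persist_steps) {
  below <- vals < thr
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= persist_steps) return(i - run + 1L)
  }
  0L
}

#' Locate the contrast stop along a vessel centerline
#'
#' Samples the CTA HU profile along the centerline at `stop_step` intervals
#' (trilinear interpolation), smooths it, and returns the smallest arc
#' length at which the profile falls below the threshold and stays below it
#' for at least the persistence length, refined to sub-step precision by
#' linear interpolation of the crossing.
#'
#' @param cta a `ct_volume` (arterial-phase CTA).
#' @param path a `centerline_path` lying inside the volume.
#' @param config a [measure_config()].
#' @return arc length `s_stop` in mm, with attributes `threshold` and
#'   `profile` (the smoothed profile as a two-column matrix).
#' @export
locate_contrast_stop <- function(cta, path, config = measure_config()) {
  L <- centerline_length(path)
  s <- seq(0, L, by = config$stop_step)
  pts <- centerline_point_at(path, s)
  raw <- interp_volume(cta, pts, fill = NA)
  if (any(is.na(raw))) {
    perv_error("centerline leaves the CTA volume", "perv_geometry_error")
  }
  prof <- smooth_profile(raw, config$stop_smooth_mm / config$stop_step)
  persist_steps <- max(1L, ceiling(config$stop_persistence / config$stop_step))

  find_stop <- function(thr) {
    idx <- first_sustained_below(prof, thr, persist_steps)
    if (idx == 0L) {
      perv_error("no occlusion detected: profile never falls below threshold",
                 "perv_no_occlusion_error")
    }
    if (idx == 1L) {
      perv_error("no patent proximal segment: profile below threshold at s = 0",
                 "perv_no_proximal_error")
    }
    # sub-step linear interpolation of the crossing between idx-1 and idx
    f <- (prof[idx - 1L] - thr) / (prof[idx - 1L] - prof[idx])
    s[idx - 1L] + f * config$stop_step
  }

  if (identical(config$stop_threshold, "auto")) {
    prox <- stats::median(prof[s <= min(5, L / 4)])
    s1 <- find_stop(config$auto_frac * prox)
    lo_win <- prof[s >= s1 + 1 & s <= s1 + 3]
    low <- if (length(lo_win)) stats::median(lo_win) else min(prof)
    thr <- (prox + low) / 2
  } else {
    thr <- config$stop_threshold
    check_num(thr, "stop_threshold")
  }
  s_stop <- find_stop(thr)
  attr(s_stop, "threshold") <- thr
  attr(s_stop, "profile") <- cbind(s = s, hu = prof)
  s_stop
}

#' Place the occlusion-site and contralateral ROIs
#'
#' The occlusion-site centre T is the centerline point `offset` mm distal of
#' the contrast stop; the contralateral centre C is its image under the
#' mirror transform, snapped to the nearest point of the contralateral
#' centerline when one is supplied.
#'
#' @param path a `centerline_path`.
#' @param s_stop contrast-stop arc length, mm.
#' @param offset distance distal of the stop, mm.
#' @param radius ROI radius, mm.
#' @param plane_normal unit normal of the ROI plane.
#' @return list of class `roi_pair`: `center_T`, `center_C`, `radius`,
#'   `plane_normal`.
#' @export
place_rois <- function(path, s_stop, offset = 1.5, radius = 1.0,
                       plane_normal = c(0, 0, 1)) {
  L <- centerline_length(path)
  if (s_stop + offset > L + 1e-9) {
    perv_error(sprintf(
      "ROI offset runs past the distal end of the centerline (%.2f + %.2f > %.2f mm)",
      s_stop, offset, L), "perv_geometry_error")
  }
  center_t <- centerline_point_at(path, s_stop + offset)
  center_c <- apply_transform(path$mirror, center_t)
  if (!is.null(path$contralateral)) {
    center_c <- nearest_on_polyline(path$contralateral, center_c)$point
  }
  structure(list(center_T = center_t, center_C = center_c, radius = radius,
                 plane_normal = plane_normal / sqrt(sum(plane_normal^2))),
            class = "roi_pair")
}

#' Mean HU over a circular ROI
#'
#' Averages the HU of every voxel whose centre lies within `radius` of the
#' ROI centre in the ROI plane and within half a slice thickness of the
#' plane along its normal.
#'
#' @param vol a `ct_volume`.
#' @param roi a `roi_pair` from [place_rois()].
#' @param side `"T"` (occlusion site) or `"C"` (contralateral).
#' @param scan scan label stored on the sample (`"CTA"` or `"NCCT"`).
#' @return list of class `attenuation_sample`: `mean_hu`, `voxel_count`,
#'   `source` (e.g. `"CTA_T"`).
#' @export
sample_mean_hu <- function(vol, roi, side = c("T", "C"),
                           scan = c("CTA", "NCCT")) {
  side <- match.arg(side)
  scan <- match.arg(scan)
  center <- if (side == "T") roi$center_T else roi$center_C
  n <- roi$plane_normal
  half_thick <- 0.5 * sum(abs(n) * vol$spacing)
  d <- dim(vol$values)
  # voxel index bounding box around the ROI
  reach <- roi$radius + half_thick
  lo <- pmax(1L, floor((center - reach - vol$origin) / vol$spacing) + 1L)
  hi <- pmin(d, ceiling((center + reach - vol$origin) / vol$spacing) + 1L)
  if (any(lo > hi)) {
    perv_error("ROI does not intersect the volume", "perv_sampling_error")
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- vol$origin[1] + (ii - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (jj - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (kk - 1) * vol$spacing[3]
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  dx <- g$x - center[1]; dy <- g$y - center[2]; dz <- g$z - center[3]
  along <- dx * n[1] + dy * n[2] + dz * n[3]
  inplane2 <- dx * dx + dy * dy + dz * dz - along * along
  inside <- abs(along) <= half_thick + 1e-9 &
    inplane2 <= roi$radius^2 + 1e-9
  if (!any(inside)) {
    perv_error("no voxel centres inside the ROI disc", "perv_sampling_error")
  }
  sub <- vol$values[ii, jj, kk, drop = FALSE]
  structure(list(mean_hu = mean(as.numeric(sub)[inside]),
                 voxel_count = sum(inside),
                 source = paste(scan, side, sep = "_")),
            class = "attenuation_sample")
}

# Locate the clot's proximal interface on the (registered) NCCT: disc-mean
# HU profile along the centerline, smoothed, first sustained upward
# crossing of the midpoint between the profile median and maximum.
# Returns the interface arc length, or NULL when the profile carries no
# usable contrast or never crosses upward.
locate_ncct_interface <- function(ncct, path, config) {
  L <- centerline_length(path)
  s <- seq(0, L, by = config$stop_step)
  prof <- vapply(s, function(si) {
    ctr <- centerline_point_at(path, si)
    roi <- structure(list(center_T = ctr, center_C = ctr,
                          radius = config$roi_radius,
                          plane_normal = config$plane_normal),
                     class = "roi_pair")
    tryCatch(sample_mean_hu(ncct, roi, "T", "NCCT")$mean_hu,
             perv_sampling_error = function(e) NA_real_)
  }, numeric(1))
  if (any(is.na(prof))) return(NULL)
  prof <- smooth_profile(prof, config$stop_smooth_mm / config$stop_step)
  if (max(prof) - stats::median(prof) < config$anchor_min_contrast) {
    return(NULL)
  }
  thr <- (stats::median(prof) + max(prof)) / 2
  persist <- max(1L, ceiling(config$stop_persistence / config$stop_step))
  above <- prof > thr
  run <- 0L
  idx <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persist) { idx <- i - run + 1L; break }
  }
  if (idx <= 1L) return(NULL)
  f <- (thr - prof[idx - 1L]) / (prof[idx] - prof[idx - 1L])
  s[idx - 1L] + f * config$stop_step
}

#' Measure one patient (or phantom)
#'
#' Full imaging pipeline: rigid registration of the NCCT onto the CTA grid,
#' contrast-stop localization on the CTA centerline profile, ROI placement
#' 1.5 mm distal of the stop with a mirrored contralateral reference, and
#' mean-HU sampling of both ROIs on both (registered) scans.
#'
#' @param ncct,cta `ct_volume`s in HU.
#' @param path a `centerline_path` of the occluded vessel.
#' @param config a [measure_config()].
#' @return list of class `perv_measurement`: `samples` (named list
#'   `cta_t`, `cta_c`, `ncct_t`, `ncct_c` of `attenuation_sample`s) and
#'   `provenance` (transform, registration convergence, `s_stop`, detected
#'   threshold, ROI geometry, voxel counts, flags).
#' @export
measure_patient <- function(ncct, cta, path, config = measure_config()) {
  flags <- character(0)
  if (config$register) {
    reg <- withCallingHandlers(
      register_rigid(ncct, cta, config$register_config),
      warning = function(w) {
        flags <<- c(flags, "registration_not_converged")
        invokeRestart("muffleWarning")
      })
    tf <- reg$transform
    ncct_use <- resample_volume(ncct, tf, cta)
  } else {
    reg <- NULL
    tf <- rigid_transform()
    ncct_use <- ncct
  }
  s_stop <- locate_contrast_stop(cta, path, config)
  roi <- place_rois(path, s_stop, offset = config$roi_offset,
                    radius = config$roi_radius,
                    plane_normal = config$plane_normal)
  # NCCT sampling sites default to the CTA-derived ROI pair; the axial
  # anchor replaces them with positions tied to the clot interface seen on
  # the NCCT itself when that interface is detectable
  roi_ncct <- roi
  anchor <- NULL
  if (isTRUE(config$axial_anchor)) {
    s_iface <- locate_ncct_interface(ncct_use, path, config)
    if (!is.null(s_iface) &&
        s_iface + config$roi_offset <= centerline_length(path)) {
      roi_ncct <- place_rois(path, s_iface, offset = config$roi_offset,
                             radius = config$roi_radius,
                             plane_normal = config$plane_normal)
      shift <- as.numeric(s_iface) - as.numeric(s_stop)
      anchor <- list(applied = TRUE, s_interface = as.numeric(s_iface),
                     shift_mm = shift)
      if (abs(shift) > config$anchor_flag_mm) {
        flags <- c(flags, "ncct_anchor_large_shift")
      }
    } else {
      anchor <- list(applied = FALSE)
    }
  }
  samples <- list(
    cta_t = sample_mean_hu(cta, roi, "T", "CTA"),
    cta_c = sample_mean_hu(cta, roi, "C", "CTA"),
    ncct_t = sample_mean_hu(ncct_use, roi_ncct, "T", "NCCT"),
    ncct_c = sample_mean_hu(ncct_use, roi_ncct, "C", "NCCT"))
  prov <- list(
    transform = tf,
    registration = if (is.null(reg)) NULL else
      list(converged = reg$converged, metric = reg$metric,
           metric_value = reg$metric_value),
    s_stop = as.numeric(s_stop),
    stop_threshold = attr(s_stop, "threshold"),
    roi = list(center_T = roi$center_T, center_C = roi$center_C,
               radius = roi$radius, plane_normal = roi$plane_normal),
    ncct_anchor = anchor,
    voxel_counts = vapply(samples, function(s) s$voxel_count, integer(1)),
    flags = flags)
  structure(list(samples = samples, provenance = prov),
            class = "perv_measurement")
}
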