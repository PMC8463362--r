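#' CT volume container
#'
#' A 3-D scalar field of calibrated Hounsfield units on an axis-aligned,
#' right-handed world grid. World coordinates of voxel (i, j, k) (1-based)
#' are `origin + (c(i, j, k) - 1) * spacing`, all in millimetres. The third
#' axis is the slice (z) direction; `spacing[3]` is the slice thickness used
#' as a cohort covariate.
#'
#' @param values 3-D numeric array of HU.
#' @param spacing numeric 3-vector of voxel spacing in mm (> 0).
#' @param origin numeric 3-vector, world position of voxel (1,1,1) centre.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    perv_error("values must be a 3-D array", "perv_input_error")
  }
  if (any(!is.finite(values))) {
    perv_error("HU values must be finite", "perv_input_error")
  }
  check_num(spacing, "spacing", 3L, positive = TRUE)
  check_num(origin, "origin", 3L)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "ct_volume: %d x %d x %d voxels, spacing [%s] mm, HU range [%.1f, %.1f]\n",
    d[1], d[2], d[3], paste(x$spacing, collapse = ", "),
    min(x$values), max(x$values)))
  invisible(x)
}

# world coordinate of the geometric volume centre
volume_center_world <- function(vol) {
  vol$origin + (dim(vol$values) - 1) / 2 * vol$spacing
}

# world-space bounding box (voxel-centre extent), rows = min/max
volume_bounds_world <- function(vol) {
  rbind(vol$origin, vol$origin + (dim(vol$values) - 1) * vol$spacing)
}

#' Trilinear interpolation of a volume at world points
#'
#' @param vol a `ct_volume`.
#' @param pts n x 3 matrix (or 3-vector) of world points in mm.
#' @param fill value returned for points outside the voxel-centre grid.
#' @return numeric vector of interpolated HU.
#' @export
interp_volume <- function(vol, pts, fill = NA_real_) {
  p <- if (is.null(dim(pts))) matrix(pts, 1, 3) else as.matrix(pts)
  d <- dim(vol$values)
  # continuous 0-based voxel coordinates
  v1 <- (p[, 1] - vol$origin[1]) / vol$spacing[1]
  v2 <- (p[, 2] - vol$origin[2]) / vol$spacing[2]
  v3 <- (p[, 3] - vol$origin[3]) / vol$spacing[3]
  eps <- 1e-9
  ok <- v1 >= -eps & v1 <= d[1] - 1 + eps &
        v2 >= -eps & v2 <= d[2] - 1 + eps &
        v3 >= -eps & v3 <= d[3] - 1 + eps
  out <- rep(fill, nrow(p))
  if (!any(ok)) return(out)
  v1 <- pmin(pmax(v1[ok], 0), d[1] - 1)
  v2 <- pmin(pmax(v2[ok], 0), d[2] - 1)
  v3 <- pmin(pmax(v3[ok], 0), d[3] - 1)
  i0 <- pmin(floor(v1), d[1] - 2); i0[d[1] == 1] <- 0
  j0 <- pmin(floor(v2), d[2] - 2); j0[d[2] == 1] <- 0
  k0 <- pmin(floor(v3), d[3] - 2); k0[d[3] == 1] <- 0
  fx <- v1 - i0; fy <- v2 - j0; fz <- v3 - k0
  i1 <- pmin(i0 + 1, d[1] - 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  vals <- vol$values
  lin <- function(i, j, k) vals[1 + i + d[1] * (j + d[2] * k)]
  c000 <- lin(i0, j0, k0); c100 <- lin(i1, j0, k0)
  c010 <- lin(i0, j1, k0); c110 <- lin(i1, j1, k0)
  c001 <- lin(i0, j0, k1); c101 <- lin(i1, j0, k1)
  c011 <- lin(i0, j1, k1); c111 <- lin(i1, j1, k1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# 1-D Gaussian kernel in voxel units; radius 3 sigma, normalized
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w / sum(w)
}

# separable Gaussian blur with replicated edges; sigma given in mm per axis
blur_volume_values <- function(values, sigma_mm, spacing) {
  d <- dim(values)
  out <- values
  for (ax in 1:3) {
    s_vox <- sigma_mm[ax] / spacing[ax]
    if (s_vox < 1e-6 || d[ax] == 1L) next
    w <- gauss_kernel(s_vox)
    r <- (length(w) - 1L) / 2L
    acc <- array(0, d)
    base <- seq_len(d[ax])
    for (o in -r:r) {
      idx <- pmin(pmax(base + o, 1L), d[ax])
      shifted <- switch(ax,
                        out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- acc + w[o + r + 1L] * shifted
    }
    out <- acc
  }
  out
}

#' Gaussian smoothing of a CT volume
#' @param vol a `ct_volume`.
#' @param fwhm_mm full width at half maximum of the kernel, in mm
#'   (scalar or per-axis 3-vector); 0 disables smoothing.
#' @return smoothed `ct_volume`.
#' @export
blur_volume <- function(vol, fwhm_mm) {
  fwhm <- rep_len(as.numeric(fwhm_mm), 3L)
  check_num(fwhm, "fwhm_mm", 3L, nonneg = TRUE)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ct_volume(blur_volume_values(vol$values, sigma, vol$spacing),
            vol$spacing, vol$origin)
}

# pyramid level: smooth (sigma = factor/2 voxels) then decimate
downsample_volume <- function(vol, factor) {
  if (factor <= 1L) return(vol)
  sigma_mm <- vol$spacing * factor / 2
  sm <- blur_volume_values(vol$values, sigma_mm, vol$spacing)
  d <- dim(sm)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  ct_volume(sm[ix, iy, iz, drop = FALSE], vol$spacing * factor, vol$origin)
}

# n x 3 matrix of world coordinates of every voxel centre (column-major order)
voxel_centers_world <- function(vol) {
  d <- dim(vol$values)
  x <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  y <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  z <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(rep(x, times = d[2] * d[3]),
        rep(rep(y, each = d[1]), times = d[3]),
        rep(z, each = d[1] * d[2]))
}

#' Resample a volume through a rigid transform
#'
#' Pull-resampling: the output shares the grid of `reference` and takes the
#' value `moving(T(x))` at each reference voxel centre `x`, with trilinear
#' interpolation.
#'
#' @param moving `ct_volume` to be resampled.
#' @param tf `rigid_transform` mapping reference (fixed) world points into
#'   the moving volume's world frame.
#' @param reference `ct_volume` defining the output grid.
#' @param fill HU value for points falling outside `moving`
#'   (default: minimum of `moving`).
#' @return resampled `ct_volume` on the reference grid.
#' @export
resample_volume <- function(moving, tf, reference, fill = NULL) {
  if (is.null(fill)) fill <- min(moving$values)
  pts <- apply_transform(tf, voxel_centers_world(reference))
  vals <- interp_volume(moving, pts, fill = fill)
  ct_volume(array(vals, dim(reference$values)),
            reference$spacing, reference$origin)
}
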