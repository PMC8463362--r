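#' Registration configuration
#'
#' Settings for [register_rigid()]. Everything is fixed and deterministic:
#' the pyramid schedule, the metric sampling (strided, not random) and the
#' optimizer iteration caps, so identical inputs give identical transforms.
#'
#' @param metric similarity metric: `"cr"` (correlation ratio of the moving
#'   intensity conditioned on fixed-intensity classes; the default — it
#'   handles the non-monotone NCCT-to-CTA intensity mapping and, unlike
#'   histogram mutual information, its within-class variance penalty cannot
#'   reward a misalignment), `"mi"` (mutual information with partial-volume
#'   bin weighting, Mattes-style) or `"ncc"` (Pearson correlation, for
#'   same-modality problems).
#' @param bins intensity bins per axis for the joint histogram.
#' @param levels pyramid downsampling factors, coarsest first.
#' @param sample_target approximate number of fixed-grid sample points used
#'   for the metric at each level.
#' @param init_translation run the brute-force cross-correlation translation
#'   initializer before optimization.
#' @param init_search_mm half-width of the initializer's translation search.
#' @param max_evals metric-evaluation cap per level.
#' @param step0_mm,step0_deg initial coordinate-descent steps at the finest
#'   level (scaled up by the pyramid factor at coarser levels).
#' @param min_step_mm,min_step_deg convergence thresholds.
#' @param fine_smooth_fwhm Gaussian FWHM (mm) applied to both volumes at the
#'   full-resolution level to suppress per-voxel HU noise.
#' @param final_scan_mm half-width (mm) of the per-axis translation sweep
#'   run after the pyramid to escape competing basins along weakly
#'   determined axes; 0 disables.
#' @param center rotation centre in world mm; default: fixed-volume centre.
#' @return list of class `register_config`.
#' @export
register_config <- function(metric = c("cr", "mi", "ncc"), bins = 32,
                            levels = c(4, 2, 1), sample_target = 9000,
                            init_translation = TRUE, init_search_mm = 8,
                            max_evals = 600,
                            step0_mm = 0.5, step0_deg = 0.5,
                            min_step_mm = 0.02, min_step_deg = 0.02,
                            fine_smooth_fwhm = 1.0,
                            final_scan_mm = 12,
                            center = NULL) {
  structure(list(metric = match.arg(metric), bins = bins, levels = levels,
                 sample_target = sample_target,
                 init_translation = init_translation,
                 init_search_mm = init_search_mm, max_evals = max_evals,
                 step0_mm = step0_mm, step0_deg = step0_deg,
                 min_step_mm = min_step_mm, min_step_deg = min_step_deg,
                 fine_smooth_fwhm = fine_smooth_fwhm,
                 final_scan_mm = final_scan_mm,
                 center = center),
            class = "register_config")
}

# similarity between paired samples; larger is better
similarity_value <- function(fv, mv, metric, bins, f_range, m_range) {
  if (metric == "ncc") {
    if (stats::sd(fv) == 0 || stats::sd(mv) == 0) return(0)
    return(stats::cor(fv, mv))
  }
  if (metric == "cr") {
    # correlation ratio eta^2(moving | fixed bins): fraction of moving
    # variance explained by the fixed-intensity class. Unlike Pearson
    # correlation it needs no monotone intensity mapping, and unlike
    # histogram MI its within-class variance penalty responds at first
    # order to any class mixing, so it cannot reward a misalignment.
    tot <- sum((mv - mean(mv))^2)
    if (tot == 0) return(0)
    b <- pmin(pmax(floor((fv - f_range[1]) / (f_range[2] - f_range[1]) * bins),
                   0), bins - 1) + 1L
    s1 <- rowsum(mv, b)
    s2 <- rowsum(mv * mv, b)
    grp <- as.integer(rownames(s1))
    nb <- tabulate(b, nbins = bins)
    wss <- sum(s2[, 1]) - sum(s1[, 1]^2 / nb[grp])
    return(1 - wss / tot)
  }
  nb <- bins
  uf <- (fv - f_range[1]) / (f_range[2] - f_range[1]) * (nb - 1)
  um <- (mv - m_range[1]) / (m_range[2] - m_range[1]) * (nb - 1)
  uf <- pmin(pmax(uf, 0), nb - 1 - 1e-9)
  um <- pmin(pmax(um, 0), nb - 1 - 1e-9)
  i0 <- floor(uf); wi <- uf - i0
  j0 <- floor(um); wj <- um - j0
  joint <- numeric(nb * nb)
  add <- function(i, j, w) {
    idx <- i + nb * j + 1
    acc <- rowsum(w, idx)
    joint[as.integer(rownames(acc))] <<- joint[as.integer(rownames(acc))] + acc
  }
  add(i0, j0, (1 - wi) * (1 - wj))
  add(i0 + 1, j0, wi * (1 - wj))
  add(i0, j0 + 1, (1 - wi) * wj)
  add(i0 + 1, j0 + 1, wi * wj)
  p <- joint / sum(joint)
  pj <- matrix(p, nb, nb)
  pf <- rowSums(pj); pm <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pf[row(pj)[nz]] * pm[col(pj)[nz]])))
}

# deterministic metric sample: voxels well above background plus a dilated
# shell around them (the gradient-bearing neighbourhood where misalignment
# actually shows), topped up with a stride sample of the background
metric_sample_points <- function(fixed, target, dilate = 4L,
                                 uniform = FALSE) {
  v <- fixed$values
  d <- dim(v)
  if (uniform) {
    # plain stride sample of the whole grid: right for correlation on
    # same-modality problems, where the shared noise field itself is the
    # sharpest alignment signal and foreground selection only biases it
    mask <- array(FALSE, d)
  } else {
    med <- stats::median(v)
    thr <- med + 0.25 * (max(v) - med)
    mask <- v > thr
  }
  if (any(mask) && !all(mask)) {
    for (it in seq_len(dilate)) {
      m <- mask
      m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
      m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
      m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
      m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
      m[, , -1] <- m[, , -1] | mask[, , -d[3]]
      m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
      mask <- m
    }
  }
  fg <- which(mask)
  rest <- which(!mask)
  if (length(rest)) {
    n_rest <- max(target - length(fg), min(1000L, target))
    stride <- max(1L, floor(length(rest) / n_rest))
    keep <- sort(c(fg, rest[seq(1L, length(rest), by = stride)]))
  } else {
    keep <- fg
  }
  pts <- voxel_centers_world(fixed)[keep, , drop = FALSE]
  # jitter sample positions off the voxel lattice (deterministic seed):
  # on-grid samples make the metric oscillate with the grid period because
  # interpolation averages noise only at off-grid alignments
  jit <- with_seed(760117L, {
    matrix(stats::runif(length(pts), -0.5, 0.5), ncol = 3)
  })
  pts <- pts + jit %*% diag(fixed$spacing)
  vals <- interp_volume(fixed, pts, fill = NA)
  ok <- !is.na(vals)
  list(pts = pts[ok, , drop = FALSE], vals = vals[ok])
}

#' Rigid NCCT-to-CTA registration
#'
#' Estimates the 6-DOF rigid transform mapping fixed-volume world points
#' into the moving volume's frame (the transform to hand to
#' [resample_volume()] to bring `moving` onto the fixed grid). Pipeline:
#' optional brute-force integer-voxel translation search by normalized
#' cross-correlation, then multi-resolution coordinate-descent maximization
#' of the similarity metric with step halving, all with fixed schedules.
#'
#' @param moving `ct_volume` to align (e.g. the NCCT).
#' @param fixed reference `ct_volume` (e.g. the CTA).
#' @param config a [register_config()].
#' @return list of class `rigid_registration`: `transform`
#'   (`rigid_transform`), `converged` (logical; `FALSE` flags that the
#'   evaluation cap was hit before the step sizes shrank to threshold),
#'   `metric_value` (final similarity), `metric`, `n_evals`.
#' @export
register_rigid <- function(moving, fixed, config = register_config()) {
  bf <- volume_bounds_world(fixed)
  bm <- volume_bounds_world(moving)
  if (any(bf[1, ] > bm[2, ]) || any(bm[1, ] > bf[2, ])) {
    perv_error("fixed and moving volumes do not overlap in world space",
               "perv_registration_error")
  }
  center <- config$center %||% volume_center_world(fixed)
  f_range <- range(fixed$values)
  m_range <- range(moving$values)

  par <- c(0, 0, 0, 0, 0, 0)  # rx, ry, rz (deg), tx, ty, tz (mm)
  n_evals <- 0L

  make_metric <- function(fixed_l, moving_l) {
    smp <- metric_sample_points(fixed_l, config$sample_target, uniform = config$metric == "ncc")
    fill <- m_range[1]
    function(p) {
      n_evals <<- n_evals + 1L
      tf <- rigid_transform(p[1:3], p[4:6], center)
      mv <- interp_volume(moving_l, apply_transform(tf, smp$pts), fill = NA)
      ok <- !is.na(mv)
      frac <- mean(ok)
      if (sum(ok) < 50 || frac < 0.5) return(-Inf)
      # weight by the in-bounds fraction: an unweighted metric can grow
      # spuriously as the overlap shrinks and samples drop out
      frac * similarity_value(smp$vals[ok], mv[ok], config$metric,
                              config$bins, f_range, m_range)
    }
  }

  # translation initializer: three brute-force NCC stages — wide search on
  # the coarse pyramid level, then medium and voxel-step passes at full
  # resolution. Every candidate is an integer-voxel translation, so a pure
  # integer-voxel shift is recovered exactly. The wide full-resolution pass
  # matters when the structure is nearly translation-invariant along one
  # axis (a straight vessel): the global optimum is then a shallow peak a
  # purely local optimizer can miss.
  if (config$init_translation) {
    coarse_f <- downsample_volume(fixed, max(config$levels))
    coarse_m <- downsample_volume(moving, max(config$levels))
    smp <- metric_sample_points(coarse_f, config$sample_target, uniform = config$metric == "ncc")
    search_one <- function(mov, step_mm, half_mm, t0) {
      half_mm <- rep_len(half_mm, 3L)
      ticks <- lapply(1:3, function(a) {
        k <- ceiling(half_mm[a] / step_mm[a])
        t0[a] + step_mm[a] * (-k:k)
      })
      best <- c(-Inf, t0)
      for (tz in ticks[[3]]) for (ty in ticks[[2]]) for (tx in ticks[[1]]) {
        mv <- interp_volume(mov, cbind(smp$pts[, 1] + tx, smp$pts[, 2] + ty,
                                       smp$pts[, 3] + tz), fill = NA)
        ok <- !is.na(mv)
        if (mean(ok) < 0.6 || sum(ok) < 50 || stats::sd(mv[ok]) == 0) next
        # the full metric, not plain correlation: the NCCT-to-CTA intensity
        # mapping is non-monotone (patent lumen bright on CTA but dark on
        # NCCT), which can make Pearson correlation prefer a false shift
        v <- mean(ok) * similarity_value(smp$vals[ok], mv[ok], config$metric,
                                         config$bins, f_range, m_range)
        if (v > best[1]) best <- c(v, tx, ty, tz)
      }
      best[2:4]
    }
    t_coarse <- search_one(coarse_m, coarse_f$spacing, config$init_search_mm,
                           c(0, 0, 0))
    smp_full <- metric_sample_points(fixed, config$sample_target, uniform = config$metric == "ncc")
    sub <- seq(1L, nrow(smp_full$pts),
               by = max(1L, floor(nrow(smp_full$pts) / 3000)))
    smp <- list(pts = smp_full$pts[sub, , drop = FALSE],
                vals = smp_full$vals[sub])
    t_mid <- search_one(moving, pmax(2, moving$spacing),
                        config$init_search_mm, t_coarse)
    smp <- smp_full
    par[4:6] <- search_one(moving, moving$spacing, 2 * moving$spacing, t_mid)
  }

  converged <- TRUE
  final_metric <- NA_real_

  # coordinate descent with step halving; returns the improved parameters
  cd_run <- function(par, metric_fn, step, min_step, eval_budget) {
    if (eval_budget < 2) {
      return(list(par = par, f = metric_fn(par), converged = TRUE))
    }
    f_cur <- metric_fn(par)
    level_evals <- 0L
    ok <- TRUE
    while (any(step > min_step)) {
      moved <- FALSE
      for (i in 1:6) {
        repeat {
          cand_up <- par; cand_up[i] <- cand_up[i] + step[i]
          cand_dn <- par; cand_dn[i] <- cand_dn[i] - step[i]
          f_up <- metric_fn(cand_up); f_dn <- metric_fn(cand_dn)
          level_evals <- level_evals + 2L
          if (f_up > f_cur && f_up >= f_dn) {
            par <- cand_up; f_cur <- f_up
          } else if (f_dn > f_cur) {
            par <- cand_dn; f_cur <- f_dn
          } else break
          moved <- TRUE
          if (level_evals >= eval_budget) break
        }
        if (level_evals >= eval_budget) break
      }
      if (level_evals >= eval_budget) {
        if (any(step > min_step)) ok <- FALSE
        break
      }
      if (!moved) step <- step / 2
    }
    list(par = par, f = f_cur, converged = ok)
  }

  min_step <- c(rep(config$min_step_deg, 3), rep(config$min_step_mm, 3))
  metric_fn <- NULL
  for (lev in config$levels) {
    if (lev > 1L) {
      fixed_l <- downsample_volume(fixed, lev)
      moving_l <- downsample_volume(moving, lev)
    } else {
      # mild smoothing at full resolution knocks down per-voxel HU noise
      # without materially widening the vessel edges
      fixed_l <- blur_volume(fixed, config$fine_smooth_fwhm)
      moving_l <- blur_volume(moving, config$fine_smooth_fwhm)
    }
    metric_fn <- make_metric(fixed_l, moving_l)
    step <- c(rep(config$step0_deg * lev, 3), rep(config$step0_mm * lev, 3))
    run <- cd_run(par, metric_fn, step, min_step, config$max_evals)
    par <- run$par
    final_metric <- run$f
    converged <- converged && run$converged
  }

  # basin-escape guard: near-axial structures (a straight vessel) admit
  # competing translation optima several mm apart along the vessel axis
  # that local descent cannot cross. With the rotation already settled,
  # sweep each translation axis at the finest level; if a sweep finds a
  # better basin, restart the fine-level descent from it.
  if (config$final_scan_mm > 0) {
    best <- list(par = par, f = final_metric)
    for (axis in 4:6) {
      for (off in seq(-config$final_scan_mm, config$final_scan_mm, by = 1)) {
        cand <- par; cand[axis] <- cand[axis] + off
        f <- metric_fn(cand)
        if (f > best$f) best <- list(par = cand, f = f)
      }
    }
    if (any(best$par != par)) {
      run <- cd_run(best$par, metric_fn,
                    c(rep(config$step0_deg, 3), rep(config$step0_mm, 3)),
                    min_step, config$max_evals)
      if (run$f > final_metric) {
        par <- run$par
        final_metric <- run$f
        converged <- converged && run$converged
      }
    }
  }

  # polish pass: a fresh small-step descent at the finest level releases
  # stalls where earlier step halving collapsed one coordinate before a
  # coupled coordinate (e.g. rotation vs translation) had caught up
  run <- cd_run(par, metric_fn,
                c(rep(0.25, 3), rep(0.25, 3)), min_step, config$max_evals)
  par <- run$par
  final_metric <- run$f
  res <- list(transform = rigid_transform(par[1:3], par[4:6], center),
              converged = converged, metric_value = final_metric,
              metric = config$metric, n_evals = n_evals)
  class(res) <- "rigid_registration"
  if (!converged) {
    warning(sprintf(
      "rigid registration hit its evaluation cap before convergence (metric %.4f)",
      final_metric))
  }
  res
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("rigid_registration (%s, %s): metric %.4f, %d evals\n",
              x$metric, if (x$converged) "converged" else "NOT converged",
              x$metric_value, x$n_evals))
  print(x$transform)
  invisible(x)
}
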