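# Independent oracles used across the suite. Each is written from first
# principles (enumeration, brute force, closed form) and must stay
# independent of the implementation path it checks.

# perviousness metrics, re-derived arithmetic (duplicate implementation)
oracle_metrics <- function(hu_t_cta, hu_c_cta, hu_t_ncct, hu_c_ncct) {
  dt <- hu_t_cta - hu_t_ncct
  dc <- hu_c_cta - hu_c_ncct
  list(delta_t = dt, delta_c = dc, void_fraction = dt / dc,
       cta_index = (hu_t_cta - hu_c_cta) / (hu_t_cta + hu_c_cta))
}

# Mann-Whitney U null distribution by dynamic programming over rank sums:
# f(n, k, s) = number of k-subsets of 1..n with rank sum s
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  smax <- na * n
  counts <- matrix(0, nrow = na + 1, ncol = smax + 1)  # [k+1, s+1]
  counts[1, 1] <- 1
  for (item in seq_len(n)) {
    for (k in rev(seq_len(min(item, na)))) {
      shifted <- c(rep(0, item), counts[k, seq_len(smax + 1 - item)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  dist <- counts[na + 1, ]
  s_vals <- 0:smax
  u_vals <- s_vals - na * (na + 1) / 2
  mu <- na * nb / 2
  sum(dist[abs(u_vals - mu) >= abs(u_obs - mu) - 1e-9]) / sum(dist)
}

# ICC(2,1) from an explicitly built two-way ANOVA table
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# brute-force voxel enumeration for disc mean-HU sampling (triple loop)
oracle_disc_mean <- function(vol, center, radius, normal = c(0, 0, 1)) {
  n <- normal / sqrt(sum(normal^2))
  half_thick <- 0.5 * sum(abs(n) * vol$spacing)
  d <- dim(vol$values)
  vals <- c(); count <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    dvec <- p - center
    along <- sum(dvec * n)
    inplane2 <- sum(dvec^2) - along^2
    if (abs(along) <= half_thick + 1e-9 && inplane2 <= radius^2 + 1e-9) {
      vals <- c(vals, vol$values[i, j, k]); count <- count + 1L
    }
  }
  list(mean = mean(vals), count = count)
}

# small phantom spec for fast unit tests (64 x 64 x 16 voxels)
small_phantom_spec <- function(vessel_offset_mm = 7, ...) {
  phantom_spec(volume_shape = c(64, 64, 16), spacing = c(0.5, 0.5, 1.0),
               thrombus_start = 12, thrombus_length = 8,
               vessel_offset_mm = vessel_offset_mm, ...)
}
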