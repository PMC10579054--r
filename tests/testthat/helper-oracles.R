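# Independent brute-force oracles, deliberately naive.

# exact two-sided signed-rank p by full enumeration of all 2^n sign vectors
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  W <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# naive loop over voxels: count of in-mask voxels at/above frac * max
bf_threshold_count <- function(values, mask, frac = 0.4) {
  smax <- -Inf
  for (i in seq_along(values)) if (mask[i] && values[i] > smax) smax <- values[i]
  cnt <- 0L
  for (i in seq_along(values)) {
    if (mask[i] && values[i] >= frac * smax) cnt <- cnt + 1L
  }
  cnt
}

# naive sphere mean around a center voxel (index triple), radius in mm
bf_sphere_mean <- function(values, spacing, center, radius_mm) {
  dims <- dim(values)
  acc <- 0
  n <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    d2 <- sum(((c(i, j, k) - center) * spacing)^2)
    if (d2 <= radius_mm^2) {
      acc <- acc + values[i, j, k]
      n <- n + 1L
    }
  }
  acc / n
}

# hand trapezoid over (0,0), (8,p8), (28,p28) divided by 28
bf_twa <- function(p8, p28) {
  (0.5 * 8 * (0 + p8) + 0.5 * 20 * (p8 + p28)) / 28
}

# tiny test phantom: one Gaussian lesion in a small grid
small_phantom <- function(peak = 10, noise = 0.05, seed = 1,
                          grid = c(20, 20, 20), sigma = 6) {
  generate_phantom(phantom_spec(
    grid_shape = grid, voxel_spacing_mm = c(4, 4, 4),
    lesions = list(lesion_spec(ceiling(grid / 2), peak_suv = peak, sigma_mm = sigma)),
    reference_center_voxel = c(5, 5, 5), reference_radii_mm = c(6, 6, 6),
    pet_noise_sd = noise, seed = seed
  ))
}
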