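# shared fixture builders; everything is generated in code at test time

# expected bin contents of a periodic single-exponential decay (exact bin
# integrals, i.e. the noiseless infinite-photon histogram)
decay_histogram <- function(tau_ns, period_ns, n_bins) {
  edges <- seq(0, period_ns, length.out = n_bins + 1)
  diff((1 - exp(-edges / tau_ns)) / (1 - exp(-period_ns / tau_ns)))
}

# closed-form phasor of a single-exponential decay
closed_form_phasor <- function(tau_ns, rep_hz = 78e6, harmonic = 1) {
  wt <- 2 * pi * harmonic * rep_hz * tau_ns * 1e-9
  c(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

# 10-plex codebook on the demonstration panel
demo_codebook <- function(n_targets = 10) {
  build_codebook(demo_panel(), paste0("gene", seq_len(n_targets)))
}

# small, quick simulation config; overrides via ...
small_config <- function(codebook = demo_codebook(), seed = 1L, ...) {
  args <- list(
    codebook = codebook,
    volume_um = c(8, 8, 3), voxel_um = c(0.1, 0.1, 0.3),
    n_time_bins = 64L, counts_per_target = 2L, seed = seed
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# place transcripts on a well-separated grid (for recall tests): overwrites
# the uniform positions with jittered grid positions at least `min_sep_um`
# apart in x-y
grid_truth <- function(config, n, min_sep_um = 2) {
  per_side <- ceiling(sqrt(n))
  pitch <- (config$volume_um[1] - 2) / per_side
  stopifnot(pitch >= min_sep_um)
  g <- expand.grid(ix = seq_len(per_side), iy = seq_len(per_side))[seq_len(n), ]
  targets <- config$codebook$codewords$target
  tibble::tibble(
    x_um = 1 + (g$ix - 0.5) * pitch,
    y_um = 1 + (g$iy - 0.5) * pitch,
    z_um = config$volume_um[3] / 2,
    target = rep_len(targets, n),
    intensity = 1
  )
}

# brute-force 3D median filter with reflect padding (oracle)
median_filter_oracle <- function(x, window) {
  d <- dim(x)
  w <- (window - 1) / 2
  reflect <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i + 0, i)   # -0 -> 1, symmetric about 0.5
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    zi <- reflect(i + (-w[1]:w[1]), d[1])
    yi <- reflect(j + (-w[2]:w[2]), d[2])
    xi <- reflect(k + (-w[3]:w[3]), d[3])
    out[i, j, k] <- median(x[zi, yi, xi])
  }
  out
}

# deterministic (noiseless) Gaussian blob on a 3D grid, peak value `peak`
gaussian_blob <- function(dim, center, sigma_vox, peak = 100) {
  idx <- arrayInd(seq_len(prod(dim)), dim)
  v <- peak * exp(
    -((idx[, 1] - center[1])^2 / (2 * sigma_vox[1]^2) +
      (idx[, 2] - center[2])^2 / (2 * sigma_vox[2]^2) +
      (idx[, 3] - center[3])^2 / (2 * sigma_vox[3]^2))
  )
  array(v, dim)
}

# sample from a 2D Gaussian via Cholesky (independent of mclust/mvtnorm)
rmvn2 <- function(n, mu, sigma) {
  z <- matrix(rnorm(2 * n), ncol = 2)
  sweep(z %*% chol(sigma), 2, mu, "+")
}

# the three printed lifetime phasor clusters of the minimal 3-target
# experiment: means and covariances in (G, S) order
printed_clusters <- function() {
  list(
    mu = list(c(0.40, 0.26), c(0.49, 0.25), c(0.57, 0.23)),
    sigma = list(
      matrix(c(89, -5, -5, 12) * 1e-5, 2),
      matrix(c(51, -8, -8, 6) * 1e-5, 2),
      matrix(c(50, -8, -8, 12) * 1e-5, 2)
    )
  )
}
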