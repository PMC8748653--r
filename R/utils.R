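# internal helpers shared across modules

# round a window size up to the nearest odd integer >= 1
odd_window <- function(w) {
  w <- pmax(1L, as.integer(round(w)))
  w + 1L - (w %% 2L)
}

# shift a 3D array by (dz, dy, dx), padding the vacated voxels with `fill`
shift3 <- function(x, dz, dy, dx, fill = -Inf) {
  d <- dim(x)
  out <- array(fill, d)
  src_z <- seq_len(d[1]) - dz; src_y <- seq_len(d[2]) - dy; src_x <- seq_len(d[3]) - dx
  ok_z <- src_z >= 1 & src_z <= d[1]
  ok_y <- src_y >= 1 & src_y <= d[2]
  ok_x <- src_x >= 1 & src_x <= d[3]
  out[ok_z, ok_y, ok_x] <- x[src_z[ok_z], src_y[ok_y], src_x[ok_x]]
  out
}

# offsets of the 26-neighbourhood
neighbour_offsets <- function() {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
}

# separable Gaussian smoothing of a 3D array with reflect padding;
# sigma is in voxels, one value per axis (z, y, x)
gaussian_smooth3 <- function(x, sigma) {
  stopifnot(length(sigma) == 3L, all(sigma >= 0))
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    x <- convolve_axis3(x, k, ax)
  }
  x
}

# 1D convolution along one axis of a 3D array, reflect padding
convolve_axis3 <- function(x, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  d <- dim(x)
  n <- d[axis]
  idx <- function(i) {
    # reflect into [1, n]
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    pmin(pmax(i, 1L), n)
  }
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    src <- idx(seq_len(n) + off)
    out <- out + kernel[t] * switch(axis,
      x[src, , , drop = FALSE],
      x[, src, , drop = FALSE],
      x[, , src, drop = FALSE]
    )
  }
  out
}

# log-density of a multivariate normal via Cholesky (small d, many points)
log_dmvnorm <- function(x, mean, sigma) {
  x <- as.matrix(x)
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
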