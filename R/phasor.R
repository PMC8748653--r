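#' Construct a time-resolved multichannel photon stack
#'
#' A photon stack holds the raw data of a spectral/FLIM acquisition: per-voxel
#' photon counts indexed by z-slice, row, column, spectral channel and
#' photon-arrival-time bin, together with the physical voxel size, the laser
#' repetition frequency and the wavelength edges of the spectral channels.
#'
#' @param counts 5-D array of non-negative counts with dimensions
#'   `(z, y, x, channel, time_bin)`.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param rep_frequency_hz laser repetition frequency in Hz. The stimulation
#'   period is `1 / rep_frequency_hz`; all photon arrival times live inside it.
#' @param channel_edges_nm wavelength bin edges in nanometres, strictly
#'   increasing, of length `n_channels + 1`.
#'
#' @return An object of class `photon_stack`.
#' @export
photon_stack <- function(counts, voxel_um, rep_frequency_hz, channel_edges_nm) {
  stopifnot(length(dim(counts)) == 5L)
  if (any(counts < 0)) stop("photon counts must be non-negative")
  stopifnot(length(voxel_um) == 3L, all(voxel_um > 0))
  stopifnot(length(rep_frequency_hz) == 1L, rep_frequency_hz > 0)
  if (length(channel_edges_nm) != dim(counts)[4] + 1L ||
      any(diff(channel_edges_nm) <= 0)) {
    stop("channel_edges_nm must be strictly increasing with length n_channels + 1")
  }
  structure(
    list(
      counts = counts,
      voxel_um = as.numeric(voxel_um),
      rep_frequency_hz = rep_frequency_hz,
      channel_edges_nm = as.numeric(channel_edges_nm)
    ),
    class = "photon_stack"
  )
}

#' @export
print.photon_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<photon_stack> %d x %d x %d voxels (z,y,x), %d channels, %d time bins\n",
    d[1], d[2], d[3], d[4], d[5]
  ))
  cat(sprintf(
    "  voxel %.3g x %.3g x %.3g um, repetition %.3g MHz, %.0f photons total\n",
    x$voxel_um[1], x$voxel_um[2], x$voxel_um[3],
    x$rep_frequency_hz / 1e6, sum(x$counts)
  ))
  invisible(x)
}

#' Lifetime phasor of a photon arrival-time histogram
#'
#' Projects a histogram of photon arrival times onto the first (or a higher)
#' harmonic of the Fourier series over the stimulation period: the cosine
#' projection is G and the sine projection is S. The transform depends only on
#' the shape of the decay, not on the number of photons. Bin k is represented
#' by its centre time `t_k = (k - 1/2) * period / n_bins`.
#'
#' @param counts photon counts per time bin.
#' @param period_ns stimulation period in nanoseconds (1 / repetition rate).
#' @param harmonic positive integer harmonic, default 1.
#'
#' @return Named numeric vector `c(g, s)`; `c(NA, NA)` for an empty histogram.
#' @export
#'
#' @examples
#' # a single-exponential 1 ns decay at 78 MHz lands on the universal semicircle
#' p <- 1 / 78e6 * 1e9
#' tk <- (seq_len(256) - 0.5) * p / 256
#' lifetime_phasor(exp(-tk / 1), p)
lifetime_phasor <- function(counts, period_ns, harmonic = 1L) {
  stopifnot(period_ns > 0, harmonic >= 1)
  total <- sum(counts)
  if (total <= 0) return(c(g = NA_real_, s = NA_real_))
  b <- length(counts)
  tk <- (seq_len(b) - 0.5) * period_ns / b
  ang <- 2 * pi * harmonic * tk / period_ns
  c(
    g = sum(counts * cos(ang)) / total,
    s = sum(counts * sin(ang)) / total
  )
}

#' Spectral phasor of a channel histogram
#'
#' Maps a per-channel photon histogram onto the unit circle: channel c of C
#' maps to angle `2 * pi * harmonic * (c - 1/2) / C` and the phasor is the
#' photon-weighted mean of the channel points. A single-channel emitter lies
#' on the unit circle; mixtures fall on chords inside it.
#'
#' @param counts photon counts per spectral channel.
#' @inheritParams lifetime_phasor
#'
#' @return Named numeric vector `c(g, s)`; `c(NA, NA)` for an empty histogram.
#' @export
spectral_phasor <- function(counts, harmonic = 1L) {
  stopifnot(harmonic >= 1)
  total <- sum(counts)
  if (total <= 0) return(c(g = NA_real_, s = NA_real_))
  ang <- spectral_angles(length(counts), harmonic)
  c(
    g = sum(counts * cos(ang)) / total,
    s = sum(counts * sin(ang)) / total
  )
}

spectral_angles <- function(n_channels, harmonic = 1L) {
  2 * pi * harmonic * (seq_len(n_channels) - 0.5) / n_channels
}

#' Phasor position of a single-exponential decay
#'
#' Closed form for where a pure fluorophore of lifetime tau lies on the
#' lifetime phasor plot: `G = 1 / (1 + (w * tau)^2)`,
#' `S = w * tau / (1 + (w * tau)^2)` with `w = 2 * pi * harmonic * rep_frequency`.
#' All single-exponential species lie on the universal semicircle of radius
#' 1/2 centred at (1/2, 0).
#'
#' @param tau_ns fluorescence lifetime in nanoseconds (vectorised).
#' @param rep_frequency_hz laser repetition frequency in Hz.
#' @param harmonic positive integer harmonic, default 1.
#'
#' @return A tibble with columns `g` and `s`, one row per lifetime.
#' @export
#'
#' @examples
#' lifetime_phasor_position(c(1, 3.5), 78e6)
lifetime_phasor_position <- function(tau_ns, rep_frequency_hz = 78e6, harmonic = 1L) {
  if (any(tau_ns < 0)) stop("tau_ns must be non-negative")
  stopifnot(rep_frequency_hz > 0, harmonic >= 1)
  wt <- 2 * pi * harmonic * rep_frequency_hz * tau_ns * 1e-9
  tibble::tibble(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phase lifetime from phasor coordinates
#'
#' Projects a phasor point back to a lifetime via its phase angle,
#' `tau = (s / g) / w`; the inverse of [lifetime_phasor_position()] on the
#' universal semicircle. Used for pseudo-colouring lifetime images. Points
#' with `g <= 0` (phase beyond 90 degrees) have no finite phase lifetime and
#' return `Inf` as a long-lifetime sentinel.
#'
#' @param g,s phasor coordinates (vectorised).
#' @inheritParams lifetime_phasor_position
#'
#' @return Phase lifetime(s) in nanoseconds.
#' @export
phase_lifetime <- function(g, s, rep_frequency_hz = 78e6, harmonic = 1L) {
  w <- 2 * pi * harmonic * rep_frequency_hz
  ifelse(g <= 0, Inf, (s / g) / w * 1e9)
}

#' Phasor-transform a photon stack voxel by voxel
#'
#' Computes, for every voxel, the lifetime phasor of its time-marginal
#' histogram and the spectral phasor of its channel-marginal histogram.
#' Voxels with fewer than `min_photons` total photons are marked invalid and
#' carry `NA` phasors; they never reach downstream clustering.
#'
#' @param stack a [photon_stack()].
#' @param harmonic positive integer harmonic, default 1.
#' @param min_photons minimum photons for a voxel to carry a defined phasor.
#'
#' @return An object of class `phasor_field`: a list of 3-D arrays
#'   `spectral_g`, `spectral_s`, `lifetime_g`, `lifetime_s`, `intensity`,
#'   `valid`, plus the acquisition metadata.
#' @export
phasor_transform <- function(stack, harmonic = 1L, min_photons = 10L) {
  stopifnot(inherits(stack, "photon_stack"))
  d <- dim(stack$counts)
  nv <- prod(d[1:3]); nc <- d[4]; nt <- d[5]
  m <- stack$counts
  dim(m) <- c(nv, nc, nt)

  time_marg <- matrix(0, nv, nt)
  chan_marg <- matrix(0, nv, nc)
  for (ch in seq_len(nc)) {
    plane <- m[, ch, , drop = FALSE]
    dim(plane) <- c(nv, nt)
    time_marg <- time_marg + plane
    chan_marg[, ch] <- rowSums(plane)
  }
  intensity <- rowSums(chan_marg)

  period_ns <- 1e9 / stack$rep_frequency_hz
  tk <- (seq_len(nt) - 0.5) * period_ns / nt
  ang_t <- 2 * pi * harmonic * tk / period_ns
  ang_c <- spectral_angles(nc, harmonic)

  safe <- ifelse(intensity > 0, intensity, 1)
  lg <- as.vector(time_marg %*% cos(ang_t)) / safe
  ls <- as.vector(time_marg %*% sin(ang_t)) / safe
  sg <- as.vector(chan_marg %*% cos(ang_c)) / safe
  ss <- as.vector(chan_marg %*% sin(ang_c)) / safe

  valid <- intensity >= min_photons
  lg[!valid] <- NA_real_; ls[!valid] <- NA_real_
  sg[!valid] <- NA_real_; ss[!valid] <- NA_real_

  shape <- d[1:3]
  field <- list(
    spectral_g = array(sg, shape),
    spectral_s = array(ss, shape),
    lifetime_g = array(lg, shape),
    lifetime_s = array(ls, shape),
    intensity = array(intensity, shape),
    valid = array(valid, shape),
    voxel_um = stack$voxel_um,
    rep_frequency_hz = stack$rep_frequency_hz,
    n_channels = nc,
    harmonic = harmonic,
    min_photons = min_photons
  )
  class(field) <- "phasor_field"
  field
}

#' @export
print.phasor_field <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<phasor_field> %d x %d x %d voxels, %d (%.1f%%) valid\n",
    d[1], d[2], d[3], sum(x$valid), 100 * mean(x$valid)
  ))
  invisible(x)
}

#' Tidy a phasor field into a per-voxel tibble
#'
#' @param x a `phasor_field`.
#' @param valid_only drop invalid voxels (default `TRUE`).
#' @param ... unused.
#'
#' @return A tibble with voxel indices, physical coordinates, intensity and
#'   the four phasor coordinates.
#' @export
as_tibble.phasor_field <- function(x, valid_only = TRUE, ...) {
  field <- x
  d <- dim(field$intensity)
  idx <- arrayInd(seq_len(prod(d)), d)
  out <- tibble::tibble(
    z = idx[, 1], y = idx[, 2], x = idx[, 3],
    x_um = (idx[, 3] - 1) * field$voxel_um[1],
    y_um = (idx[, 2] - 1) * field$voxel_um[2],
    z_um = (idx[, 1] - 1) * field$voxel_um[3],
    intensity = as.vector(field$intensity),
    spectral_g = as.vector(field$spectral_g),
    spectral_s = as.vector(field$spectral_s),
    lifetime_g = as.vector(field$lifetime_g),
    lifetime_s = as.vector(field$lifetime_s),
    valid = as.vector(field$valid)
  )
  if (valid_only) out <- dplyr::filter(out, .data$valid)
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
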