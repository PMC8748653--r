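#' Configuration of a synthetic spectral/FLIM experiment
#'
#' Defines the virtual sample and instrument used by the synthetic-data
#' generator. The defaults reproduce the simulated study conditions:
#' diffraction-limited transcripts rendered as 3-D Gaussians with an x-y
#' standard deviation of 200 nm and a z standard deviation of 500 nm, a peak
#' intensity of 1 +/- 0.3 (truncated at 0.1), a 100 x 100 x 300 nm voxel grid
#' of 1000 x 1000 pixels and 33 slices, and a 78 MHz pulsed excitation.
#' The photon budget and the background level are generator choices (no
#' canonical values exist): by default the brightest voxel of a unit-intensity
#' transcript collects 300 expected photons and the background contributes
#' 0.1 photons per voxel, spread uniformly over channels and time bins.
#'
#' @param codebook a [build_codebook()] result naming targets and dye pairs.
#' @param volume_um physical extents `(Lx, Ly, Lz)` in micrometres.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param psf_sigma_um Gaussian profile sd `(sigma_xy, sigma_z)`.
#' @param peak_intensity_mean,peak_intensity_sd normal distribution of the
#'   per-transcript peak intensity (arbitrary units), truncated at 0.1.
#' @param photons_per_unit_intensity expected photons in the peak voxel of a
#'   unit-intensity transcript.
#' @param background_rate expected background photons per voxel.
#' @param rep_frequency_hz laser repetition frequency in Hz.
#' @param n_time_bins photon arrival-time bins per period.
#' @param channel_edges_nm detector bin edges; default spans 550-750 nm with
#'   one bin per panel channel.
#' @param counts_per_target transcripts placed per codeword.
#' @param seed RNG seed used by [simulate_experiment()].
#'
#' @return A list of class `sim_config` with the derived grid dimensions in
#'   `grid_dim` (z, y, x).
#' @export
simulation_config <- function(codebook,
                              volume_um = c(100, 100, 9.9),
                              voxel_um = c(0.1, 0.1, 0.3),
                              psf_sigma_um = c(0.2, 0.5),
                              peak_intensity_mean = 1,
                              peak_intensity_sd = 0.3,
                              photons_per_unit_intensity = 300,
                              background_rate = 0.1,
                              rep_frequency_hz = 78e6,
                              n_time_bins = 256L,
                              channel_edges_nm = NULL,
                              counts_per_target = 1L,
                              seed = 1L) {
  stopifnot(
    inherits(codebook, "flim_codebook"),
    length(volume_um) == 3L, all(volume_um > 0),
    length(voxel_um) == 3L, all(voxel_um > 0),
    length(psf_sigma_um) == 2L, all(psf_sigma_um > 0),
    peak_intensity_sd >= 0, photons_per_unit_intensity > 0,
    background_rate >= 0, rep_frequency_hz > 0,
    n_time_bins >= 2, counts_per_target >= 0
  )
  nchan <- attr(codebook$panel, "n_channels")
  if (is.null(channel_edges_nm)) {
    channel_edges_nm <- seq(550, 750, length.out = nchan + 1L)
  }
  stopifnot(length(channel_edges_nm) == nchan + 1L)
  structure(
    list(
      codebook = codebook,
      volume_um = volume_um,
      voxel_um = voxel_um,
      grid_dim = c(
        max(1L, round(volume_um[3] / voxel_um[3])),
        max(1L, round(volume_um[2] / voxel_um[2])),
        max(1L, round(volume_um[1] / voxel_um[1]))
      ),
      psf_sigma_um = psf_sigma_um,
      peak_intensity_mean = peak_intensity_mean,
      peak_intensity_sd = peak_intensity_sd,
      photons_per_unit_intensity = photons_per_unit_intensity,
      background_rate = background_rate,
      rep_frequency_hz = rep_frequency_hz,
      n_time_bins = as.integer(n_time_bins),
      channel_edges_nm = as.numeric(channel_edges_nm),
      counts_per_target = as.integer(counts_per_target),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Place ground-truth transcripts uniformly in the volume
#'
#' Draws `counts_per_target` transcripts per codeword at continuous
#' uniform-random positions (no exclusion, so crowding arises naturally at
#' high density) with peak intensities from a truncated normal. Uses the
#' current RNG state; [simulate_experiment()] seeds it from the config.
#'
#' @param config a [simulation_config()].
#'
#' @return A tibble (`x_um`, `y_um`, `z_um`, `target`, `intensity`).
#' @export
place_transcripts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  targets <- config$codebook$codewords$target
  n <- config$counts_per_target * length(targets)
  if (n == 0) {
    return(tibble::tibble(
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      target = character(), intensity = numeric()
    ))
  }
  intensity <- rnorm(n, config$peak_intensity_mean, config$peak_intensity_sd)
  while (any(bad <- intensity < 0.1)) {
    intensity[bad] <- rnorm(sum(bad), config$peak_intensity_mean,
                            config$peak_intensity_sd)
  }
  tibble::tibble(
    x_um = runif(n, 0, config$volume_um[1]),
    y_um = runif(n, 0, config$volume_um[2]),
    z_um = runif(n, 0, config$volume_um[3]),
    target = rep(targets, each = config$counts_per_target),
    intensity = intensity
  )
}

# probability of each spectral channel for a Gaussian emission profile,
# truncated to the detector range and renormalised
channel_probs <- function(center, sigma, edges) {
  p <- diff(pnorm(edges, center, sigma))
  if (sum(p) <= 0) stop("emission profile falls outside the detector range")
  p / sum(p)
}

# probability of each arrival-time bin for a periodic single-exponential
# decay of lifetime tau (ns) wrapped into the period (ns)
time_bin_probs <- function(tau_ns, period_ns, n_bins) {
  edges <- seq(0, period_ns, length.out = n_bins + 1L)
  cdf <- (1 - exp(-edges / tau_ns)) / (1 - exp(-period_ns / tau_ns))
  diff(cdf)
}

#' Render a photon stack from ground-truth transcripts
#'
#' Each transcript contributes a 3-D Gaussian photon-rate profile (integrated
#' over voxels, truncated at 4 sigma) whose peak-voxel expectation is
#' `intensity * photons_per_unit_intensity`. Photons split equally between
#' the codeword's dyes; each dye draws spectral channels from its Gaussian
#' emission profile integrated over the channel edges and arrival-time bins
#' from its periodic exponential decay. Per-voxel counts are Poisson; the
#' background adds Poisson photons uniform over space, channel and time.
#'
#' @param truth a [place_transcripts()] tibble.
#' @param config a [simulation_config()].
#'
#' @return A [photon_stack()].
#' @export
render_photon_stack <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  gd <- config$grid_dim # (nz, ny, nx)
  nz <- gd[1]; ny <- gd[2]; nx <- gd[3]
  nv <- prod(gd)
  nchan <- attr(config$codebook$panel, "n_channels")
  nt <- config$n_time_bins
  panel <- config$codebook$panel
  period_ns <- 1e9 / config$rep_frequency_hz
  vx <- config$voxel_um

  # expected photons per voxel, per panel fluorophore
  rate <- lapply(seq_len(nrow(panel)), function(i) array(0, gd))
  names(rate) <- panel$name
  sig <- c(config$psf_sigma_um[2], config$psf_sigma_um[1], config$psf_sigma_um[1])
  vxzyx <- c(vx[3], vx[2], vx[1])

  if (nrow(truth) > 0) {
    # voxel-integrated Gaussian along each axis, normalised to peak 1
    axis_profile <- function(mu, sigma, dx, n) {
      lo <- max(1L, floor((mu - 4 * sigma) / dx) + 1L)
      hi <- min(n, ceiling((mu + 4 * sigma) / dx) + 1L)
      if (lo > hi) return(NULL)
      centers <- (lo:hi - 1) * dx
      p <- pnorm(centers + dx / 2, mu, sigma) - pnorm(centers - dx / 2, mu, sigma)
      peak <- pnorm(dx / 2, 0, sigma) - pnorm(-dx / 2, 0, sigma)
      list(idx = lo:hi, w = p / peak)
    }
    for (r in seq_len(nrow(truth))) {
      fl <- codeword_fluors(config$codebook, truth$target[r])
      mu <- c(truth$z_um[r], truth$y_um[r], truth$x_um[r])
      pz <- axis_profile(mu[1], sig[1], vxzyx[1], nz)
      py <- axis_profile(mu[2], sig[2], vxzyx[2], ny)
      px <- axis_profile(mu[3], sig[3], vxzyx[3], nx)
      if (is.null(pz) || is.null(py) || is.null(px)) next
      prof <- outer(outer(pz$w, py$w), px$w)
      amp <- truth$intensity[r] * config$photons_per_unit_intensity / length(fl)
      for (f in fl) {
        rate[[f]][pz$idx, py$idx, px$idx] <-
          rate[[f]][pz$idx, py$idx, px$idx] + amp * prof
      }
    }
  }

  counts <- integer(nv * nchan * nt)
  for (i in seq_len(nrow(panel))) {
    lam <- rate[[i]]
    hot <- which(lam > 0)
    if (length(hot) == 0) next
    nph <- rpois(length(hot), lam[hot])
    keep <- nph > 0
    if (!any(keep)) next
    vox <- rep(hot[keep], nph[keep])
    np <- length(vox)
    ch <- sample.int(nchan, np, replace = TRUE,
                     prob = channel_probs(panel$emission_center_nm[i],
                                          panel$emission_sigma_nm[i],
                                          config$channel_edges_nm))
    tb <- sample.int(nt, np, replace = TRUE,
                     prob = time_bin_probs(panel$lifetime_ns[i], period_ns, nt))
    lin <- vox + nv * (ch - 1) + nv * nchan * (tb - 1)
    acc <- tabulate(lin, nbins = nv * nchan * nt)
    counts <- counts + acc
  }

  if (config$background_rate > 0) {
    nbg <- rpois(1, config$background_rate * nv)
    if (nbg > 0) {
      lin <- sample.int(nv, nbg, replace = TRUE) +
        nv * (sample.int(nchan, nbg, replace = TRUE) - 1) +
        nv * nchan * (sample.int(nt, nbg, replace = TRUE) - 1)
      counts <- counts + tabulate(lin, nbins = nv * nchan * nt)
    }
  }

  dim(counts) <- c(gd, nchan, nt)
  photon_stack(counts, vx, config$rep_frequency_hz, config$channel_edges_nm)
}

#' Simulate a full experiment with ground truth
#'
#' Seeds the RNG from `config$seed`, places transcripts and renders the
#' photon stack; bit-identical for identical configs.
#'
#' @param config a [simulation_config()].
#' @param truth_csv optional path; when given, the ground truth is written
#'   there as CSV.
#'
#' @return A list with elements `stack` (a [photon_stack()]) and `truth`
#'   (the ground-truth tibble).
#' @export
simulate_experiment <- function(config, truth_csv = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- place_transcripts(config)
  stack <- render_photon_stack(truth, config)
  if (!is.null(truth_csv)) utils::write.csv(truth, truth_csv, row.names = FALSE)
  list(stack = stack, truth = truth)
}

#' Simulate a nuclear-stain volume
#'
#' Places `n_cells` non-overlapping ellipsoidal nuclei of high mean photon
#' count on a dim Poisson background; a fixture generator for nucleus
#' segmentation and territory growth.
#'
#' @param n_cells number of nuclei.
#' @param grid_dim stack dimensions `(nz, ny, nx)`.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param radius_um ellipsoid semi-axes `(rx, ry, rz)`.
#' @param nucleus_rate,background_rate mean photons per voxel inside/outside.
#' @param max_tries placement retries before giving up.
#'
#' @return A list: `stack` (3-D count array), `centers` (tibble of true
#'   centres in voxel and physical coordinates).
#' @export
simulate_nuclei <- function(n_cells, grid_dim = c(16L, 64L, 64L),
                            voxel_um = c(0.1, 0.1, 0.3),
                            radius_um = c(1.5, 1.5, 1.0),
                            nucleus_rate = 50, background_rate = 0.5,
                            max_tries = 500L) {
  stopifnot(n_cells >= 0, length(grid_dim) == 3L)
  nz <- grid_dim[1]; ny <- grid_dim[2]; nx <- grid_dim[3]
  rz <- radius_um[3] / voxel_um[3]
  ry <- radius_um[2] / voxel_um[2]
  rx <- radius_um[1] / voxel_um[1]
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(centers) < n_cells) {
    cand <- c(runif(1, 1 + rz, nz - rz), runif(1, 1 + ry, ny - ry),
              runif(1, 1 + rx, nx - rx))
    # 2.2x the semi-axes: disjoint with at least a voxel-scale gap so that
    # neighbouring nuclei stay resolvable by connected components
    ok <- nrow(centers) == 0 || all(
      ((centers[, 1] - cand[1]) / (2.2 * rz))^2 +
      ((centers[, 2] - cand[2]) / (2.2 * ry))^2 +
      ((centers[, 3] - cand[3]) / (2.2 * rx))^2 > 1
    )
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_cells, " non-overlapping nuclei")
    }
  }
  lam <- array(background_rate, grid_dim)
  if (n_cells > 0) {
    idx <- arrayInd(seq_len(prod(grid_dim)), grid_dim)
    for (i in seq_len(n_cells)) {
      inside <- ((idx[, 1] - centers[i, 1]) / rz)^2 +
        ((idx[, 2] - centers[i, 2]) / ry)^2 +
        ((idx[, 3] - centers[i, 3]) / rx)^2 <= 1
      lam[inside] <- nucleus_rate
    }
  }
  stack <- array(rpois(length(lam), lam), grid_dim)
  list(
    stack = stack,
    centers = tibble::tibble(
      cell = seq_len(n_cells),
      z = centers[, 1], y = centers[, 2], x = centers[, 3]
    )
  )
}
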