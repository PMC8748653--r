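#' Estimate the smooth background of an intensity stack
#'
#' Voxelwise median over a window ten times the expected punctum size
#' (converted to voxels per axis and rounded up to odd), with reflect padding
#' at the edges. Diffraction-limited puncta are far smaller than the window,
#' so they do not bias the median; slowly varying background (out-of-focus
#' light, autofluorescence haze) is tracked.
#'
#' @param intensity 3-D array `(z, y, x)` of photon counts.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param puncta_size_um expected punctum size (the instrument's diffraction
#'   limit), default 0.25 um.
#'
#' @return A 3-D background array of the same shape.
#' @export
estimate_background <- function(intensity, voxel_um, puncta_size_um = 0.25) {
  stopifnot(length(dim(intensity)) == 3L, puncta_size_um > 0)
  d <- dim(intensity)
  # axes of the array are (z, y, x); voxel_um is (dx, dy, dz)
  win <- odd_window(10 * puncta_size_um / c(voxel_um[3], voxel_um[2], voxel_um[1]))
  if (any(win > d)) {
    warning("median window exceeds stack extent; using the global median")
    return(array(median(intensity), d))
  }
  median_filter3_cpp(as.numeric(intensity), as.integer(d), as.integer(win))
}

#' Matched-filter prominence map
#'
#' Gaussian smoothing (sigma per axis = punctum size in voxels, anisotropy
#' respected) of the background-subtracted stack. The value at each voxel is
#' its prominence over the surrounding region; negatives are clipped to zero.
#'
#' @inheritParams estimate_background
#' @param background matching background array from [estimate_background()].
#'
#' @return A filtered 3-D array of the same shape.
#' @export
prominence_map <- function(intensity, background, voxel_um,
                           puncta_size_um = 0.25) {
  stopifnot(all(dim(intensity) == dim(background)))
  sigma <- puncta_size_um / c(voxel_um[3], voxel_um[2], voxel_um[1])
  out <- gaussian_smooth3(intensity - background, sigma)
  out[out < 0] <- 0
  out
}

#' Find local maxima of a filtered stack
#'
#' Maxima of the 26-neighbourhood — the discrete fixed points of a vanishing
#' gradient with negative divergence — with filtered value at least
#' `min_prominence`. Plateaus of equal-valued neighbouring maxima are reduced
#' to a single voxel at the plateau centroid.
#'
#' @param filtered 3-D array from [prominence_map()].
#' @param min_prominence minimum filtered value for a peak to be kept; the
#'   default is five times the robust noise scale of the filtered stack
#'   ([default_min_prominence()]).
#'
#' @return An integer matrix with columns `z`, `y`, `x` (possibly 0 rows).
#' @export
find_local_maxima <- function(filtered,
                              min_prominence = default_min_prominence(filtered)) {
  stopifnot(length(dim(filtered)) == 3L, min_prominence >= 0)
  cand <- filtered > 0 & filtered >= min_prominence
  if (!any(cand)) return(empty_maxima())
  offs <- neighbour_offsets()
  for (i in seq_len(nrow(offs))) {
    nb <- shift3(filtered, offs$dz[i], offs$dy[i], offs$dx[i], fill = -Inf)
    cand <- cand & filtered >= nb
    if (!any(cand)) return(empty_maxima())
  }
  # adjacent candidates are necessarily equal-valued plateaus: label and
  # reduce each plateau to its centroid voxel
  lab <- label_components3_cpp(cand, dim(filtered), 26L)
  idx <- which(lab > 0)
  comp <- lab[idx]
  pos <- arrayInd(idx, dim(filtered))
  out <- t(vapply(split(seq_along(comp), comp), function(rows) {
    if (length(rows) == 1L) return(pos[rows, ])
    ctr <- colMeans(pos[rows, , drop = FALSE])
    # snap to the member voxel nearest the centroid
    d2 <- colSums((t(pos[rows, , drop = FALSE]) - ctr)^2)
    pos[rows[which.min(d2)], ]
  }, integer(3)))
  colnames(out) <- c("z", "y", "x")
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

empty_maxima <- function() {
  matrix(integer(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x")))
}

#' Default prominence threshold
#'
#' Five times the robust noise scale of the filtered stack. Because the
#' filtered map is clipped at zero, the plain MAD underestimates the noise
#' (more than half the voxels can be exactly zero); instead the scale is
#' estimated from the median of the strictly positive values, which for
#' symmetric zero-mean noise is the half-normal median `0.6745 * sigma`.
#'
#' @param filtered 3-D array from [prominence_map()].
#' @return A scalar threshold.
#' @export
default_min_prominence <- function(filtered) {
  pos <- filtered[filtered > 0]
  if (length(pos) == 0) return(.Machine$double.eps)
  sigma <- median(pos) / stats::qnorm(0.75)
  5 * max(sigma, .Machine$double.eps)
}

# voxel offsets of an axis-aligned ellipsoid of semi-axes r (voxels)
ellipsoid_offsets <- function(r) {
  rr <- pmax(1, r)
  g <- expand.grid(
    dz = -ceiling(rr[1]):ceiling(rr[1]),
    dy = -ceiling(rr[2]):ceiling(rr[2]),
    dx = -ceiling(rr[3]):ceiling(rr[3])
  )
  keep <- (g$dz / rr[1])^2 + (g$dy / rr[2])^2 + (g$dx / rr[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Measure detected puncta
#'
#' For each local maximum: `brightness` is the background-subtracted photon
#' sum over a 2-sigma ellipsoid, `size` the number of ellipsoid voxels whose
#' filtered value exceeds half the peak's, `prominence` the filtered peak
#' value, and `channel_presence` the set of spectral channels whose local
#' Poisson signal-to-noise over the 1-sigma core is at least
#' `channel_snr_threshold`. Puncta whose ellipsoid is clipped by the stack
#' boundary are retained and flagged `edge`.
#'
#' A bright punctum can reach an absolute SNR of 3 in a neighbouring channel
#' through spectral cross-talk alone, so presence additionally requires the
#' channel to hold at least `channel_fraction_threshold` of the punctum's
#' background-subtracted photons.
#'
#' @param maxima matrix from [find_local_maxima()].
#' @param channel_stacks 4-D array `(z, y, x, channel)` of per-channel counts
#'   (the time-marginal of a photon stack).
#' @param background background array from [estimate_background()].
#' @param filtered filtered array from [prominence_map()].
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param puncta_size_um expected punctum size in micrometres.
#' @param channel_snr_threshold minimum per-channel SNR, default 3.
#' @param channel_fraction_threshold minimum share of the punctum's photons a
#'   channel must carry to count as present, default 0.05.
#'
#' @return A tibble with one row per punctum: voxel and physical coordinates,
#'   `size`, `brightness`, `prominence`, `channels` (list column), `edge`.
#' @export
measure_puncta <- function(maxima, channel_stacks, background, filtered,
                           voxel_um, puncta_size_um = 0.25,
                           channel_snr_threshold = 3,
                           channel_fraction_threshold = 0.05) {
  d <- dim(filtered)
  stopifnot(all(dim(channel_stacks)[1:3] == d), all(dim(background) == d))
  nchan <- dim(channel_stacks)[4]
  sigma <- puncta_size_um / c(voxel_um[3], voxel_um[2], voxel_um[1])
  off2 <- ellipsoid_offsets(2 * sigma)
  off1 <- ellipsoid_offsets(1 * sigma)
  intensity <- rowSums(matrix(channel_stacks, prod(d), nchan))
  dim(intensity) <- d

  one <- function(i) {
    ctr <- maxima[i, ]
    vox2 <- sweep(off2, 2, ctr, "+")
    inb <- vox2[, 1] >= 1 & vox2[, 1] <= d[1] &
      vox2[, 2] >= 1 & vox2[, 2] <= d[2] &
      vox2[, 3] >= 1 & vox2[, 3] <= d[3]
    edge <- any(!inb)
    vox2 <- vox2[inb, , drop = FALSE]
    lin2 <- vox2[, 1] + d[1] * (vox2[, 2] - 1) + d[1] * d[2] * (vox2[, 3] - 1)
    peak_prom <- filtered[ctr[1], ctr[2], ctr[3]]

    vox1 <- sweep(off1, 2, ctr, "+")
    inb1 <- vox1[, 1] >= 1 & vox1[, 1] <= d[1] &
      vox1[, 2] >= 1 & vox1[, 2] <= d[2] &
      vox1[, 3] >= 1 & vox1[, 3] <= d[3]
    vox1 <- vox1[inb1, , drop = FALSE]
    lin1 <- vox1[, 1] + d[1] * (vox1[, 2] - 1) + d[1] * d[2] * (vox1[, 3] - 1)

    # per-channel SNR: core photon excess over the local background estimate,
    # scaled by the Poisson noise of that background
    bg_ch <- sum(background[lin1]) / nchan
    excess <- vapply(seq_len(nchan), function(ch) {
      sum(channel_stacks[lin1 + prod(d) * (ch - 1)]) - bg_ch
    }, numeric(1))
    snr <- excess / sqrt(max(bg_ch, 1))
    total_excess <- sum(pmax(excess, 0))
    chans <- which(snr >= channel_snr_threshold &
                     excess >= channel_fraction_threshold * total_excess)

    tibble::tibble(
      id = i,
      z = unname(ctr[1]), y = unname(ctr[2]), x = unname(ctr[3]),
      x_um = unname((ctr[3] - 1) * voxel_um[1]),
      y_um = unname((ctr[2] - 1) * voxel_um[2]),
      z_um = unname((ctr[1] - 1) * voxel_um[3]),
      size = sum(filtered[lin2] >= peak_prom / 2),
      brightness = sum(intensity[lin2] - background[lin2]),
      prominence = peak_prom,
      channels = list(chans),
      edge = edge
    )
  }
  if (nrow(maxima) == 0) {
    return(tibble::tibble(
      id = integer(), z = integer(), y = integer(), x = integer(),
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      size = integer(), brightness = numeric(), prominence = numeric(),
      channels = list(), edge = logical()
    ))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(maxima)), one))
}

#' Detect puncta in a photon stack
#'
#' End-to-end 3-D blob detection: background estimation (voxelwise median),
#' matched filtering (Gaussian of the punctum size), strict 26-neighbourhood
#' local maxima, and per-punctum measurement. A convenience composition of
#' [estimate_background()], [prominence_map()], [find_local_maxima()] and
#' [measure_puncta()].
#'
#' @param stack a [photon_stack()].
#' @param puncta_size_um expected punctum size in micrometres.
#' @param min_prominence peak threshold; `NULL` for the robust default.
#' @param channel_snr_threshold minimum per-channel SNR, default 3.
#'
#' @return The [measure_puncta()] tibble.
#' @export
detect_puncta <- function(stack, puncta_size_um = 0.25, min_prominence = NULL,
                          channel_snr_threshold = 3) {
  stopifnot(inherits(stack, "photon_stack"))
  d <- dim(stack$counts)
  chan <- rowSums(array(stack$counts, c(prod(d[1:3]) * d[4], d[5])))
  dim(chan) <- d[1:4]
  intensity <- rowSums(matrix(chan, prod(d[1:3]), d[4]))
  dim(intensity) <- d[1:3]
  bg <- estimate_background(intensity, stack$voxel_um, puncta_size_um)
  filt <- prominence_map(intensity, bg, stack$voxel_um, puncta_size_um)
  mp <- if (is.null(min_prominence)) default_min_prominence(filt) else min_prominence
  mx <- find_local_maxima(filt, mp)
  measure_puncta(mx, chan, bg, filt, stack$voxel_um, puncta_size_um,
                 channel_snr_threshold)
}
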