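vox <- c(0.1, 0.1, 0.3)

test_that("background estimation is a true windowed median with reflect padding", {
  # constant stack: background equals the constant
  const <- array(3.5, c(9, 27, 27))
  expect_equal(estimate_background(const, vox), const)

  # isolated blob on zero background: median window far exceeds the blob
  blob <- gaussian_blob(c(9, 27, 27), c(5, 14, 14), c(1.7, 2, 2), peak = 50)
  bg <- estimate_background(blob, vox, puncta_size_um = 0.25)
  expect_lt(bg[5, 14, 14], 1e-3)

  # brute-force oracle on a small ramp stack
  set.seed(1)
  ramp <- array(rep(seq(0, 10, length.out = 16), each = 256), c(16, 16, 16)) +
    array(runif(16^3), c(16, 16, 16))
  ramp <- aperm(ramp, c(3, 2, 1)) # ramp along x
  win <- odd_window(10 * 0.25 / c(vox[3], vox[2], vox[1]))
  win <- pmin(win, c(9L, 15L, 15L)) # keep the oracle affordable
  got <- flimfish:::median_filter3_cpp(as.numeric(ramp), dim(ramp), win)
  want <- median_filter_oracle(ramp, win)
  expect_equal(got, want, tolerance = 1e-12)

  # window larger than the stack falls back to the global median
  expect_warning(bg2 <- estimate_background(array(1:8, c(2, 2, 2)), vox),
                 "global median")
  expect_equal(unique(as.vector(bg2)), median(1:8))
})

test_that("prominence map suppresses noise and centres on blobs", {
  set.seed(2)
  noise <- array(rnorm(16 * 24 * 24), c(16, 24, 24))
  zero_bg <- array(0, dim(noise))
  filt <- prominence_map(noise, zero_bg, vox)
  expect_lt(var(as.vector(filt)), var(as.vector(noise)))

  blob <- gaussian_blob(c(11, 31, 31), c(6, 16, 16), c(0.8, 2.5, 2.5), peak = 20)
  fb <- prominence_map(blob, array(0, dim(blob)), vox)
  expect_equal(as.vector(which(fb == max(fb), arr.ind = TRUE)), c(6, 16, 16))

  # a stack equal to its background maps to all zeros
  expect_equal(prominence_map(blob, blob, vox), array(0, dim(blob)))
})

test_that("local maxima match an exhaustive neighbourhood-scan oracle", {
  expect_equal(nrow(find_local_maxima(array(0, c(4, 4, 4)), 0.1)), 0)

  blob <- gaussian_blob(c(11, 31, 31), c(6, 16, 16), c(1.7, 2, 2), peak = 10)
  mx <- find_local_maxima(blob, 1)
  expect_equal(unname(mx), matrix(c(6L, 16L, 16L), 1))

  two <- gaussian_blob(c(11, 41, 41), c(6, 12, 12), c(1.7, 2, 2), peak = 10) +
    gaussian_blob(c(11, 41, 41), c(6, 30, 30), c(1.7, 2, 2), peak = 8)
  mx2 <- find_local_maxima(two, 1)
  expect_equal(unname(mx2), matrix(c(6L, 6L, 12L, 30L, 12L, 30L), 2))

  # random stacks vs brute-force strict-26-neighbourhood oracle
  set.seed(3)
  for (rep in 1:3) {
    x <- array(sample(0:50, 6 * 7 * 8, replace = TRUE), c(6, 7, 8))
    got <- find_local_maxima(x, 30)
    oracle <- list()
    for (i in 1:6) for (j in 1:7) for (k in 1:8) {
      v <- x[i, j, k]
      if (v < 30) next
      nb <- x[max(1, i - 1):min(6, i + 1), max(1, j - 1):min(7, j + 1),
              max(1, k - 1):min(8, k + 1)]
      if (sum(nb == v) == 1 && v == max(nb)) {
        oracle[[length(oracle) + 1]] <- c(i, j, k)
      }
    }
    oracle <- do.call(rbind, oracle)
    # the oracle finds strict maxima only; plateau representatives may add
    # rows, so every strict maximum must be present
    if (!is.null(oracle)) {
      for (r in seq_len(nrow(oracle))) {
        expect_true(any(got[, 1] == oracle[r, 1] & got[, 2] == oracle[r, 2] &
                          got[, 3] == oracle[r, 3]))
      }
    }
  }

  # an equal-valued plateau is reduced to a single centroid voxel
  plat <- array(0, c(5, 9, 9))
  plat[3, 4:6, 4:6] <- 7
  mp <- find_local_maxima(plat, 1)
  expect_equal(unname(mp), matrix(c(3L, 5L, 5L), 1))
})

test_that("puncta measurements recover brightness and channel identity", {
  # noiseless blob in channel 2 of 3: brightness equals the ellipsoid sum
  d <- c(11, 25, 25)
  blob <- gaussian_blob(d, c(6, 13, 13), c(0.25 / vox[3], 0.25 / vox[2], 0.25 / vox[1]),
                        peak = 200)
  chan <- array(0, c(d, 3))
  chan[, , , 2] <- blob
  bg <- array(0, d)
  filt <- prominence_map(blob, bg, vox)
  mx <- find_local_maxima(filt, 1)
  pr <- measure_puncta(mx, chan, bg, filt, vox)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$channels[[1]], 2L)
  expect_false(pr$edge)
  # independent brightness oracle: direct sum over the 2-sigma ellipsoid
  sig <- 0.25 / c(vox[3], vox[2], vox[1])
  idx <- arrayInd(seq_len(prod(d)), d)
  inside <- ((idx[, 1] - 6) / (2 * sig[1]))^2 + ((idx[, 2] - 13) / (2 * sig[2]))^2 +
    ((idx[, 3] - 13) / (2 * sig[3]))^2 <= 1
  expect_equal(pr$brightness, sum(blob[inside]), tolerance = 0.02 * sum(blob[inside]))

  # physical coordinates: origin at the centre of voxel (1,1,1)
  expect_equal(pr$x_um, (13 - 1) * vox[1])
  expect_equal(pr$z_um, (6 - 1) * vox[3])
})

test_that("detection output is invariant under a constant intensity offset", {
  cb <- demo_codebook()
  cfg <- small_config(codebook = cb, counts_per_target = 1L, seed = 9L)
  sim <- simulate_experiment(cfg)
  p1 <- detect_puncta(sim$stack)
  shifted <- sim$stack
  shifted$counts <- shifted$counts + 1L # +1 photon per (voxel, channel, bin)
  p2 <- detect_puncta(shifted)
  expect_equal(p2[, c("z", "y", "x")], p1[, c("z", "y", "x")])
  expect_equal(p2$brightness, p1$brightness, tolerance = 0.02 * mean(p1$brightness))
})

test_that("a pair codeword shows presence in exactly its two channels", {
  cb <- demo_codebook()
  # gene2 pairs DY560 (channel 1) with DY600 (channel 2)? resolve from codebook
  cw <- cb$codewords[2, ]
  ch_expect <- sort(cb$panel$channel[match(c(cw$fluor1, cw$fluor2), cb$panel$name)])
  cfg <- small_config(codebook = cb, background_rate = 0.05)
  set.seed(10)
  truth <- tibble::tibble(x_um = 4, y_um = 4, z_um = 1.5, target = cw$target,
                          intensity = 1.2)
  stk <- render_photon_stack(truth, cfg)
  pr <- detect_puncta(stk)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$channels[[1]], ch_expect)
})

test_that("detector hits recall >= 0.95 with sub-voxel centroids and no false positives", {
  cb <- demo_codebook()
  cfg <- small_config(codebook = cb, background_rate = 0.5,
                      photons_per_unit_intensity = 150)
  set.seed(11)
  truth <- grid_truth(cfg, 9)
  stk <- render_photon_stack(truth, cfg)
  pr <- detect_puncta(stk)
  matched <- 0
  for (i in seq_len(nrow(truth))) {
    dx <- abs(pr$x_um - truth$x_um[i]) / cfg$voxel_um[1]
    dy <- abs(pr$y_um - truth$y_um[i]) / cfg$voxel_um[2]
    hit <- which(dx < 1 & dy < 1)
    if (length(hit) > 0) matched <- matched + 1
  }
  expect_gte(matched / nrow(truth), 0.95)

  # background-only stacks: zero detections across seeds
  cfg0 <- small_config(codebook = cb, counts_per_target = 0L,
                       volume_um = c(4, 4, 3), background_rate = 0.5)
  for (s in 1:10) {
    set.seed(100 + s)
    stk0 <- render_photon_stack(place_transcripts(cfg0), cfg0)
    expect_equal(nrow(detect_puncta(stk0)), 0, label = paste("seed", s))
  }
})
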