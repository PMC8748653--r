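test_that("a one-component fit recovers the sample mean", {
  set.seed(1)
  x <- rmvn2(500, c(0.4, 0.3), diag(c(1e-4, 2e-4)))
  m <- fit_phasor_gmm(x, 1)
  expect_equal(as.vector(m$means), colMeans(x), tolerance = 1e-8)
  expect_equal(m$weights, 1)
})

test_that("EM recovers the printed three-cluster geometry within 0.005", {
  cl <- printed_clusters()
  set.seed(2)
  x <- do.call(rbind, lapply(1:3, function(i) rmvn2(10000, cl$mu[[i]], cl$sigma[[i]])))
  m <- fit_phasor_gmm(x, 3, seed = 1)
  # match recovered means to truth by nearest neighbour
  err <- vapply(cl$mu, function(mu) {
    min(sqrt(colSums((t(m$means) - mu)^2)))
  }, numeric(1))
  expect_true(all(err < 0.005))
  # distance between the leftmost and rightmost recovered clusters
  gs <- m$means[, 1]
  dist_lr <- sqrt(sum((m$means[which.min(gs), ] - m$means[which.max(gs), ])^2))
  # true generative distance is sqrt(0.03^2 + 0.17^2) = 0.1726, printed as 0.17
  expect_lt(abs(dist_lr - 0.1726), 0.005)
  expect_equal(round(dist_lr, 2), 0.17)
})

test_that("posteriors follow the Bayes rule", {
  cl <- printed_clusters()
  set.seed(3)
  x <- do.call(rbind, lapply(1:3, function(i) rmvn2(2000, cl$mu[[i]], cl$sigma[[i]])))
  m <- fit_phasor_gmm(x, 3, seed = 1)

  # a point exactly at a component mean of well-separated clusters
  p_at_mean <- posterior_phasor(m, m$means)
  expect_true(all(diag(p_at_mean) > 0.99))

  # symmetric two-cluster model: the midpoint splits 50/50
  sym <- structure(
    list(k = 2L, d = 2L,
         means = rbind(c(0.3, 0.4), c(0.5, 0.4)),
         covariances = array(rep(diag(1e-3, 2), 2), c(2, 2, 2)),
         weights = c(0.5, 0.5), loglik = NA_real_, n = 0L,
         dim_names = c("g", "s"), mapping = NULL),
    class = "phasor_gmm"
  )
  expect_equal(as.vector(posterior_phasor(sym, rbind(c(0.4, 0.4)))),
               c(0.5, 0.5), tolerance = 1e-12)

  # brute-force density oracle on 100 random points
  skip_if_not_installed("mvtnorm")
  set.seed(4)
  pts <- matrix(runif(200, 0.2, 0.6), ncol = 2)
  dens <- vapply(seq_len(m$k), function(j) {
    m$weights[j] * mvtnorm::dmvnorm(pts, m$means[j, ], m$covariances[, , j])
  }, numeric(100))
  expect_equal(posterior_phasor(m, pts), dens / rowSums(dens), tolerance = 1e-8)
})

test_that("empirical misassignment stays within the Bayes error bound", {
  # two overlapping clusters with known truth
  mu <- list(c(0.40, 0.40), c(0.46, 0.40))
  sg <- diag(4e-4, 2) # sd 0.02 per axis, 3 sigma gap -> some overlap
  set.seed(5)
  n <- 5000
  x <- rbind(rmvn2(n, mu[[1]], sg), rmvn2(n, mu[[2]], sg))
  truth <- rep(1:2, each = n)
  m <- fit_phasor_gmm(x, 2, seed = 1)
  # order components to match the truth
  ord <- order(m$means[, 1])
  cls <- assign_phasors(m, x)
  pred <- match(cls$component, ord)
  err_rate <- mean(pred != truth)
  # Bayes error of the true generative model (isotropic equal covariances:
  # the optimal rule is nearest mean)
  d1 <- exp(-rowSums(sweep(x, 2, mu[[1]])^2) / (2 * 4e-4))
  d2 <- exp(-rowSums(sweep(x, 2, mu[[2]])^2) / (2 * 4e-4))
  bayes_rate <- mean((truth == 1 & d2 > d1) | (truth == 2 & d1 > d2))
  expect_lte(err_rate, bayes_rate + 0.02)
})

test_that("component matching resolves label switching via optimal assignment", {
  cb <- demo_codebook(4)
  sig <- expected_signatures(cb, 78e6)
  dims <- c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")
  # scramble the signature order into a fake fitted model with 5 components
  perm <- c(3, 1, 4, 2)
  means <- rbind(as.matrix(sig[perm, dims]) + 0.002, c(0.1, 0.1, 0.4, 0.4))
  model <- structure(
    list(k = 5L, d = 4L, means = means,
         covariances = array(rep(diag(1e-4, 4), 5), c(4, 4, 5)),
         weights = rep(0.2, 5), loglik = NA_real_, n = 0L,
         dim_names = dims, mapping = NULL),
    class = "phasor_gmm"
  )
  mapped <- map_components(model, sig)
  expect_equal(mapped$mapping,
               c(sig$target[perm], "autofluorescence"))
})

test_that("puncta mean phasors are intensity-weighted", {
  # three-voxel hand oracle
  f <- list(
    spectral_g = array(0, c(1, 1, 3)), spectral_s = array(0, c(1, 1, 3)),
    lifetime_g = array(c(0.2, 0.5, 0.8), c(1, 1, 3)),
    lifetime_s = array(c(0.1, 0.4, 0.3), c(1, 1, 3)),
    intensity = array(c(100, 50, 50), c(1, 1, 3)),
    valid = array(TRUE, c(1, 1, 3)),
    voxel_um = c(0.1, 0.1, 0.3), rep_frequency_hz = 78e6,
    n_channels = 1L, harmonic = 1L, min_photons = 10L
  )
  class(f) <- "phasor_field"
  pu <- tibble::tibble(id = 1L, z = 1L, y = 1L, x = 2L)
  got <- puncta_phasor(pu, f, puncta_size_um = 0.03) # 2 sigma reaches x +/- 1
  w <- c(100, 50, 50)
  expect_equal(got$lifetime_g, sum(w * c(0.2, 0.5, 0.8)) / sum(w))
  expect_equal(got$lifetime_s, sum(w * c(0.1, 0.4, 0.3)) / sum(w))
  expect_equal(got$n_valid, 3L)

  # all-identical phasors pass through; equal weights give the midpoint
  f$intensity <- array(c(60, 60, 1e9), c(1, 1, 3))
  f$valid <- array(c(TRUE, TRUE, FALSE), c(1, 1, 3))
  pu2 <- tibble::tibble(id = 1L, z = 1L, y = 1L, x = 1L)
  got2 <- puncta_phasor(pu2, f, puncta_size_um = 0.03)
  expect_equal(got2$lifetime_g, mean(c(0.2, 0.5)))
  expect_equal(got2$n_valid, 2L)

  # no valid member voxels: undefined phasor
  f$valid <- array(FALSE, c(1, 1, 3))
  got3 <- puncta_phasor(pu2, f, puncta_size_um = 0.03)
  expect_true(is.na(got3$lifetime_g))
  expect_equal(got3$n_valid, 0L)
})

test_that("decoding applies the rejection rules in order", {
  cb <- demo_codebook()
  model <- signature_model(cb, 78e6)
  sig <- expected_signatures(cb, 78e6)
  mk <- function(chans, gs) {
    tibble::tibble(
      id = 1L, z = 1L, y = 1L, x = 1L,
      channels = list(chans),
      spectral_g = gs[1], spectral_s = gs[2],
      lifetime_g = gs[3], lifetime_s = gs[4]
    )
  }
  # more than two channels: overlapping, regardless of phasor
  g1 <- as.numeric(sig[1, c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")])
  expect_equal(decode_puncta(mk(c(1L, 2L, 4L), g1), model, cb)$label, "overlapping")
  # single channel in a pair-only codebook: undetermined
  expect_equal(decode_puncta(mk(2L, g1), model, cb)$label, "undetermined")
  # matching channel set at the signature centroid: assigned with posterior ~ 1
  ch1 <- sig$channels[[1]]
  got <- decode_puncta(mk(ch1, g1), model, cb)
  expect_equal(got$label, sig$target[1])
  expect_gt(got$posterior, 0.99)
  # phasor near a *different* codeword's centroid but inconsistent channels:
  # the consistent component wins
  g5 <- as.numeric(sig[5, c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")])
  got2 <- decode_puncta(mk(ch1, g5), model, cb)
  expect_true(got2$label %in% c(sig$target[1], "undetermined"))
  expect_false(identical(got2$label, sig$target[5]))
})

test_that("singleton codewords disable single-channel rejection on their channel", {
  cb <- build_codebook(
    mixed_lifetime_panel(), c("short", "both", "long"),
    codewords = list("AX647", c("AX647", "AT647"), "AT647"),
    allow_singletons = TRUE
  )
  model <- signature_model(cb, 78e6, mode = "lifetime")
  p_short <- closed_form_phasor(1.0)
  pu <- tibble::tibble(
    id = 1L, z = 1L, y = 1L, x = 1L, channels = list(2L),
    lifetime_g = unname(p_short["g"]), lifetime_s = unname(p_short["s"])
  )
  expect_equal(decode_puncta(pu, model, cb)$label, "short")
  # the midpoint decodes to the pair codeword
  p_mid <- (closed_form_phasor(1.0) + closed_form_phasor(3.5)) / 2
  pu$lifetime_g <- unname(p_mid["g"]); pu$lifetime_s <- unname(p_mid["s"])
  expect_equal(decode_puncta(pu, model, cb)$label, "both")
  # channel 1 has no codeword in this book: undetermined
  pu$channels <- list(1L)
  expect_equal(decode_puncta(pu, model, cb)$label, "undetermined")
})

test_that("lifetime component fractions follow the chord projection", {
  a <- closed_form_phasor(1.0)
  b <- closed_form_phasor(3.5)
  expect_equal(component_fraction(a, a, b), 1)
  expect_equal(component_fraction(b, a, b), 0)
  expect_equal(component_fraction((a + b) / 2, a, b), 0.5)
  # an off-chord point projects to the same fraction as its chord foot
  mid <- (a + b) / 2
  chord <- a - b
  ortho <- c(-chord[2], chord[1]) / sqrt(sum(chord^2))
  expect_equal(component_fraction(mid + 0.05 * ortho, a, b), 0.5, tolerance = 1e-12)
  # fractions clamp to [0, 1]
  expect_equal(component_fraction(a + 2 * chord, a, b), 1)
  expect_error(component_fraction(a, a, a), "distinct")
})

test_that("decode summaries conserve counts across categories", {
  labels <- c(rep("gene1", 5), rep("gene2", 3), rep("undetermined", 4),
              rep("overlapping", 2))
  s <- decode_summary(labels)
  cats <- s[s$group %in% c("assigned", "undetermined", "overlapping"), ]
  expect_equal(sum(cats$count), length(labels))
  expect_equal(cats$count[cats$group == "assigned"], 8L)
  expect_equal(sum(s$count[s$group == "target"]), 8L)
  expect_equal(sum(cats$percent), 100)
})

test_that("the full classification pipeline decodes a low-density stack", {
  cb <- demo_codebook()
  cfg <- small_config(codebook = cb, counts_per_target = 2L, seed = 21L)
  sim <- simulate_experiment(cfg)
  res <- classify_stack(sim$stack, cb, seed = 2L)

  # conservation: assigned + undetermined + overlapping = total detected
  cats <- res$summary[res$summary$group %in%
                        c("assigned", "undetermined", "overlapping"), ]
  expect_equal(sum(cats$count), nrow(res$puncta))

  # >= 90% of decoded puncta match the nearest ground-truth target
  dec <- res$puncta[!res$puncta$label %in% c("undetermined", "overlapping"), ]
  expect_gt(nrow(dec), 0)
  ok <- vapply(seq_len(nrow(dec)), function(i) {
    d2 <- (sim$truth$x_um - dec$x_um[i])^2 + (sim$truth$y_um - dec$y_um[i])^2 +
      (sim$truth$z_um - dec$z_um[i])^2
    sim$truth$target[which.min(d2)] == dec$label[i]
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # decoding is invariant to global intensity scaling
  scaled <- sim$stack
  scaled$counts <- scaled$counts * 3L
  res2 <- classify_stack(scaled, cb, seed = 2L)
  expect_equal(sort(res2$puncta$label), sort(res$puncta$label))

  # negative control: background-only stack assigns ~ nothing
  cfg0 <- small_config(codebook = cb, counts_per_target = 0L,
                       volume_um = c(4, 4, 3), background_rate = 0.5, seed = 22L)
  sim0 <- simulate_experiment(cfg0)
  res0 <- classify_stack(sim0$stack, cb, seed = 2L)
  assigned0 <- res0$summary$count[res0$summary$group == "assigned"]
  expect_lte(assigned0, 1)
})

test_that("tidy and glance expose the mixture parameters", {
  set.seed(6)
  x <- rbind(rmvn2(300, c(0.3, 0.3), diag(1e-4, 2)),
             rmvn2(300, c(0.5, 0.5), diag(1e-4, 2)))
  colnames(x) <- c("lifetime_g", "lifetime_s")
  m <- fit_phasor_gmm(x, 2, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_true(all(c("component", "weight", "lifetime_g", "lifetime_s") %in% names(td)))
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  gl <- glance(m)
  expect_equal(gl$k, 2)
  expect_equal(gl$n, 600)
})
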