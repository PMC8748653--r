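#' Fit a Gaussian mixture model to phasor coordinates
#'
#' EM fit with full (unconstrained) covariances via [mclust::Mclust()], with
#' deterministic model-based initialisation on a seeded subset. Use one
#' component per expected signature plus one extra to absorb autofluorescence
#' and noise. Near-singular covariances are regularised by a diagonal floor.
#'
#' @param x matrix or data frame of phasor coordinates (2 or 4 columns:
#'   lifetime-only or joint spectral/lifetime).
#' @param k number of mixture components.
#' @param seed RNG seed for the initialisation subset.
#' @param covariance_floor diagonal regularisation added when a component
#'   covariance is not positive-definite.
#'
#' @return An object of class `phasor_gmm` with elements `k`, `d`, `means`
#'   (k x d), `covariances` (d x d x k), `weights`, `loglik`, `n`, and an
#'   initially empty component-to-codeword `mapping`.
#' @export
fit_phasor_gmm <- function(x, k, seed = 1L, covariance_floor = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 10 * k) stop("need at least 10 observations per component")
  sub <- NULL
  if (nrow(x) > 2000) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sub <- sample.int(nrow(x), 2000)
  }
  fit <- Mclust(
    x, G = k, modelNames = "VVV",
    initialization = if (is.null(sub)) NULL else list(subset = sub),
    verbose = FALSE
  )
  if (is.null(fit)) stop("EM failed to fit a ", k, "-component mixture")
  d <- ncol(x)
  sigma <- fit$parameters$variance$sigma
  for (j in seq_len(k)) {
    if (inherits(try(chol(sigma[, , j]), silent = TRUE), "try-error")) {
      warning("singular covariance in component ", j, "; applying floor")
      sigma[, , j] <- sigma[, , j] + diag(covariance_floor, d)
    }
  }
  structure(
    list(
      k = k, d = d,
      means = t(fit$parameters$mean),
      covariances = sigma,
      weights = fit$parameters$pro,
      loglik = fit$loglik,
      n = nrow(x),
      dim_names = colnames(x) %||% paste0("phasor", seq_len(d)),
      mapping = NULL
    ),
    class = "phasor_gmm"
  )
}

# save/restore RNG state so seeded subsampling does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.phasor_gmm <- function(x, ...) {
  cat(sprintf("<phasor_gmm> %d components in %dD, n = %d, loglik = %.1f\n",
              x$k, x$d, x$n, x$loglik))
  if (!is.null(x$mapping)) {
    cat("  mapped:", paste(x$mapping, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.phasor_gmm <- function(x, ...) {
  out <- tibble::as_tibble(x$means)
  names(out) <- x$dim_names
  dplyr::bind_cols(
    tibble::tibble(
      component = seq_len(x$k),
      weight = x$weights,
      label = x$mapping %||% rep(NA_character_, x$k)
    ),
    out
  )
}

#' @export
glance.phasor_gmm <- function(x, ...) {
  n_par <- x$k - 1 + x$k * x$d + x$k * x$d * (x$d + 1) / 2
  tibble::tibble(
    k = x$k, dimensions = x$d, n = x$n, loglik = x$loglik,
    bic = 2 * x$loglik - n_par * log(x$n)
  )
}

#' Posterior component probabilities for new phasor points
#'
#' Direct Bayes-rule evaluation of the fitted mixture at new coordinates,
#' allowing components to be empty in the new data (a pretrained model can be
#' applied to any later acquisition).
#'
#' @param model a [fit_phasor_gmm()] model.
#' @param x matrix/data frame of coordinates with `model$d` columns.
#'
#' @return An `n x k` matrix of posterior probabilities (rows sum to 1).
#' @export
posterior_phasor <- function(model, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == model$d)
  logd <- vapply(seq_len(model$k), function(j) {
    log(model$weights[j]) + log_dmvnorm(x, model$means[j, ], model$covariances[, , j])
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p / rowSums(p)
}

#' Assign phasor points to mixture components
#'
#' @inheritParams posterior_phasor
#'
#' @return A tibble with `component` (argmax posterior), `posterior` (its
#'   probability) and `label` (the mapped codeword when the model carries a
#'   mapping).
#' @export
assign_phasors <- function(model, x) {
  p <- posterior_phasor(model, x)
  comp <- max.col(p, ties.method = "first")
  tibble::tibble(
    component = comp,
    posterior = p[cbind(seq_len(nrow(p)), comp)],
    label = if (is.null(model$mapping)) NA_character_ else model$mapping[comp]
  )
}

#' Match mixture components to codebook signatures
#'
#' Resolves EM label switching by assigning each expected signature to the
#' nearest component mean, jointly, via the Hungarian algorithm
#' ([clue::solve_LSAP()]); components left unassigned (the fit has one more
#' component than there are signatures) are labelled `"autofluorescence"`.
#'
#' @param model a [fit_phasor_gmm()] model.
#' @param signatures an [expected_signatures()] tibble.
#' @param dims which signature coordinates to match on; defaults to the
#'   model's dimensionality (4D joint, or the lifetime pair for a 2D model).
#'
#' @return The model with its `mapping` field filled (component -> target).
#' @export
map_components <- function(model, signatures, dims = NULL) {
  stopifnot(inherits(model, "phasor_gmm"))
  if (is.null(dims)) {
    dims <- if (model$d == 4) {
      c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")
    } else {
      c("lifetime_g", "lifetime_s")
    }
  }
  sig <- as.matrix(signatures[, dims])
  if (nrow(sig) > model$k) {
    stop("more signatures than mixture components")
  }
  cost <- outer(seq_len(nrow(sig)), seq_len(model$k), Vectorize(function(i, j) {
    sqrt(sum((sig[i, ] - model$means[j, ])^2))
  }))
  sol <- clue::solve_LSAP(cost)
  mapping <- rep("autofluorescence", model$k)
  mapping[as.integer(sol)] <- signatures$target
  model$mapping <- mapping
  model
}

#' Build a mixture model directly from codebook signatures
#'
#' A pretrained-model substitute for runs with too few puncta to fit EM (or
#' for decoding against a priori expectations): one isotropic component per
#' expected signature, plus a broad central autofluorescence component, with
#' equal weights and the component-to-codeword mapping already filled.
#'
#' @param codebook a [build_codebook()] result.
#' @param rep_frequency_hz laser repetition frequency in Hz.
#' @param mode `"4d"` joint spectral/lifetime or `"lifetime"` only.
#' @param sd per-coordinate standard deviation of each signature component
#'   (phasor units); the experimental phasor scatter is typically around 0.01.
#'
#' @return A mapped `phasor_gmm`.
#' @export
signature_model <- function(codebook, rep_frequency_hz = 78e6,
                            mode = c("4d", "lifetime"), sd = 0.01) {
  mode <- match.arg(mode)
  sig <- expected_signatures(codebook, rep_frequency_hz)
  dims_cols <- if (mode == "4d") {
    c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")
  } else {
    c("lifetime_g", "lifetime_s")
  }
  d <- length(dims_cols)
  k <- nrow(sig) + 1L
  covs <- array(0, c(d, d, k))
  for (j in seq_len(k - 1L)) covs[, , j] <- diag(sd^2, d)
  covs[, , k] <- diag((10 * sd)^2, d) # broad autofluorescence catch-all
  means <- rbind(as.matrix(sig[, dims_cols]), rep(0.4, d))
  model <- structure(
    list(k = k, d = d, means = means, covariances = covs,
         weights = rep(1 / k, k), loglik = NA_real_, n = 0L,
         dim_names = dims_cols, mapping = NULL),
    class = "phasor_gmm"
  )
  map_components(model, sig, dims = dims_cols)
}

#' Mean phasor of each punctum
#'
#' Intensity-weighted mean of the phasor coordinates of the valid voxels in
#' each punctum's 2-sigma ellipsoid. Puncta with no valid member voxel get
#' `NA` phasors (and decode to undetermined downstream).
#'
#' @param puncta a [measure_puncta()] / [detect_puncta()] tibble.
#' @param field a [phasor_transform()] result.
#' @param puncta_size_um expected punctum size in micrometres.
#'
#' @return The puncta tibble with added `spectral_g`, `spectral_s`,
#'   `lifetime_g`, `lifetime_s`, `n_valid` columns.
#' @export
puncta_phasor <- function(puncta, field, puncta_size_um = 0.25) {
  stopifnot(inherits(field, "phasor_field"))
  d <- dim(field$intensity)
  sigma <- puncta_size_um / c(field$voxel_um[3], field$voxel_um[2], field$voxel_um[1])
  offs <- ellipsoid_offsets(2 * sigma)
  one <- function(zc, yc, xc) {
    vox <- sweep(offs, 2, c(zc, yc, xc), "+")
    inb <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
      vox[, 2] >= 1 & vox[, 2] <= d[2] &
      vox[, 3] >= 1 & vox[, 3] <= d[3]
    vox <- vox[inb, , drop = FALSE]
    lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
    lin <- lin[field$valid[lin]]
    if (length(lin) == 0) {
      return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    }
    w <- field$intensity[lin]
    c(
      sum(w * field$spectral_g[lin]) / sum(w),
      sum(w * field$spectral_s[lin]) / sum(w),
      sum(w * field$lifetime_g[lin]) / sum(w),
      sum(w * field$lifetime_s[lin]) / sum(w),
      length(lin)
    )
  }
  vals <- t(mapply(one, puncta$z, puncta$y, puncta$x))
  if (nrow(puncta) == 0) {
    vals <- matrix(numeric(0), ncol = 5)
  }
  puncta$spectral_g <- vals[, 1]
  puncta$spectral_s <- vals[, 2]
  puncta$lifetime_g <- vals[, 3]
  puncta$lifetime_s <- vals[, 4]
  puncta$n_valid <- as.integer(vals[, 5])
  puncta
}

#' Decode puncta into codeword labels with error rejection
#'
#' Applies the gating rules in order: (1) presence in more than two spectral
#' channels means several transcripts share the punctum — `"overlapping"`;
#' (2) presence in fewer than two channels with no codeword expected on
#' exactly that channel set (a singleton dye, or a pair sharing one channel)
#' — `"undetermined"`; (3) otherwise the punctum takes the codeword of its
#' maximum-posterior mixture component among those consistent with the
#' channel set, provided the posterior reaches `posterior_threshold`;
#' assignment to the autofluorescence component, an inconsistent channel set
#' or a low posterior all yield `"undetermined"`. Low-confidence puncta keep
#' their posterior in the output rather than being dropped.
#'
#' @param puncta a [puncta_phasor()] tibble (needs `channels` and phasor
#'   columns).
#' @param model a mapped [fit_phasor_gmm()] (see [map_components()]).
#' @param codebook the [build_codebook()] in use.
#' @param posterior_threshold minimum posterior for assignment, default 0.5.
#'
#' @return The puncta tibble with `label` and `posterior` columns.
#' @export
decode_puncta <- function(puncta, model, codebook, posterior_threshold = 0.5) {
  stopifnot(inherits(model, "phasor_gmm"), !is.null(model$mapping))
  sig <- expected_signatures(codebook, 78e6)
  # channel-set key per codeword, e.g. "1+3" or "2"
  cw_key <- vapply(sig$channels, function(ch) paste(ch, collapse = "+"), character(1))
  names(cw_key) <- sig$target

  dims_cols <- if (model$d == 4) {
    c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")
  } else {
    c("lifetime_g", "lifetime_s")
  }

  n <- nrow(puncta)
  label <- rep("undetermined", n)
  post <- rep(NA_real_, n)
  if (n > 0) {
    xs <- as.matrix(puncta[, dims_cols])
    has_phasor <- stats::complete.cases(xs)
    pp <- matrix(NA_real_, n, model$k)
    if (any(has_phasor)) {
      pp[has_phasor, ] <- posterior_phasor(model, xs[has_phasor, , drop = FALSE])
    }
    for (i in seq_len(n)) {
      chans <- sort(unique(puncta$channels[[i]]))
      if (length(chans) > 2) {
        label[i] <- "overlapping"
        next
      }
      key <- paste(chans, collapse = "+")
      consistent <- names(cw_key)[cw_key == key]
      if (length(chans) < 2 && length(consistent) == 0) next # undetermined
      if (!has_phasor[i]) next
      comp_ok <- which(model$mapping %in% consistent)
      if (length(comp_ok) == 0) next
      j <- comp_ok[which.max(pp[i, comp_ok])]
      post[i] <- pp[i, j]
      if (pp[i, j] >= posterior_threshold) label[i] <- model$mapping[j]
    }
  }
  puncta$label <- label
  puncta$posterior <- post
  puncta
}

#' Fraction of one lifetime component in a phasor point
#'
#' Multicomponent analysis on the chord between two pure-species phasor
#' positions: the photon-weighted share of component `a` is the scalar
#' projection of `p - b` onto `a - b`, normalised by the squared chord
#' length and clamped to `[0, 1]`. Points off the chord (noise, a third
#' species) project orthogonally onto it.
#'
#' @param p matrix (or length-2 vector) of phasor points.
#' @param a,b the two pure-component phasor positions (distinct).
#'
#' @return Fractions in `[0, 1]`, one per row of `p`.
#' @export
#'
#' @examples
#' a <- c(0.81, 0.40); b <- c(0.25, 0.44)
#' component_fraction((a + b) / 2, a, b) # equal mixture -> 0.5
component_fraction <- function(p, a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b)) stop("endpoints must be distinct")
  p <- matrix(as.numeric(unlist(p)), ncol = length(a))
  f <- as.vector((sweep(p, 2, b) %*% (a - b)) / sum((a - b)^2))
  pmin(pmax(f, 0), 1)
}

#' Summarise decoding bookkeeping
#'
#' Conservation-checked tally of the decoder's categories: every detected
#' punctum is exactly one of assigned (a codeword), undetermined, or
#' overlapping.
#'
#' @param decoded a [decode_puncta()] tibble, or a character vector of labels.
#'
#' @return A tibble with one row per category (`assigned`, `undetermined`,
#'   `overlapping`) plus counts per target, with `count` and `percent` of the
#'   total detected.
#' @export
decode_summary <- function(decoded) {
  labels <- if (is.character(decoded)) decoded else decoded$label
  total <- length(labels)
  cat_of <- function(l) {
    ifelse(l %in% c("undetermined", "overlapping"), l, "assigned")
  }
  cats <- table(factor(cat_of(labels),
                       levels = c("assigned", "undetermined", "overlapping")))
  by_cat <- tibble::tibble(
    group = names(cats),
    target = NA_character_,
    count = as.integer(cats),
    percent = if (total > 0) 100 * as.integer(cats) / total else rep(NA_real_, 3)
  )
  tg <- labels[!labels %in% c("undetermined", "overlapping")]
  by_target <- if (length(tg) > 0) {
    tt <- sort(table(tg), decreasing = TRUE)
    tibble::tibble(
      group = "target", target = names(tt),
      count = as.integer(tt), percent = 100 * as.integer(tt) / total
    )
  } else {
    NULL
  }
  dplyr::bind_rows(by_cat, by_target)
}

#' Run the full decoding pipeline on a photon stack
#'
#' Composition of the pipeline stages: phasor transform, 3-D blob detection,
#' per-punctum mean phasors, Gaussian-mixture classification and codeword
#' decoding with error rejection. When no pretrained model is supplied one is
#' fitted on the detected puncta phasors with one component per signature
#' plus an autofluorescence component; if too few puncta are available for EM
#' the expected signatures themselves serve as fixed mixture centres.
#'
#' @param stack a [photon_stack()].
#' @param codebook the [build_codebook()] used in the experiment.
#' @param model optional pretrained [fit_phasor_gmm()]; refitted when `NULL`.
#' @param mode `"4d"` for joint spectral/lifetime clustering or `"lifetime"`
#'   for clustering on the lifetime phasor only (spectral identity then comes
#'   from channel presence alone, appropriate for few, discrete channels).
#' @param min_photons phasor validity threshold per voxel.
#' @param puncta_size_um expected punctum size.
#' @param min_prominence detection threshold, `NULL` for the robust default.
#' @param channel_snr_threshold per-channel presence threshold.
#' @param posterior_threshold decoding threshold.
#' @param seed seed for the GMM initialisation.
#'
#' @return A list of class `flim_decode`: `puncta` (decoded tibble),
#'   `summary` ([decode_summary()]), `model`, `field`.
#' @export
classify_stack <- function(stack, codebook, model = NULL,
                           mode = c("4d", "lifetime"),
                           min_photons = 10L, puncta_size_um = 0.25,
                           min_prominence = NULL, channel_snr_threshold = 3,
                           posterior_threshold = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  field <- phasor_transform(stack, min_photons = min_photons)
  puncta <- detect_puncta(stack, puncta_size_um, min_prominence,
                          channel_snr_threshold)
  puncta <- puncta_phasor(puncta, field, puncta_size_um)

  sig <- expected_signatures(codebook, stack$rep_frequency_hz)
  dims_cols <- if (mode == "4d") {
    c("spectral_g", "spectral_s", "lifetime_g", "lifetime_s")
  } else {
    c("lifetime_g", "lifetime_s")
  }
  if (is.null(model)) {
    xs <- as.matrix(puncta[, dims_cols])
    xs <- xs[stats::complete.cases(xs), , drop = FALSE]
    k <- nrow(sig) + 1L
    if (nrow(xs) >= 10 * k) {
      model <- map_components(fit_phasor_gmm(xs, k, seed = seed), sig,
                              dims = dims_cols)
    } else {
      model <- signature_model(codebook, stack$rep_frequency_hz, mode = mode)
    }
  }
  puncta <- decode_puncta(puncta, model, codebook, posterior_threshold)
  structure(
    list(
      puncta = puncta,
      summary = decode_summary(puncta),
      model = model,
      field = field
    ),
    class = "flim_decode"
  )
}

#' @export
print.flim_decode <- function(x, ...) {
  cat(sprintf("<flim_decode> %d puncta\n", nrow(x$puncta)))
  print(head(x$summary, 3))
  invisible(x)
}
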