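#' Expected fraction of isolated puncta
#'
#' Analytic optical-crowding model: with `N` puncta placed independently and
#' uniformly in a volume `V_T`, a given punctum is isolated (resolvable) when
#' none of the other `N - 1` falls inside its exclusion volume `v_i` (the
#' instrument PSF volume, since transcripts are sub-diffraction), so the
#' expected isolated fraction is `n / N = (1 - v_i / V_T)^(N - 1)`.
#'
#' @param n_total true number of puncta `N` (vectorised, >= 1).
#' @param psf_volume_um3 per-punctum exclusion volume `v_i` in um^3.
#' @param total_volume_um3 scanned/cellular volume `V_T` in um^3.
#'
#' @return Isolated fraction(s) in `(0, 1]`.
#' @export
#'
#' @examples
#' isolated_fraction(13776, 0.1, 68000) # ~0.98
isolated_fraction <- function(n_total, psf_volume_um3, total_volume_um3) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(psf_volume_um3 < 0) || any(psf_volume_um3 >= total_volume_um3)) {
    stop("need 0 <= psf_volume_um3 < total_volume_um3")
  }
  (1 - psf_volume_um3 / total_volume_um3)^(n_total - 1)
}

#' Estimate the true puncta count from the detected count
#'
#' Numerically inverts the crowding model: solves
#' `N * (1 - v_i / V_T)^(N - 1) = n` for the smaller positive root by
#' bracketed bisection on `[n, N*]`, where `N* = 1 / ln(1 / (1 - v_i / V_T))`
#' maximises the left-hand side and so bounds the physical root (the larger
#' root corresponds to a volume almost tiled by puncta and is discarded).
#'
#' @param n_detected detected (isolated) puncta count `n`, >= 0.
#' @param psf_volume_um3 per-punctum exclusion volume in um^3.
#' @param total_volume_um3 total volume in um^3.
#' @param tol relative tolerance of the root, default 1e-8.
#'
#' @return The estimated true count `N >= n`.
#' @export
#'
#' @examples
#' estimate_true_count(13500, 0.1, 68000) # ~13776, a 2.0% loss
estimate_true_count <- function(n_detected, psf_volume_um3, total_volume_um3,
                                tol = 1e-8) {
  if (n_detected < 0) stop("n_detected must be >= 0")
  if (n_detected == 0) return(0)
  p <- psf_volume_um3 / total_volume_um3
  if (p <= 0) return(n_detected)
  n_star <- -1 / log1p(-p) # maximiser of N (1-p)^(N-1)
  f <- function(N) N * (1 - p)^(N - 1) - n_detected
  if (f(n_star) < 0) {
    stop("detected count exceeds the model's maximum: density beyond validity")
  }
  uniroot(f, lower = n_detected, upper = n_star,
          tol = tol * n_star)$root
}

#' Crowding-loss interval over a range of PSF volumes
#'
#' Inverts the crowding model at the two endpoints of an assumed PSF-volume
#' interval and reports the percentage of puncta lost to overlap at each.
#' The headline `loss_pct` is relative to the detected count,
#' `100 * (N - n) / n`; the loss relative to the true count,
#' `100 * (N - n) / N`, is also reported.
#'
#' @param n_detected detected puncta count.
#' @param total_volume_um3 total imaged cellular volume in um^3.
#' @param psf_volume_um3 PSF-volume endpoints (or any grid) in um^3.
#'
#' @return A tibble with one row per PSF volume: `psf_volume_um3`,
#'   `n_true`, `loss_pct` (vs detected, rounded to 1 decimal) and
#'   `loss_pct_true` (vs true).
#' @export
#'
#' @examples
#' overlap_interval(13500, 68000, c(0.1, 0.3)) # 2.0% to 6.6%
overlap_interval <- function(n_detected, total_volume_um3,
                             psf_volume_um3 = c(0.1, 0.3)) {
  stopifnot(all(psf_volume_um3 > 0), all(diff(psf_volume_um3) >= 0))
  n_true <- vapply(psf_volume_um3, estimate_true_count,
                   numeric(1), n_detected = n_detected,
                   total_volume_um3 = total_volume_um3)
  tibble::tibble(
    psf_volume_um3 = psf_volume_um3,
    n_detected = n_detected,
    n_true = n_true,
    loss_pct = round(100 * (n_true - n_detected) / n_detected, 1),
    loss_pct_true = round(100 * (n_true - n_detected) / n_true, 1)
  )
}

#' Monte-Carlo verification of the crowding model
#'
#' Places `N` points uniformly at random in a box of volume `V_T`; a point
#' counts as isolated when no other point lies within the merge distance
#' implied by the PSF volume — the radius of the sphere of volume `v_i`, so
#' that the exclusion volume around each punctum equals `v_i` as in the
#' analytic model. Reports the mean observed isolated fraction across
#' iterations against the model prediction for each density.
#'
#' @param n_points vector of true puncta counts (one density per value).
#' @param iterations random placements per density, default 10.
#' @param psf_volume_um3 per-punctum volume in um^3.
#' @param total_volume_um3 box volume in um^3 (cube side `V_T^(1/3)`).
#' @param periodic use periodic (minimum-image) distances, default `TRUE`.
#'   The analytic model describes a homogeneous medium; toroidal wrapping
#'   removes the box-edge bias (spheres clipped by the walls) that a finite
#'   box would otherwise introduce.
#' @param seed RNG seed.
#'
#' @return A tibble of class `crowding_sim` with per-density rows:
#'   `n_points`, `observed` (mean isolated fraction), `se` (standard error
#'   over iterations), `predicted`.
#' @export
simulate_crowding <- function(n_points, iterations = 10L,
                              psf_volume_um3 = 0.1,
                              total_volume_um3 = 1000,
                              periodic = TRUE,
                              seed = 1L) {
  stopifnot(iterations >= 1, all(n_points >= 1))
  set.seed(seed)
  side <- total_volume_um3^(1 / 3)
  r <- (3 * psf_volume_um3 / (4 * pi))^(1 / 3) # radius of equal-volume sphere
  pair_dist2 <- function(pts) {
    n <- nrow(pts)
    d2 <- matrix(0, n, n)
    for (ax in 1:3) {
      dd <- abs(outer(pts[, ax], pts[, ax], "-"))
      if (periodic) dd <- pmin(dd, side - dd)
      d2 <- d2 + dd^2
    }
    d2
  }
  one <- function(n) {
    fr <- vapply(seq_len(iterations), function(it) {
      pts <- matrix(runif(3 * n, 0, side), ncol = 3)
      if (n == 1) return(1)
      d2 <- pair_dist2(pts)
      diag(d2) <- Inf
      mean(apply(d2, 1, min) >= r^2)
    }, numeric(1))
    tibble::tibble(
      n_points = n,
      observed = mean(fr),
      se = if (iterations > 1) sd(fr) / sqrt(iterations) else NA_real_,
      predicted = isolated_fraction(n, psf_volume_um3, total_volume_um3)
    )
  }
  out <- dplyr::bind_rows(lapply(n_points, one))
  class(out) <- c("crowding_sim", class(out))
  out
}
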