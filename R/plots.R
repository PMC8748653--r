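#' Plot a phasor field
#'
#' Two-panel-style phasor plot of the valid voxels: the lifetime phasor
#' cloud with the universal semicircle, or the spectral phasor cloud with
#' the unit circle.
#'
#' @param object a `phasor_field`.
#' @param which `"lifetime"` or `"spectral"`.
#' @param bins bin count for the 2-D histogram.
#' @param ... unused.
#'
#' @return A ggplot object.
#' @method autoplot phasor_field
#' @export
autoplot.phasor_field <- function(object, which = c("lifetime", "spectral"),
                                  bins = 120, ...) {
  which <- match.arg(which)
  df <- as_tibble(object, valid_only = TRUE)
  gcol <- paste0(substr(which, 1, 8), "_g")
  scol <- paste0(substr(which, 1, 8), "_s")
  theta <- seq(0, pi, length.out = 200)
  guide <- if (which == "lifetime") {
    tibble::tibble(g = 0.5 + 0.5 * cos(theta), s = 0.5 * sin(theta))
  } else {
    th <- seq(0, 2 * pi, length.out = 400)
    tibble::tibble(g = cos(th), s = sin(th))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[gcol]], y = .data[[scol]])) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_path(data = guide, ggplot2::aes(x = .data$g, y = .data$s),
                       inherit.aes = FALSE, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "G", y = "S",
                  title = paste(which, "phasor")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted phasor mixture
#'
#' Component means with 2-sigma covariance ellipses over the first two
#' model dimensions (lifetime G/S for a 2-D model).
#'
#' @param object a `phasor_gmm`.
#' @param dims which two dimensions to draw, default `c(1, 2)`.
#' @param ... unused.
#'
#' @return A ggplot object.
#' @method autoplot phasor_gmm
#' @export
autoplot.phasor_gmm <- function(object, dims = c(1, 2), ...) {
  stopifnot(length(dims) == 2)
  theta <- seq(0, 2 * pi, length.out = 100)
  circ <- rbind(cos(theta), sin(theta))
  ell <- dplyr::bind_rows(lapply(seq_len(object$k), function(j) {
    s <- object$covariances[dims, dims, j]
    e <- eigen(s)
    pts <- t(object$means[j, dims] +
               e$vectors %*% diag(2 * sqrt(pmax(e$values, 0))) %*% circ)
    tibble::tibble(component = factor(j), g = pts[, 1], s = pts[, 2])
  }))
  ctr <- tibble::tibble(
    component = factor(seq_len(object$k)),
    g = object$means[, dims[1]], s = object$means[, dims[2]],
    label = object$mapping %||% as.character(seq_len(object$k))
  )
  ggplot2::ggplot(ell, ggplot2::aes(x = .data$g, y = .data$s,
                                    colour = .data$component)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = ctr, size = 2) +
    ggplot2::geom_text(data = ctr, ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "G", y = "S", title = "phasor mixture components") +
    ggplot2::theme_minimal()
}

#' Plot a crowding simulation against the analytic model
#'
#' @param object a [simulate_crowding()] tibble.
#' @param ... unused.
#'
#' @return A ggplot object.
#' @method autoplot crowding_sim
#' @export
autoplot.crowding_sim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_points)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$observed,
      ymin = .data$observed - 3 * .data$se,
      ymax = .data$observed + 3 * .data$se
    )) +
    ggplot2::labs(x = "true puncta count", y = "isolated fraction",
                  title = "optical crowding: simulation vs model") +
    ggplot2::theme_minimal()
}

#' Histogram of lifetime component fractions
#'
#' For puncta carrying zero, half or all of component `a`'s photons the
#' fraction histogram is trimodal at 0, 1/2 and 1.
#'
#' @param fractions numeric vector from [component_fraction()].
#' @param bins histogram bins, default 40.
#'
#' @return A ggplot object.
#' @export
plot_fraction_histogram <- function(fractions, bins = 40) {
  ggplot2::ggplot(tibble::tibble(fraction = fractions),
                  ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(0, 0.5, 1), linetype = 3) +
    ggplot2::labs(x = "component fraction", y = "puncta") +
    ggplot2::theme_minimal()
}

#' Scatter plot of counts vs reference expression
#'
#' @param correlation a [correlate_with_reference()] result.
#'
#' @return A ggplot object.
#' @export
autoplot_correlation <- function(correlation) {
  df <- attr(correlation, "data")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(
      x = "reference expression", y = "detected counts",
      title = sprintf("Pearson r = %.2f", correlation$r[1])
    ) +
    ggplot2::theme_minimal()
}
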