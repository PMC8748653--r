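#' Number of unordered fluorophore pairs
#'
#' With combinatorial labelling each target carries two distinct fluorophores,
#' so a panel of n dyes distinguishes `choose(n, 2) = (n^2 - n) / 2` targets:
#' multiplexing capacity grows quadratically in the panel size.
#'
#' @param n number of fluorophores in the panel (vectorised, each >= 1).
#'
#' @return Integer vector of pair counts.
#' @export
#'
#' @examples
#' n_pairs(5)  # 10-plex from five dyes
#' n_pairs(12) # 66-plex from twelve
n_pairs <- function(n) {
  if (any(n < 1)) stop("n must be >= 1")
  as.integer((n^2 - n) / 2)
}

#' Define a fluorophore panel
#'
#' @param name fluorophore names (unique).
#' @param emission_center_nm centre of the Gaussian emission profile.
#' @param emission_sigma_nm width (sd) of the emission profile, > 0.
#' @param lifetime_ns single-exponential fluorescence lifetime, > 0.
#' @param channel index of the spectral detection channel the dye dominates.
#' @param n_channels total number of detection channels (default
#'   `max(channel)`).
#'
#' @return A tibble with class `fluorophore_panel` carrying an `n_channels`
#'   attribute.
#' @export
fluorophore_panel <- function(name, emission_center_nm, emission_sigma_nm,
                              lifetime_ns, channel,
                              n_channels = max(channel)) {
  stopifnot(
    !anyDuplicated(name),
    all(emission_sigma_nm > 0),
    all(lifetime_ns > 0),
    all(channel >= 1), all(channel <= n_channels)
  )
  out <- tibble::tibble(
    name = as.character(name),
    emission_center_nm = as.numeric(emission_center_nm),
    emission_sigma_nm = as.numeric(emission_sigma_nm),
    lifetime_ns = as.numeric(lifetime_ns),
    channel = as.integer(channel)
  )
  attr(out, "n_channels") <- as.integer(n_channels)
  class(out) <- c("fluorophore_panel", class(out))
  out
}

#' Demonstration fluorophore panels
#'
#' `demo_panel()` returns five generic dyes spread over a 550-750 nm detector
#' with one dye per channel and lifetimes spanning 0.5-4 ns, loosely modelled
#' on common commercial fluorophores; its ten pairwise combinations drive the
#' 10-plex examples. `mixed_lifetime_panel()` returns a three-dye panel over
#' two channels in which the two red dyes share a spectral band and are
#' separated only by lifetime (1 ns vs 3.5 ns, the Alexa647/ATTO647 kind of
#' pair); it exercises singleton codewords and lifetime-only clustering.
#'
#' @return A [fluorophore_panel()].
#' @export
demo_panel <- function() {
  fluorophore_panel(
    name = c("DY560", "DY600", "DY640", "DY690", "DY730"),
    emission_center_nm = c(570, 610, 650, 690, 730),
    emission_sigma_nm = c(10, 10, 10, 10, 10),
    lifetime_ns = c(4.0, 2.5, 0.5, 1.0, 3.5),
    channel = c(1L, 2L, 3L, 4L, 5L),
    n_channels = 5L
  )
}

#' @rdname demo_panel
#' @export
mixed_lifetime_panel <- function() {
  fluorophore_panel(
    name = c("AT565", "AX647", "AT647"),
    emission_center_nm = c(590, 668, 669),
    emission_sigma_nm = c(15, 15, 15),
    lifetime_ns = c(3.4, 1.0, 3.5),
    channel = c(1L, 2L, 2L),
    n_channels = 2L
  )
}

#' Build a combinatorial codebook
#'
#' Assigns each target an unordered pair of panel fluorophores (or, where
#' explicitly requested, a single dye). When `codewords` is omitted the pairs
#' are assigned deterministically in lexicographic panel order. Singleton
#' codewords are permitted only with `allow_singletons = TRUE` because a
#' single-channel event is otherwise rejected as undetermined by the decoder;
#' a singleton target disables that rejection for its channel.
#'
#' @param panel a [fluorophore_panel()].
#' @param targets character vector of target names.
#' @param codewords optional named list (one entry per target) of character
#'   vectors of length 1 or 2 naming panel fluorophores.
#' @param negative_controls targets expected to produce no signal.
#' @param allow_singletons permit length-1 codewords.
#'
#' @return An object of class `flim_codebook`.
#' @export
#'
#' @examples
#' build_codebook(demo_panel(), paste0("gene", 1:10))
build_codebook <- function(panel, targets, codewords = NULL,
                           negative_controls = character(),
                           allow_singletons = FALSE) {
  stopifnot(inherits(panel, "fluorophore_panel"), !anyDuplicated(targets))
  if (is.null(codewords)) {
    if (length(targets) > n_pairs(nrow(panel))) {
      stop(sprintf(
        "codebook capacity exceeded: %d targets but only %d pairs from %d fluorophores",
        length(targets), n_pairs(nrow(panel)), nrow(panel)
      ))
    }
    pairs <- utils::combn(panel$name, 2)
    codewords <- lapply(seq_along(targets), function(i) pairs[, i])
  } else {
    stopifnot(length(codewords) == length(targets))
  }
  key <- vapply(codewords, function(cw) {
    cw <- as.character(cw)
    if (!all(cw %in% panel$name)) {
      stop("unknown fluorophore in codeword: ", paste(cw, collapse = ", "))
    }
    if (length(cw) == 2 && cw[1] == cw[2]) {
      stop("a pair codeword must use two distinct fluorophores")
    }
    if (length(cw) == 1 && !allow_singletons) {
      stop("singleton codewords require allow_singletons = TRUE")
    }
    if (!length(cw) %in% 1:2) stop("codewords must have 1 or 2 fluorophores")
    paste(sort(cw), collapse = "+")
  }, character(1))
  if (anyDuplicated(key)) stop("duplicate codeword: ", key[duplicated(key)][1])

  cw_sorted <- lapply(codewords, function(cw) sort(as.character(cw)))
  out <- structure(
    list(
      panel = panel,
      codewords = tibble::tibble(
        target = as.character(targets),
        fluor1 = unname(vapply(cw_sorted, `[`, character(1), 1)),
        fluor2 = unname(vapply(cw_sorted, function(cw) {
          if (length(cw) == 2) cw[2] else NA_character_
        }, character(1)))
      ),
      negative_controls = as.character(negative_controls)
    ),
    class = "flim_codebook"
  )
  out
}

#' @export
print.flim_codebook <- function(x, ...) {
  cat(sprintf(
    "<flim_codebook> %d targets from %d fluorophores (%d channels, capacity %d)\n",
    nrow(x$codewords), nrow(x$panel), attr(x$panel, "n_channels"),
    n_pairs(nrow(x$panel))
  ))
  print(x$codewords, n = 10)
  invisible(x)
}

codeword_fluors <- function(codebook, target) {
  row <- codebook$codewords[codebook$codewords$target == target, ]
  if (nrow(row) != 1) stop("unknown target: ", target)
  fl <- c(row$fluor1, row$fluor2)
  fl[!is.na(fl)]
}

#' Expected channel sets and phasor signatures of a codebook
#'
#' For every codeword, the expected spectral channels are the union of the two
#' dyes' channels, the expected lifetime phasor is the equal-photon midpoint
#' of the two dyes' single-exponential positions, and the expected spectral
#' phasor is the midpoint of their channel points on the unit circle (phasor
#' transforms are linear in photon fractions, so a 1:1 photon split lands in
#' the middle of the chord). Singleton codewords sit at the dye's own
#' position.
#'
#' @param codebook a [build_codebook()] result.
#' @param rep_frequency_hz laser repetition frequency in Hz.
#' @param harmonic positive integer harmonic, default 1.
#'
#' @return A tibble with one row per target: `channels` (list column of
#'   sorted channel indices), `spectral_g`, `spectral_s`, `lifetime_g`,
#'   `lifetime_s`.
#' @export
expected_signatures <- function(codebook, rep_frequency_hz = 78e6, harmonic = 1L) {
  stopifnot(inherits(codebook, "flim_codebook"))
  panel <- codebook$panel
  nchan <- attr(panel, "n_channels")
  ang <- spectral_angles(nchan, harmonic)
  life <- lifetime_phasor_position(panel$lifetime_ns, rep_frequency_hz, harmonic)

  one <- function(target) {
    fl <- codeword_fluors(codebook, target)
    i <- match(fl, panel$name)
    ch <- sort(unique(panel$channel[i]))
    # equal-photon mixture: mean of the member dyes' positions
    tibble::tibble(
      target = target,
      channels = list(ch),
      spectral_g = mean(cos(ang[panel$channel[i]])),
      spectral_s = mean(sin(ang[panel$channel[i]])),
      lifetime_g = mean(life$g[i]),
      lifetime_s = mean(life$s[i])
    )
  }
  dplyr::bind_rows(lapply(codebook$codewords$target, one))
}

#' Read or write a codebook as YAML
#'
#' The on-disk format stores the fluorophore table, the per-target codewords
#' and the negative controls; `read_codebook(write_codebook(x, f))`
#' round-trips exactly.
#'
#' @param codebook a `flim_codebook`.
#' @param path file path.
#'
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   a `flim_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "flim_codebook"))
  panel <- codebook$panel
  obj <- list(
    n_channels = attr(panel, "n_channels"),
    fluorophores = lapply(seq_len(nrow(panel)), function(i) {
      as.list(panel[i, ])
    }),
    codewords = stats::setNames(
      lapply(codebook$codewords$target, function(tg) {
        as.list(codeword_fluors(codebook, tg))
      }),
      codebook$codewords$target
    ),
    negative_controls = as.list(codebook$negative_controls)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- yaml::read_yaml(path)
  fl <- dplyr::bind_rows(lapply(obj$fluorophores, tibble::as_tibble))
  panel <- fluorophore_panel(
    fl$name, fl$emission_center_nm, fl$emission_sigma_nm,
    fl$lifetime_ns, fl$channel,
    n_channels = obj$n_channels
  )
  cws <- lapply(obj$codewords, unlist)
  build_codebook(
    panel, names(cws),
    codewords = cws,
    negative_controls = unlist(obj$negative_controls) %||% character(),
    allow_singletons = TRUE
  )
}
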