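#' Write and read photon stacks as multi-page TIFF with a sidecar config
#'
#' The 5-D count array is written as 32-bit float TIFF pages in
#' time-within-channel-within-z order, with a YAML sidecar (`<path>.yaml`)
#' declaring the axis layout, dimensions, voxel size, repetition frequency
#' and channel edges. Counts round-trip bit-exactly. Reading requires the
#' sidecar (or an explicit `layout` list with the same fields): TIFF tags
#' alone do not carry the acquisition metadata.
#'
#' @param stack a [photon_stack()].
#' @param path TIFF file path.
#' @param layout optional metadata list overriding the sidecar.
#'
#' @return `write_photon_stack` returns `path` invisibly; `read_photon_stack`
#'   returns a [photon_stack()].
#' @export
write_photon_stack <- function(stack, path) {
  stopifnot(inherits(stack, "photon_stack"))
  d <- dim(stack$counts)
  scale <- max(stack$counts, 1)
  pages <- vector("list", d[1] * d[4] * d[5])
  i <- 0L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      for (tb in seq_len(d[5])) {
        i <- i + 1L
        pages[[i]] <- stack$counts[z, , , ch, tb] / scale
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(
      axes = "z,channel,time_bin pages of (y,x)",
      dim = as.integer(d),
      scale = scale,
      voxel_um = stack$voxel_um,
      rep_frequency_hz = stack$rep_frequency_hz,
      channel_edges_nm = stack$channel_edges_nm
    ),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_photon_stack
#' @export
read_photon_stack <- function(path, layout = NULL) {
  sidecar <- paste0(path, ".yaml")
  if (is.null(layout)) {
    if (!file.exists(sidecar)) {
      stop("metadata required: no sidecar config at ", sidecar,
           " and no explicit layout given")
    }
    layout <- yaml::read_yaml(sidecar)
  }
  d <- as.integer(unlist(layout$dim))
  if (length(d) != 5L) stop("layout must declare 5 dimensions (z,y,x,channel,time_bin)")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != d[1] * d[4] * d[5]) {
    stop(sprintf("layout mismatch: expected %d pages (z*channel*time), found %d",
                 d[1] * d[4] * d[5], length(pages)))
  }
  counts <- array(0, d)
  i <- 0L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      for (tb in seq_len(d[5])) {
        i <- i + 1L
        counts[z, , , ch, tb] <- pages[[i]] * layout$scale
      }
    }
  }
  counts <- round(counts)
  photon_stack(counts, unlist(layout$voxel_um), layout$rep_frequency_hz,
               unlist(layout$channel_edges_nm))
}

#' Write a phasor field as float TIFF planes
#'
#' Four phasor planes per z-slice (spectral G, S; lifetime G, S, with invalid
#' voxels as 0) plus a separate intensity TIFF.
#'
#' @param field a [phasor_transform()] result.
#' @param path base path; writes `<path>_phasor.tif` and
#'   `<path>_intensity.tif`.
#'
#' @return Invisibly, the two paths.
#' @export
write_phasor_field <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  d <- dim(field$intensity)
  planes <- list()
  clean <- function(a) { a[is.na(a)] <- 0; (a + 1) / 2 } # map [-1,1] to [0,1]
  for (z in seq_len(d[1])) {
    planes <- c(planes, list(
      clean(field$spectral_g[z, , ]), clean(field$spectral_s[z, , ]),
      clean(field$lifetime_g[z, , ]), clean(field$lifetime_s[z, , ])
    ))
  }
  p1 <- paste0(path, "_phasor.tif")
  p2 <- paste0(path, "_intensity.tif")
  tiff::writeTIFF(planes, p1, bits.per.sample = 32L, reduce = FALSE)
  mx <- max(field$intensity, 1)
  ipl <- lapply(seq_len(d[1]), function(z) field$intensity[z, , ] / mx)
  tiff::writeTIFF(ipl, p2, bits.per.sample = 32L, reduce = FALSE)
  invisible(c(p1, p2))
}

#' Run the end-to-end pipeline and write its outputs
#'
#' Loads (or simulates) a photon stack, runs detection, phasor
#' classification and decoding, and writes the puncta table (CSV), the
#' summary (JSON, including the seed and a config hash so a rerun is
#' reproducible), the phasor/intensity TIFFs and, when a nuclear stack is
#' given, per-cell counts (CSV). Stage-level counts are logged via
#' `message()` so conservation is auditable.
#'
#' @param stack a [photon_stack()], or a TIFF path readable by
#'   [read_photon_stack()].
#' @param codebook a [build_codebook()] or a YAML path for [read_codebook()].
#' @param out_dir output directory (created if needed).
#' @param nuclear_stack optional 3-D array for cell segmentation.
#' @param seed seed passed to the classifier.
#' @param min_nucleus_volume_um3 debris-rejection threshold for
#'   [segment_nuclei()].
#' @param ... further arguments to [classify_stack()].
#'
#' @return The [classify_stack()] result, invisibly, with `outputs` listing
#'   the files written.
#' @export
run_pipeline <- function(stack, codebook, out_dir, nuclear_stack = NULL,
                         seed = 1L, min_nucleus_volume_um3 = 30, ...) {
  if (is.character(stack)) stack <- read_photon_stack(stack)
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("pipeline: classifying stack of ",
          paste(dim(stack$counts), collapse = "x"))
  res <- classify_stack(stack, codebook, seed = seed, ...)
  message("pipeline: ", nrow(res$puncta), " puncta detected")

  puncta_csv <- file.path(out_dir, "puncta.csv")
  flat <- res$puncta
  flat$channels <- vapply(flat$channels, paste, character(1), collapse = "+")
  utils::write.csv(flat, puncta_csv, row.names = FALSE)

  outputs <- c(puncta_csv)
  if (!is.null(nuclear_stack)) {
    nuclei <- segment_nuclei(nuclear_stack, stack$voxel_um,
                             min_volume_um3 = min_nucleus_volume_um3)
    if (any(nuclei > 0)) {
      terr <- grow_territories(nuclei, stack$voxel_um)
      cells <- assign_puncta_to_cells(res$puncta, terr, stack$voxel_um)
      cells_csv <- file.path(out_dir, "cells.csv")
      utils::write.csv(cells, cells_csv, row.names = FALSE)
      outputs <- c(outputs, cells_csv)
      message("pipeline: ", max(nuclei), " cells segmented")
    }
  }

  cfg_hash <- rlang::hash(list(dim(stack$counts), codebook$codewords, seed))
  summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(
      seed = seed,
      config_hash = cfg_hash,
      total = nrow(res$puncta),
      categories = stats::setNames(
        as.list(res$summary$count[1:3]),
        res$summary$group[1:3]
      ),
      per_target = {
        tg <- res$summary[res$summary$group == "target", ]
        stats::setNames(as.list(tg$count), tg$target)
      }
    ),
    summary_json, auto_unbox = TRUE, pretty = TRUE
  )
  outputs <- c(outputs, summary_json)

  write_phasor_field(res$field, file.path(out_dir, "stack"))
  outputs <- c(outputs, file.path(out_dir, c("stack_phasor.tif", "stack_intensity.tif")))

  res$outputs <- outputs
  invisible(res)
}
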