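#' Segment nuclei from a nuclear-stain stack
#'
#' Thresholds the photon-count histogram by a two-class hard split (Otsu's
#' criterion via [EBImage::otsu()]), labels 3-D connected components (26-
#' connectivity) and discards components smaller than a minimum nucleus
#' volume (debris rejection).
#'
#' @param stack 3-D array `(z, y, x)` of nuclear-stain counts.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param min_volume_um3 minimum nucleus volume, default 30 um^3.
#'
#' @return An integer label array (0 = background, 1..n = nuclei).
#' @export
segment_nuclei <- function(stack, voxel_um, min_volume_um3 = 30) {
  stopifnot(length(dim(stack)) == 3L)
  mx <- max(stack)
  if (mx <= 0) return(array(0L, dim(stack)))
  # flatten to a single frame: one global histogram split, not per-slice
  flat <- EBImage::Image(matrix(stack / mx, nrow = dim(stack)[1]))
  thr <- EBImage::otsu(flat, range = c(0, 1)) * mx
  mask <- stack > thr
  lab <- label_components3_cpp(mask, dim(stack), 26L)
  vox_vol <- prod(voxel_um)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * vox_vol >= min_volume_um3)
  out <- array(0L, dim(stack))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# surface voxels of each label: labelled voxels with >= 1 differing neighbour
surface_voxels <- function(labels) {
  d <- dim(labels)
  offs <- neighbour_offsets()
  surf <- array(FALSE, d)
  for (i in seq_len(nrow(offs))) {
    nb <- shift3(labels, offs$dz[i], offs$dy[i], offs$dx[i], fill = 0)
    surf <- surf | (labels > 0 & nb != labels)
  }
  idx <- which(surf)
  pos <- arrayInd(idx, d)
  lapply(split(seq_along(idx), labels[idx]), function(r) pos[r, , drop = FALSE])
}

#' Grow cell territories from segmented nuclei
#'
#' Simultaneous iterative dilation of all nucleus labels by a minimal
#' 3x3x3 kernel into unlabelled space until the volume is fully tiled — a
#' Voronoi-like tessellation seeded by the nucleus surfaces rather than
#' points, so each territory face bisects the gap between the two closest
#' nucleus edges. Voxels reached by several labels in the same iteration go
#' to the label whose nucleus surface is nearest in physical distance; exact
#' ties go to the lower cell id.
#'
#' After growth, a bounded number of boundary-refinement passes re-evaluate
#' voxels sitting on a territory interface with the same nearest-surface
#' criterion: the discrete 3x3x3 wavefront advances in chessboard rather than
#' Euclidean distance, and the refinement corrects the voxel-scale bias this
#' leaves along oblique interfaces.
#'
#' @param nucleus_labels integer label array from [segment_nuclei()].
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#' @param refine boundary-refinement passes after growth, default 3.
#'
#' @return An integer territory label array tiling the whole volume.
#' @export
grow_territories <- function(nucleus_labels, voxel_um, refine = 3L) {
  d <- dim(nucleus_labels)
  lab <- nucleus_labels
  if (all(lab == 0)) stop("no nuclei to grow from")
  offs <- neighbour_offsets()
  scale <- c(voxel_um[3], voxel_um[2], voxel_um[1]) # (z, y, x) axes
  surf <- surface_voxels(nucleus_labels)

  nearest_label <- function(vox, cand) {
    dmin <- vapply(cand, function(l) {
      s <- surf[[as.character(l)]]
      if (is.null(s)) return(Inf)
      min(colSums(((t(s) - vox) * scale)^2))
    }, numeric(1))
    cand[order(dmin, cand)][1]
  }

  repeat {
    if (!any(lab == 0)) break
    lab0 <- lab # label state at the start of this (simultaneous) iteration
    first <- array(0L, d)
    conflict <- array(FALSE, d)
    for (i in seq_len(nrow(offs))) {
      nb <- shift3(lab0, offs$dz[i], offs$dy[i], offs$dx[i], fill = 0L)
      new <- lab0 == 0 & nb > 0
      conflict <- conflict | (new & first > 0 & first != nb)
      first[new & first == 0] <- nb[new & first == 0]
    }
    frontier <- which(lab0 == 0 & first > 0)
    if (length(frontier) == 0) break
    plain <- frontier[!conflict[frontier]]
    lab[plain] <- first[plain]
    contested <- frontier[conflict[frontier]]
    if (length(contested) > 0) {
      pos <- arrayInd(contested, d)
      for (r in seq_along(contested)) {
        vox <- pos[r, ]
        cand <- integer(0)
        for (i in seq_len(nrow(offs))) {
          zz <- vox[1] + offs$dz[i]; yy <- vox[2] + offs$dy[i]; xx <- vox[3] + offs$dx[i]
          if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] &&
              xx >= 1 && xx <= d[3] && lab0[zz, yy, xx] > 0) {
            cand <- c(cand, lab0[zz, yy, xx])
          }
        }
        cand <- sort(unique(cand))
        lab[contested[r]] <- nearest_label(vox, cand)
      }
    }
  }

  for (pass in seq_len(refine)) {
    # voxels on an interface: some neighbour carries a different label
    iface <- array(FALSE, d)
    for (i in seq_len(nrow(offs))) {
      nb <- shift3(lab, offs$dz[i], offs$dy[i], offs$dx[i], fill = 0L)
      iface <- iface | (nb > 0 & nb != lab)
    }
    iface <- iface & nucleus_labels == 0 # never reassign nucleus voxels
    vx_list <- which(iface)
    if (length(vx_list) == 0) break
    pos <- arrayInd(vx_list, d)
    changed <- FALSE
    for (r in seq_along(vx_list)) {
      vox <- pos[r, ]
      cand <- lab[vox[1], vox[2], vox[3]]
      for (i in seq_len(nrow(offs))) {
        zz <- vox[1] + offs$dz[i]; yy <- vox[2] + offs$dy[i]; xx <- vox[3] + offs$dx[i]
        if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3]) {
          cand <- c(cand, lab[zz, yy, xx])
        }
      }
      best <- nearest_label(vox, sort(unique(cand[cand > 0])))
      if (best != lab[vx_list[r]]) {
        lab[vx_list[r]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Assign decoded puncta to cell territories
#'
#' Each assigned punctum increments the count of its target in the territory
#' containing its centroid voxel; undetermined and overlapping puncta are
#' tallied separately per cell. Centroids falling on unlabelled voxels (no
#' nuclei nearby) land in cell 0, the unassigned bucket.
#'
#' @param decoded a [decode_puncta()] tibble (with `z`, `y`, `x`, `label`).
#' @param territories label array from [grow_territories()].
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#'
#' @return A tibble `(cell, target, count)` where `target` includes the
#'   special categories `undetermined` and `overlapping`, plus a
#'   `territory_volume_um3` column.
#' @export
assign_puncta_to_cells <- function(decoded, territories, voxel_um) {
  d <- dim(territories)
  vol <- tibble::tibble(
    cell = as.integer(names(table(territories))),
    territory_volume_um3 = as.numeric(table(territories)) * prod(voxel_um)
  )
  if (nrow(decoded) == 0) {
    return(dplyr::mutate(vol, target = NA_character_, count = 0L)[, c("cell", "target", "count", "territory_volume_um3")])
  }
  lin <- decoded$z + d[1] * (decoded$y - 1) + d[1] * d[2] * (decoded$x - 1)
  out <- tibble::tibble(cell = as.integer(territories[lin]), target = decoded$label)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$cell, .data$target),
    count = dplyr::n(), .groups = "drop"
  )
  dplyr::left_join(out, vol, by = "cell")
}

#' Volume-normalised mean counts per cell
#'
#' Total detected counts divided by the total imaged cellular volume and
#' multiplied by a nominal mean cell volume; used when the imaged slab is
#' thinner than a cell so per-territory counts would under-count.
#'
#' @param counts total counts (vectorised, e.g. one per target).
#' @param total_cellular_volume_um3 total imaged cellular volume in um^3.
#' @param mean_cell_volume_um3 nominal mean cell volume, default 3000 um^3.
#'
#' @return Normalised counts per cell.
#' @export
#'
#' @examples
#' mean_counts_per_cell(13500, 68000) # ~595.6 per cell
mean_counts_per_cell <- function(counts, total_cellular_volume_um3,
                                 mean_cell_volume_um3 = 3000) {
  if (total_cellular_volume_um3 <= 0) stop("total cellular volume must be > 0")
  counts / total_cellular_volume_um3 * mean_cell_volume_um3
}

#' Total cellular volume by intensity thresholding
#'
#' Counts voxels whose signal (typically dim cellular autofluorescence,
#' which distinguishes cells from the empty gaps between them) exceeds a
#' threshold, times the voxel volume.
#'
#' @param stack 3-D array of intensities.
#' @param threshold intensity threshold.
#' @param voxel_um voxel size `(dx, dy, dz)` in micrometres.
#'
#' @return Volume in um^3.
#' @export
estimate_cellular_volume <- function(stack, threshold, voxel_um) {
  sum(stack > threshold) * prod(voxel_um)
}

#' Correlate per-target counts with reference expression
#'
#' Pearson correlation between imaging-derived counts and an external
#' reference (e.g. normalised bulk RNA-seq counts), with the paired data
#' retained for plotting.
#'
#' @param counts named numeric vector or tibble column of per-target counts.
#' @param reference reference expression values, same order/length.
#'
#' @return A tibble with `r` and `n`; the paired values are attached as the
#'   `"data"` attribute (used by [autoplot_correlation()]).
#' @export
correlate_with_reference <- function(counts, reference) {
  stopifnot(length(counts) == length(reference), length(counts) >= 3)
  if (sd(counts) == 0 || sd(reference) == 0) {
    warning("zero variance; correlation undefined")
    r <- NA_real_
  } else {
    r <- cor(counts, reference)
  }
  out <- tibble::tibble(r = r, n = length(counts))
  attr(out, "data") <- tibble::tibble(
    target = names(counts) %||% as.character(seq_along(counts)),
    count = as.numeric(counts), reference = as.numeric(reference)
  )
  out
}
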