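# Binarization and compartment masks. Thresholds are chosen per slice and per
# channel from the intensities found at image edges: edges sit on the
# foreground/background transition, so the median intensity over edge pixels
# is a robust cut between the two populations.

#' Edge-intensity-based threshold for one slice
#'
#' Detects edge pixels as those whose Sobel gradient magnitude exceeds its own
#' Otsu cut, and returns the median original intensity over those edge pixels.
#' If no edge pixels are found the Otsu threshold of the whole slice is used
#' instead. A constant slice returns `max + 1` (an empty-mask sentinel) with a
#' warning.
#'
#' @param slice_image 2-D numeric intensity matrix.
#' @return A single threshold intensity; voxels strictly above it are
#'   foreground.
#' @export
edge_based_threshold <- function(slice_image) {
  if (length(slice_image) < 1L) stop("slice has no pixels", call. = FALSE)
  r <- range(slice_image)
  if (r[1] == r[2]) {
    warning("constant slice: returning empty-mask sentinel threshold")
    return(r[2] + 1)
  }
  g <- sobel_magnitude(slice_image)
  cut <- otsu_threshold(as.numeric(g))
  edge <- g > cut
  if (!any(edge)) return(otsu_threshold(as.numeric(slice_image)))
  stats::median(slice_image[edge])
}

# Sobel gradient magnitude with replicated borders.
sobel_magnitude <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  pad <- m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  sh <- function(dy, dx) pad[seq_len(ny) + 1L + dy, seq_len(nx) + 1L + dx]
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  sqrt(gy^2 + gx^2)
}

#' Binarize one channel of a stack with per-slice edge-based thresholds
#'
#' Each slice gets its own threshold: the median original intensity over its
#' edge pixels. The gradient-magnitude cut that defines "edge pixels" is,
#' however, pooled over all slices of the channel (one Otsu cut on the
#' stack's gradient magnitudes): fluorescence signal is sparse along z, and a
#' slice containing no labelled structure has only weak texture gradients,
#' all below the pooled cut, so it correctly yields an empty mask instead of
#' thresholding background texture.
#'
#' @param stack an [image_stack()] (smoothing with [smooth_stack()] first is
#'   recommended).
#' @param channel channel role or index.
#' @return A list with `mask` (3-D logical array, `(z, y, x)`) and
#'   `thresholds` (one per slice; a slice with no edge pixels gets the
#'   empty-mask sentinel `max intensity + 1`).
#' @export
binarize_stack <- function(stack, channel) {
  vol <- channel_volume(stack, channel)
  nz <- dim(vol)[1]
  thr <- numeric(nz)
  mask <- array(FALSE, dim = dim(vol))
  grads <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- vol[z, , ]
    dim(sl) <- dim(vol)[2:3]
    grads[[z]] <- sobel_magnitude(sl)
  }
  gp <- as.numeric(unlist(grads))
  # real structure edges occupy a tiny pixel fraction, where Otsu alone can
  # land inside the background-texture gradient mode; the mean + 4 sd floor
  # keeps light-tailed texture gradients out of the edge set
  cut <- max(otsu_threshold(gp), mean(gp) + 4 * sd(gp))
  # stack-level background ceiling: a slice threshold may never fall into
  # the background intensity distribution, whatever its edge pixels say
  # (median + 3 MAD on a deterministic stride subsample; background voxels
  # dominate fluorescence stacks, so the median/MAD track the background)
  sub <- vol[seq(1L, length(vol), by = max(1L, length(vol) %/% 200000L))]
  med <- stats::median(sub)
  floor_thr <- med + 3 * 1.4826 * stats::median(abs(sub - med))
  for (z in seq_len(nz)) {
    sl <- vol[z, , ]
    dim(sl) <- dim(vol)[2:3]
    edge <- grads[[z]] > cut
    thr[z] <- if (any(edge)) {
      max(stats::median(sl[edge]), floor_thr)
    } else {
      max(sl) + 1  # no labelled structure in this slice
    }
    mask[z, , ] <- sl > thr[z]
  }
  list(mask = mask, thresholds = thr)
}

#' Refine a binary 3-D mask
#'
#' Removes 26-connected foreground components below a physical volume cut-off,
#' fills background cavities fully enclosed in 3D (6-connected background),
#' then closes remaining gaps by morphological closing with a 1-voxel-radius
#' structuring element.
#'
#' @param mask 3-D logical array.
#' @param min_cluster_volume_um3 minimum component volume to keep, default 5.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return Refined 3-D logical array.
#' @export
refine_mask <- function(mask, min_cluster_volume_um3 = 5, voxel_size) {
  vox_vol <- prod(voxel_size)
  lab <- cc3(mask, 26L)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes * vox_vol >= min_cluster_volume_um3
    mask <- array(lab > 0L & keep[pmax(lab, 1L)], dim = dim(mask))
  }
  mask <- fill3(mask)
  erode3(dilate3(mask))
}

#' Derive nucleus / soma / branch compartments
#'
#' The soma is reconstructed by a geodesic opening at the core thickness:
#' voxels whose distance to the cell surface is at least
#' `soma_core_distance_um` form the core; core components are kept when they
#' overlap a nucleus, dilated back by the same physical distance (exact
#' anisotropic dilation, clipped to the cell mask) so the eroded soma rind is
#' restored while thin processes stay out, and finally conditionally dilated
#' until the overlapping nucleus is covered. Branches are the exact set
#' complement `cell & !soma`. Nucleus components with no overlapping cell
#' voxel, or with no soma core, are discarded and recorded.
#'
#' @param cell_mask 3-D logical array from the membrane channel.
#' @param nucleus_raw refined 3-D logical array from the nuclear channel.
#' @param distance_map `distance_map` object (or plain array) for `cell_mask`.
#' @param soma_core_distance_um core thickness cut-off, default 1.2.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return An object of class `segmentation_masks`: `cell_mask`,
#'   `nucleus_mask`, `soma_mask`, `branch_mask`, `dropped_nuclei` (tibble of
#'   discarded nucleus components with reasons).
#' @export
derive_compartments <- function(cell_mask, nucleus_raw, distance_map,
                                soma_core_distance_um = 1.2, voxel_size) {
  dvals <- if (inherits(distance_map, "distance_map")) {
    distance_map$values
  } else {
    distance_map
  }
  stopifnot(identical(dim(cell_mask), dim(nucleus_raw)),
            identical(dim(cell_mask), dim(dvals)))
  cell_context <- dilate3(cell_mask)
  core <- dvals >= soma_core_distance_um
  core_lab <- cc3(core, 26L)
  nuc_lab <- cc3(nucleus_raw, 26L)
  n_nuc <- max(nuc_lab)
  dropped <- tibble::tibble(nucleus_component = integer(), reason = character())
  keep_core <- logical(max(core_lab, 1L))
  keep_nuc <- logical(max(n_nuc, 1L))
  if (n_nuc > 0L) {
    for (k in seq_len(n_nuc)) {
      nk <- nuc_lab == k & cell_context
      if (!any(cell_mask[nk])) {
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          nucleus_component = k, reason = "no_cell_overlap"))
        next
      }
      cl <- unique(core_lab[nk & core])
      cl <- cl[cl > 0L]
      if (length(cl) == 0L) {
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          nucleus_component = k, reason = "no_soma_core"))
        next
      }
      keep_core[cl] <- TRUE
      keep_nuc[k] <- TRUE
    }
  }
  nucleus_mask <- array(nuc_lab > 0L & keep_nuc[pmax(nuc_lab, 1L)],
                        dim = dim(nucleus_raw)) & cell_context
  soma <- array(core_lab > 0L & keep_core[pmax(core_lab, 1L)],
                dim = dim(cell_mask))
  if (any(soma)) {
    # restore the rind eroded by the core cut: exact anisotropic dilation of
    # the kept core by soma_core_distance_um, clipped to the cell
    reach <- edt3(!soma, voxel_size)
    soma <- (soma | (reach <= soma_core_distance_um)) & cell_mask
  }
  # conditional dilation inside the cell mask until the kept nuclei (within
  # the cell) are covered; bounded to keep degenerate geometry finite
  target <- nucleus_mask & cell_mask
  for (it in seq_len(50L)) {
    if (all(soma[target])) break
    grown <- dilate3(soma) & cell_mask
    if (identical(grown, soma)) break
    soma <- grown
  }
  soma <- soma | target  # guarantee somata contain their nuclei
  masks <- structure(
    list(cell_mask = cell_mask,
         nucleus_mask = nucleus_mask,
         soma_mask = soma,
         branch_mask = cell_mask & !soma,
         dropped_nuclei = dropped),
    class = "segmentation_masks")
  stopifnot(!any(masks$soma_mask & !masks$cell_mask),
            !any(masks$nucleus_mask & masks$cell_mask & !masks$soma_mask))
  masks
}

#' Segment a stack into nested compartment masks
#'
#' Convenience wrapper running [binarize_stack()] on both channels,
#' [refine_mask()] on each, a [distance_map()], and [derive_compartments()].
#'
#' @param stack a smoothed [image_stack()].
#' @param min_cluster_volume_um3 passed to [refine_mask()] (cell mask);
#'   the nucleus mask uses a quarter of it.
#' @param soma_core_distance_um passed to [derive_compartments()].
#' @return A list with `masks` (class `segmentation_masks`), `dmap`,
#'   and `per_slice_thresholds` (tibble: channel, z, threshold).
#' @export
segment_stack <- function(stack, min_cluster_volume_um3 = 5,
                          soma_core_distance_um = 1.2) {
  vs <- stack$voxel_size
  bc <- binarize_stack(stack, "membrane_marker")
  bn <- binarize_stack(stack, "nuclear_stain")
  cell <- refine_mask(bc$mask, min_cluster_volume_um3, vs)
  nuc <- refine_mask(bn$mask, min_cluster_volume_um3 / 4, vs)
  dmap <- distance_map(cell, vs)
  masks <- derive_compartments(cell, nuc, dmap, soma_core_distance_um, vs)
  thr <- dplyr::bind_rows(
    tibble::tibble(channel = "membrane_marker",
                   z = seq_along(bc$thresholds) - 1L,
                   threshold = bc$thresholds),
    tibble::tibble(channel = "nuclear_stain",
                   z = seq_along(bn$thresholds) - 1L,
                   threshold = bn$thresholds))
  list(masks = masks, dmap = dmap, per_slice_thresholds = thr)
}

#' Export compartment masks as an 8-bit label TIFF volume
#'
#' Encoding: 0 background, 1 branch, 2 soma, 3 nucleus (nucleus drawn on top
#' of soma).
#'
#' @param masks a `segmentation_masks` object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  lab <- array(0L, dim = dim(masks$cell_mask))
  lab[masks$branch_mask] <- 1L
  lab[masks$soma_mask] <- 2L
  lab[masks$nucleus_mask & masks$cell_mask] <- 3L
  nz <- dim(lab)[1]
  pages <- lapply(seq_len(nz), function(z) {
    m <- lab[z, , ]
    dim(m) <- dim(lab)[2:3]
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
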