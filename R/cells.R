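# Segregation of the stack-wide skeleton into single cells (one per soma) by
# shortest paths, the exclusion rules, and backtracing from result rows to
# stack coordinates.

#' Pick the soma centre node for each soma
#'
#' Somata are the connected components of the soma mask; the centre node of a
#' soma is the skeleton node whose watershed segment contains the soma's
#' highest distance-map voxel (the thickest point).
#'
#' @param graph a `skeleton_graph`.
#' @param masks a `segmentation_masks` object.
#' @param dmap the [distance_map()] of the cell mask.
#' @return Tibble: `soma_id`, `center_node`, `has_nucleus`.
#' @export
soma_center_nodes <- function(graph, masks, dmap) {
  sl <- cc3(masks$soma_mask, 26L)
  k <- max(sl)
  if (k == 0L) {
    return(tibble::tibble(soma_id = integer(), center_node = integer(),
                          has_nucleus = logical()))
  }
  st <- .label_stats(as.integer(sl), vol_dim(sl), logical(0),
                     as.logical(masks$nucleus_mask & masks$cell_mask),
                     as.numeric(dmap$values))
  center <- integer(k)
  for (i in seq_len(k)) {
    center[i] <- graph$label_volume[st$d_argmax[i] + 1L]
  }
  tibble::tibble(soma_id = seq_len(k),
                 center_node = center,
                 has_nucleus = st$n_nucleus > 0)
}

#' Segregate the skeleton into cells by shortest paths
#'
#' Every node's edge-length-weighted shortest-path distance to each soma
#' centre node is computed; the node joins the nearest soma's cell.
#' Equidistant nodes go to the soma with the smaller canonical id. Nodes
#' unreachable from any soma stay unassigned (recorded in the
#' `unassigned_nodes` attribute).
#'
#' @param graph a `skeleton_graph`.
#' @param soma_centers tibble from [soma_center_nodes()] (or an integer vector
#'   of centre node ids).
#' @return A tibble of cells (class `cell_table`): `cell_id`,
#'   `soma_node_id`, `has_nucleus`, and a list-column `node_ids`.
#' @export
segregate_cells <- function(graph, soma_centers) {
  if (is.numeric(soma_centers)) {
    soma_centers <- tibble::tibble(soma_id = seq_along(soma_centers),
                                   center_node = as.integer(soma_centers),
                                   has_nucleus = TRUE)
  }
  if (nrow(soma_centers) == 0L) {
    warning("no soma found: returning empty cell table")
    out <- tibble::tibble(cell_id = integer(), soma_node_id = integer(),
                          has_nucleus = logical(), node_ids = list())
    class(out) <- c("cell_table", class(out))
    return(out)
  }
  soma_centers <- soma_centers[order(soma_centers$center_node), ]
  gi <- as_igraph(graph)
  dmat <- igraph::distances(
    gi, v = as.character(soma_centers$center_node),
    weights = igraph::E(gi)$weight)
  dmat <- dmat[, as.character(graph$nodes$id), drop = FALSE]
  reachable <- apply(dmat, 2, function(col) any(is.finite(col)))
  # which.min returns the first (lowest soma index = smallest canonical
  # centre id) among ties
  owner <- apply(dmat, 2, which.min)
  owner[!reachable] <- NA_integer_
  cells <- lapply(seq_len(nrow(soma_centers)), function(i) {
    tibble::tibble(
      cell_id = i,
      soma_node_id = soma_centers$center_node[i],
      has_nucleus = soma_centers$has_nucleus[i],
      node_ids = list(graph$nodes$id[!is.na(owner) & owner == i]))
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "unassigned_nodes") <- graph$nodes$id[is.na(owner)]
  class(out) <- c("cell_table", class(out))
  out
}

#' Apply the cell exclusion rules
#'
#' Border rule: a cell is excluded when its voxel territory touches a stack
#' border and the centroid of its soma lies closer than the margin to that
#' same border (15 um for X/Y borders, 8 um for Z borders). Proximity rule:
#' two cells whose skeletons were connected before segregation and whose soma
#' centroids lie closer than `soma_min_separation_um` are both excluded.
#' Cells whose soma has no overlapping nucleus are excluded as likely
#' false positives (toggleable). Nothing is deleted - cells are flagged with
#' an `exclusion_reason` of `none`, `border_proximity`, `soma_too_close`, or
#' `no_nucleus`.
#'
#' @param cells a `cell_table` from [segregate_cells()].
#' @param graph the `skeleton_graph` the cells came from.
#' @param margin_xy_um,margin_z_um border margins, defaults 15 and 8.
#' @param soma_min_separation_um default 15.
#' @param require_nucleus exclude no-nucleus cells, default TRUE.
#' @return The cell table with `soma_centroid` columns (um), `included`, and
#'   `exclusion_reason` filled in.
#' @export
apply_exclusion_rules <- function(cells, graph, margin_xy_um = 15,
                                  margin_z_um = 8,
                                  soma_min_separation_um = 15,
                                  require_nucleus = TRUE) {
  n <- graph$nodes
  dims <- dim(graph$label_volume)
  vs <- graph$voxel_size
  extent <- (dims - 1) * vs  # centre-to-centre physical extent (z, y, x)
  k <- nrow(cells)
  sz <- sy <- sx <- rep(NA_real_, k)
  touches <- matrix(FALSE, k, 6,
                    dimnames = list(NULL, colnames(graph$touches)))
  for (i in seq_len(k)) {
    ids <- cells$node_ids[[i]]
    soma_ids <- ids[n$compartment[ids] == "soma"]
    if (length(soma_ids) == 0L) soma_ids <- cells$soma_node_id[i]
    w <- n$n_soma_vox[soma_ids]
    if (sum(w) == 0) w <- n$n_vox[soma_ids]
    sz[i] <- sum(n$z_um[soma_ids] * w) / sum(w)
    sy[i] <- sum(n$y_um[soma_ids] * w) / sum(w)
    sx[i] <- sum(n$x_um[soma_ids] * w) / sum(w)
    touches[i, ] <- apply(graph$touches[ids, , drop = FALSE], 2, any)
  }
  # distance of the soma centroid to each of the six borders
  border_dist <- cbind(
    z_lo = sz, z_hi = extent[1] - sz,
    y_lo = sy, y_hi = extent[2] - sy,
    x_lo = sx, x_hi = extent[3] - sx)
  margin <- c(z_lo = margin_z_um, z_hi = margin_z_um,
              y_lo = margin_xy_um, y_hi = margin_xy_um,
              x_lo = margin_xy_um, x_hi = margin_xy_um)
  reason <- rep("none", k)
  for (i in seq_len(k)) {
    viol <- touches[i, ] & border_dist[i, colnames(touches)] <
      margin[colnames(touches)]
    if (any(viol)) reason[i] <- "border_proximity"
  }
  # proximity rule: only cells connected before segregation
  gi <- as_igraph(graph)
  comp <- igraph::components(gi)$membership
  cell_comp <- comp[as.character(cells$soma_node_id)]
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (cell_comp[i] != cell_comp[j]) next
        d <- sqrt((sz[i] - sz[j])^2 + (sy[i] - sy[j])^2 + (sx[i] - sx[j])^2)
        if (d < soma_min_separation_um) {
          reason[i] <- ifelse(reason[i] == "none", "soma_too_close", reason[i])
          reason[j] <- ifelse(reason[j] == "none", "soma_too_close", reason[j])
        }
      }
    }
  }
  if (require_nucleus) {
    reason[reason == "none" & !cells$has_nucleus] <- "no_nucleus"
  }
  cells$soma_centroid_z_um <- sz
  cells$soma_centroid_y_um <- sy
  cells$soma_centroid_x_um <- sx
  cells$included <- reason == "none"
  cells$exclusion_reason <- reason
  cells
}

#' Volume and surface area of a cell territory
#'
#' Volume is the voxel count times the physical voxel volume. Surface area is
#' measured on a triangulated isosurface of the binary territory: the
#' territory is padded, lightly Gaussian-smoothed (sigma = 1 voxel, which
#' removes the voxelization staircase), and triangulated by marching
#' tetrahedra at level 0.5 with anisotropic vertex placement.
#'
#' @param territory 3-D logical array (a single cell's voxels), or a
#'   `cell_table` row's node ids together with `label_volume`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return A list with `volume_um3` and `surface_area_um2`.
#' @export
extract_cell_geometry <- function(territory, voxel_size) {
  if (!any(territory)) stop("territory is empty", call. = FALSE)
  v <- sum(territory) * prod(voxel_size)
  idx <- which(territory, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 3L, 1L)
  hi <- pmin(apply(idx, 2, max) + 3L, dim(territory))
  crop <- territory[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  pad <- array(0, dim = dim(crop) + 4L)
  pad[3:(dim(crop)[1] + 2L), 3:(dim(crop)[2] + 2L), 3:(dim(crop)[3] + 2L)] <-
    crop * 1.0
  sm <- gauss3(pad, c(1, 1, 1))
  a <- .mt_surface_area(as.numeric(sm), vol_dim(sm), as.numeric(voxel_size),
                        0.5)
  list(volume_um3 = v, surface_area_um2 = a)
}

# Territory mask of one cell from the graph label volume.
cell_territory <- function(graph, node_ids) {
  array(graph$label_volume %in% node_ids, dim = dim(graph$label_volume))
}

#' Backtrace a result row to its stack coordinates
#'
#' Returns, for one cell of a pipeline result, the provenance needed to find
#' it in the source stack: file, retained slice range, soma centroid in both
#' voxel (0-based, z/y/x) and physical coordinates, the territory bounding
#' box, and a cropped label volume for visual inspection.
#'
#' @param result a `stack_result` from [process_stack()] / [run_pipeline()].
#' @param cell_id integer id of the cell.
#' @return A list of class `backtrace_record`.
#' @export
backtrace <- function(result, cell_id) {
  cells <- result$cells
  row <- which(cells$cell_id == cell_id)
  if (length(row) != 1L) stop("unknown cell id: ", cell_id, call. = FALSE)
  g <- result$graph
  vs <- g$voxel_size
  terr <- cell_territory(g, cells$node_ids[[row]])
  idx <- which(terr, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  crop <- g$label_volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  centroid_um <- c(z = cells$soma_centroid_z_um[row],
                   y = cells$soma_centroid_y_um[row],
                   x = cells$soma_centroid_x_um[row])
  structure(
    list(cell_id = cell_id,
         source = result$source,
         retained_slices_z0 = result$qc$retained_range - 1L,
         soma_centroid_um = centroid_um,
         soma_centroid_voxel0 = round(centroid_um / vs),
         bounding_box_voxel0 = rbind(lo = lo - 1L, hi = hi - 1L),
         label_crop = crop,
         included = cells$included[row],
         exclusion_reason = cells$exclusion_reason[row]),
    class = "backtrace_record")
}

#' @export
print.backtrace_record <- function(x, ...) {
  cat(sprintf("<backtrace> cell %d from %s\n", x$cell_id,
              x$source %||% "<in-memory stack>"))
  cat(sprintf("  soma centroid (z,y,x): %.2f, %.2f, %.2f um; included: %s\n",
              x$soma_centroid_um[1], x$soma_centroid_um[2],
              x$soma_centroid_um[3], x$included))
  invisible(x)
}
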