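# The 59-feature morphology roster: 12 simple-shape features, 29 skeleton
# features, 18 graph-theoretical features. Node- and branch-level quantities
# are summarised by five percentile scores (minimum, 25th percentile, median,
# 75th percentile, maximum; linear interpolation). Ratio features whose
# denominator count is zero take the sentinel value 0 and the cell is flagged
# in the companion quality column.

PCT_TAGS <- c("min", "P25", "P50", "P75", "max")

roster_row <- function(name, family, tag = "none", units = "") {
  tibble::tibble(feature = name, family = family, percentile_tag = tag,
                 units = units)
}

pct_rows <- function(base, family, units = "") {
  dplyr::bind_rows(lapply(PCT_TAGS, function(t) {
    roster_row(paste(base, t), family, t, units)
  }))
}

#' The canonical 59-feature roster
#'
#' An ordered catalogue of the feature columns: name, family (`simple`,
#' `skeleton`, `graph`), percentile tag (`min`, `P25`, `P50`, `P75`, `max`,
#' or `none`), and units. Family sizes are 12 / 29 / 18. Percentile variants
#' of one quantity share the base name before the tag (e.g. `Volume P75`),
#' which is how [select_features()] recognises variant families.
#'
#' @return A 59-row tibble.
#' @export
feature_roster <- function() {
  dplyr::bind_rows(
    # --- simple shape (12)
    roster_row("Sphericity", "simple"),
    roster_row("Circularity", "simple"),
    roster_row("Cell volume", "simple", units = "um3"),
    roster_row("Surface area", "simple", units = "um2"),
    roster_row("Soma volume", "simple", units = "um3"),
    roster_row("Nucleus volume", "simple", units = "um3"),
    roster_row("Extent ratio", "simple"),
    pct_rows("Volume", "simple", "um3"),
    # --- skeleton (29)
    roster_row("Nodes total", "skeleton"),
    roster_row("Branching nodes", "skeleton"),
    roster_row("End-nodes", "skeleton"),
    roster_row("Nodes in branches", "skeleton"),
    roster_row("Nodes per branch", "skeleton"),
    roster_row("End-nodes in branches", "skeleton"),
    roster_row("End-nodes per branch", "skeleton"),
    roster_row("Branch segments", "skeleton"),
    roster_row("Segments per branch", "skeleton"),
    roster_row("Branch cycles", "skeleton"),
    roster_row("Major branches", "skeleton"),
    roster_row("Soma nodes", "skeleton"),
    roster_row("Edges total", "skeleton"),
    roster_row("Total skeleton length", "skeleton", units = "um"),
    pct_rows("Branch length skeleton", "skeleton", "um"),
    pct_rows("Branch length air-line", "skeleton", "um"),
    pct_rows("Branch sinuosity", "skeleton"),
    # --- graph (18)
    pct_rows("Closeness", "graph"),
    pct_rows("Betweenness", "graph"),
    pct_rows("Degree", "graph"),
    roster_row("Diameter", "graph", units = "um"),
    roster_row("Characteristic path length", "graph", units = "um"),
    roster_row("Global efficiency", "graph", units = "1/um"))
}

#' Fingerprint of the feature roster
#'
#' A stable hash of the roster contents, recorded in every output bundle so
#' results can cite the roster version they were computed with.
#'
#' @return Character scalar like `"mg59-1-<hex>"`.
#' @export
roster_hash <- function() {
  r <- feature_roster()
  paste0("mg59-1-",
         fnv1a_hash(paste(r$feature, r$family, r$percentile_tag,
                          collapse = ";")))
}

#' Five-percentile summary
#'
#' Minimum, 25th percentile, median, 75th percentile, and maximum, with
#' linear interpolation between order statistics (quantile type 7). Stated
#' explicitly because percentile conventions differ across ecosystems.
#'
#' @param values numeric vector.
#' @param sentinel value returned for all five scores when `values` is empty.
#' @return Named numeric vector `(min, P25, P50, P75, max)`.
#' @export
percentile_summary <- function(values, sentinel = 0) {
  if (length(values) == 0L) {
    return(stats::setNames(rep(sentinel, 5), PCT_TAGS))
  }
  q <- stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  stats::setNames(q, PCT_TAGS)
}

#' Sphericity of a 3-D body
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`: the ratio of the surface area of a sphere of
#' equal volume to the body's surface area. 1 for a ball; at most 1 + a small
#' discretization tolerance for triangulated surfaces.
#'
#' @param volume_um3 volume, > 0.
#' @param surface_area_um2 surface area, > 0.
#' @return Scalar sphericity.
#' @export
sphericity <- function(volume_um3, surface_area_um2) {
  if (volume_um3 <= 0 || surface_area_um2 <= 0) {
    stop("volume and surface area must be positive", call. = FALSE)
  }
  pi^(1 / 3) * (6 * volume_um3)^(2 / 3) / surface_area_um2
}

#' Circularity index of an area/perimeter pair
#'
#' `4 pi A / P^2`; 1 for a circle. Computed in the exact same way as the
#' manual circularity index on a thresholded projection.
#'
#' @param area area of the 2-D shape.
#' @param perimeter boundary length.
#' @return Scalar circularity.
#' @export
circularity <- function(area, perimeter) {
  if (area <= 0 || perimeter <= 0) {
    stop("area and perimeter must be positive", call. = FALSE)
  }
  4 * pi * area / perimeter^2
}

#' Circularity of a cell territory's z-projection
#'
#' The territory is projected along z (any-voxel union), the area taken as
#' pixel count times pixel area, and the perimeter measured as the
#' boundary-contour length (marching squares at level 0.5 on a lightly
#' smoothed projection, physical units).
#'
#' @param territory 3-D logical array.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return Scalar circularity.
#' @export
circularity_projection <- function(territory, voxel_size) {
  proj <- apply(territory, c(2, 3), any)
  if (!any(proj)) stop("empty projection", call. = FALSE)
  area <- sum(proj) * voxel_size[2] * voxel_size[3]
  idx <- which(proj, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 3L, 1L)
  hi <- pmin(apply(idx, 2, max) + 3L, dim(proj))
  crop <- proj[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE]
  pad <- matrix(0, nrow(crop) + 4L, ncol(crop) + 4L)
  pad[3:(nrow(crop) + 2L), 3:(ncol(crop) + 2L)] <- crop * 1.0
  vol <- array(pad, dim = c(dim(pad), 1L))
  sm <- gauss3(vol, c(1, 1, 0))[, , 1]
  per <- .ms_perimeter(sm, as.numeric(voxel_size[2:3]), 0.5)
  circularity(area, per)
}

#' Sinuosity of a major branch
#'
#' The in-branch shortest-path length from the branch's entry node to its
#' path-farthest node, divided by the straight-line distance between those
#' same two nodes. 1 for a collinear chain; single-node branches return 1 by
#' convention.
#'
#' @param branch_nodes integer node ids of one major branch.
#' @param entry_node the branch's soma-adjacent entry node.
#' @param graph the cell's `skeleton_graph`.
#' @return Scalar >= 1 (up to floating point).
#' @export
branch_sinuosity <- function(branch_nodes, entry_node, graph) {
  geo <- branch_geometry(branch_nodes, entry_node, graph)
  geo$sinuosity
}

# Path length entry -> farthest node within the branch subgraph, the air-line
# distance between the same endpoints, and their ratio.
branch_geometry <- function(branch_nodes, entry_node, graph) {
  if (length(branch_nodes) < 2L) {
    return(list(skeleton_length = 0, airline_length = 0, sinuosity = 1))
  }
  e <- graph$edges
  sub <- e[e$from %in% branch_nodes & e$to %in% branch_nodes, , drop = FALSE]
  gi <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(sub$from), to = as.character(sub$to),
                   weight = sub$length_um),
    directed = FALSE,
    vertices = data.frame(name = as.character(branch_nodes)))
  d <- igraph::distances(gi, v = as.character(entry_node),
                         weights = igraph::E(gi)$weight)[1, ]
  d <- d[is.finite(d)]
  far <- names(d)[which.max(d)]
  skel <- unname(d[far])
  n <- graph$nodes
  i <- as.integer(far)
  air <- sqrt((n$z_um[entry_node] - n$z_um[i])^2 +
              (n$y_um[entry_node] - n$y_um[i])^2 +
              (n$x_um[entry_node] - n$x_um[i])^2)
  list(skeleton_length = skel, airline_length = air,
       sinuosity = if (air > 0) skel / air else 1)
}

#' Skeleton-family features of one cell
#'
#' Counts and ratios over the cell's skeleton graph: total/branching/end
#' nodes, nodes and end-nodes in branches and per major branch, branch
#' segments (edges with both endpoints in branches) and per branch, branch
#' cycles (circuit rank), major branch count, soma nodes, total edges and
#' skeleton length, and five-percentile summaries of per-branch skeleton
#' length, air-line length, and sinuosity.
#'
#' @param graph the cell's `skeleton_graph`.
#' @param branches result of [identify_major_branches()] on the cell graph.
#' @return Named list of skeleton features.
#' @export
skeleton_features <- function(graph, branches) {
  n <- graph$nodes
  e <- graph$edges
  soma_ids <- n$id[n$compartment == "soma"]
  branch_ids <- n$id[n$compartment == "branch"]
  nb <- length(unique(branches$assignment$branch_id))
  deg <- n$degree
  in_branch_edge <- e$from %in% branch_ids & e$to %in% branch_ids
  n_seg <- sum(in_branch_edge)
  end_in_branch <- sum(deg[branch_ids] == 1L)
  per_branch <- function(x) if (nb > 0) x / nb else 0
  geo <- lapply(seq_len(nb), function(b) {
    nodes_b <- branches$assignment$node_id[branches$assignment$branch_id == b]
    entry <- branches$entries$entry_node[branches$entries$branch_id == b]
    branch_geometry(nodes_b, entry, graph)
  })
  skel_len <- vapply(geo, `[[`, numeric(1), "skeleton_length")
  air_len <- vapply(geo, `[[`, numeric(1), "airline_length")
  sinu <- vapply(geo, `[[`, numeric(1), "sinuosity")
  out <- list(
    "Nodes total" = nrow(n),
    "Branching nodes" = sum(deg > 2L),
    "End-nodes" = sum(deg == 1L),
    "Nodes in branches" = length(branch_ids),
    "Nodes per branch" = per_branch(length(branch_ids)),
    "End-nodes in branches" = end_in_branch,
    "End-nodes per branch" = per_branch(end_in_branch),
    "Branch segments" = n_seg,
    "Segments per branch" = per_branch(n_seg),
    "Branch cycles" = count_branch_cycles(graph, soma_ids),
    "Major branches" = nb,
    "Soma nodes" = length(soma_ids),
    "Edges total" = nrow(e),
    "Total skeleton length" = sum(e$length_um))
  out <- c(out,
           as.list(stats::setNames(percentile_summary(skel_len),
                                   paste("Branch length skeleton", PCT_TAGS))),
           as.list(stats::setNames(percentile_summary(air_len),
                                   paste("Branch length air-line", PCT_TAGS))),
           as.list(stats::setNames(percentile_summary(sinu, sentinel = 0),
                                   paste("Branch sinuosity", PCT_TAGS))))
  out
}

#' Graph-family features of one cell
#'
#' Edge-length-weighted node centralities on the (connected) cell graph:
#' closeness `(n-1) / sum of shortest-path distances`, betweenness as the
#' fraction of all-pairs shortest paths through the node (normalised by
#' `(n-1)(n-2)/2`, path multiplicity counted fractionally), and degree, each
#' summarised by five percentiles; plus the graph diameter, characteristic
#' path length (mean pairwise distance), and global efficiency (mean inverse
#' distance). Cells with fewer than 3 nodes have betweenness 0 everywhere.
#'
#' @param graph the cell's `skeleton_graph`.
#' @return Named list of graph features.
#' @export
graph_features <- function(graph) {
  n_nodes <- nrow(graph$nodes)
  if (n_nodes == 1L) {
    clo <- 0
    btw <- 0
    deg <- 0
    diam <- 0
    cpl <- 0
    geff <- 0
  } else {
    gi <- as_igraph(graph)
    w <- igraph::E(gi)$weight
    clo <- suppressWarnings(
      igraph::closeness(gi, weights = w, normalized = TRUE))
    clo[!is.finite(clo)] <- 0
    btw <- if (n_nodes < 3L) {
      rep(0, n_nodes)
    } else {
      igraph::betweenness(gi, weights = w, normalized = TRUE)
    }
    deg <- graph$nodes$degree
    dm <- igraph::distances(gi, weights = w)
    pd <- dm[upper.tri(dm)]
    pd <- pd[is.finite(pd)]
    diam <- if (length(pd)) max(pd) else 0
    cpl <- if (length(pd)) mean(pd) else 0
    geff <- if (length(pd)) mean(1 / pd) else 0
  }
  c(as.list(stats::setNames(percentile_summary(clo),
                            paste("Closeness", PCT_TAGS))),
    as.list(stats::setNames(percentile_summary(btw),
                            paste("Betweenness", PCT_TAGS))),
    as.list(stats::setNames(percentile_summary(deg),
                            paste("Degree", PCT_TAGS))),
    list("Diameter" = diam,
         "Characteristic path length" = cpl,
         "Global efficiency" = geff))
}

# Simple-shape features of one cell.
simple_features <- function(graph, cells_row, masks) {
  ids <- cells_row$node_ids[[1]]
  terr <- cell_territory(graph, ids)
  vs <- graph$voxel_size
  geom <- extract_cell_geometry(terr, vs)
  circ <- circularity_projection(terr, vs)
  soma_vol <- sum(terr & masks$soma_mask) * prod(vs)
  nuc_vol <- sum(terr & masks$nucleus_mask & masks$cell_mask) * prod(vs)
  idx <- which(terr, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1L) * vs
  node_vols <- graph$nodes$volume_um3[ids]
  c(list(
    "Sphericity" = sphericity(geom$volume_um3, geom$surface_area_um2),
    "Circularity" = circ,
    "Cell volume" = geom$volume_um3,
    "Surface area" = geom$surface_area_um2,
    "Soma volume" = soma_vol,
    "Nucleus volume" = nuc_vol,
    "Extent ratio" = min(ext) / max(ext)),
    as.list(stats::setNames(percentile_summary(node_vols),
                            paste("Volume", PCT_TAGS))))
}

# Cell-level subgraph of the full skeleton graph, renumbered 1..n but keeping
# centroids, volumes, compartments, and label volume references.
cell_subgraph <- function(graph, node_ids) {
  keep <- sort(node_ids)
  new_id <- integer(nrow(graph$nodes))
  new_id[keep] <- seq_along(keep)
  n <- graph$nodes[keep, ]
  n$id <- seq_along(keep)
  e <- graph$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  e$from <- new_id[e$from]
  e$to <- new_id[e$to]
  g <- graph
  g$nodes <- n
  g$touches <- graph$touches[keep, , drop = FALSE]
  g$edges <- e
  g$cell_node_ids <- keep  # original ids, for territory lookups
  refresh_graph_derived(g)
}

#' Compute all 59 features for one cell
#'
#' @param graph the full-stack `skeleton_graph`.
#' @param cells_row one row of a flagged `cell_table`.
#' @param masks the stack's `segmentation_masks`.
#' @return Named list of 59 features plus `quality_degenerate` (TRUE when any
#'   ratio feature hit its 0 sentinel).
#' @export
cell_features <- function(graph, cells_row, masks) {
  ids <- cells_row$node_ids[[1]]
  sub <- cell_subgraph(graph, ids)
  # territory lookups need original ids; simple features use the full graph
  simple <- simple_features(graph, cells_row, masks)
  branches <- identify_major_branches(sub)
  skel <- skeleton_features(sub, branches)
  grf <- graph_features(sub)
  feats <- c(simple, skel, grf)
  feats$quality_degenerate <-
    skel[["Major branches"]] == 0 || skel[["Nodes in branches"]] == 0
  feats
}

#' Assemble the per-cell feature table
#'
#' @param cells flagged `cell_table`.
#' @param feature_maps list of per-cell named feature lists (from
#'   [cell_features()]), one per included cell, in `cells` order.
#' @param metadata optional tibble of per-cell metadata columns to prepend
#'   (recycled against included cells).
#' @return A `feature_table` tibble: metadata columns, then exactly the 59
#'   roster columns in canonical order, then `quality_degenerate`.
#' @export
assemble_feature_table <- function(cells, feature_maps, metadata = NULL) {
  roster <- feature_roster()
  inc <- cells[cells$included, ]
  stopifnot(length(feature_maps) == nrow(inc))
  if (nrow(inc) == 0L) {
    out <- tibble::as_tibble(
      c(list(cell_id = integer()),
        stats::setNames(rep(list(numeric()), nrow(roster)), roster$feature),
        list(quality_degenerate = logical())))
    class(out) <- c("feature_table", class(out))
    attr(out, "roster") <- roster
    attr(out, "roster_hash") <- roster_hash()
    return(out)
  }
  rows <- lapply(seq_along(feature_maps), function(i) {
    fm <- feature_maps[[i]]
    missing <- setdiff(roster$feature, names(fm))
    extra <- setdiff(setdiff(names(fm), "quality_degenerate"), roster$feature)
    if (length(missing) || length(extra)) {
      stop("roster mismatch; missing: ",
           paste(missing, collapse = ", "),
           "; extra: ", paste(extra, collapse = ", "), call. = FALSE)
    }
    vals <- tibble::as_tibble(fm[roster$feature])
    vals$quality_degenerate <- isTRUE(fm$quality_degenerate)
    vals$cell_id <- inc$cell_id[i]
    vals
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("cell_id", roster$feature, "quality_degenerate")]
  if (!is.null(metadata)) {
    out <- dplyr::bind_cols(metadata, out)
  }
  class(out) <- c("feature_table", class(out))
  attr(out, "roster") <- roster
  attr(out, "roster_hash") <- roster_hash()
  out
}

#' Feature columns of a feature table
#' @param table a `feature_table`.
#' @return Character vector of the 59 feature column names.
#' @export
feature_columns <- function(table) {
  attr(table, "roster")$feature %||% feature_roster()$feature
}
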