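# Skeleton construction: anisotropic distance map on the cell mask, watershed
# over the (negated) distance map seeded at its local maxima, and a graph
# whose nodes are watershed-segment centroids joined by straight edges.

#' Anisotropic Euclidean distance map
#'
#' For each foreground voxel, the exact shortest physical distance (in
#' micrometres) to the nearest background voxel, honouring the anisotropic
#' sampling `(dz, dy, dx)`. Zero outside the mask.
#'
#' @param cell_mask 3-D logical array.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return An object of class `distance_map` with fields `values` (3-D array)
#'   and `voxel_size`.
#' @export
distance_map <- function(cell_mask, voxel_size) {
  if (!any(cell_mask)) {
    warning("empty mask: distance map is all zero")
    return(structure(list(values = array(0, dim = dim(cell_mask)),
                          voxel_size = voxel_size),
                     class = "distance_map"))
  }
  structure(list(values = edt3(cell_mask, voxel_size),
                 voxel_size = voxel_size),
            class = "distance_map")
}

#' Watershed segmentation of the distance map
#'
#' Marker-based watershed on the negated distance map. Markers are the
#' 26-neighbourhood local maxima of the distance map (plateaus merged into a
#' single marker), greedily thinned so that no two markers lie closer than
#' `min_separation_um` (higher-valued maxima win; ties break on scan order).
#' Regions grow by 6-connected priority flooding, so every foreground voxel
#' receives exactly one positive label and background stays 0.
#'
#' @param dmap a [distance_map()].
#' @param cell_mask 3-D logical array the map was computed on.
#' @param min_separation_um minimum physical marker separation, default 0.6.
#' @return Integer 3-D label array.
#' @export
watershed_segments <- function(dmap, cell_mask, min_separation_um = 0.6) {
  d <- dmap$values
  vs <- dmap$voxel_size
  if (!any(cell_mask)) return(array(0L, dim = dim(cell_mask)))
  cand <- array(.local_max26(as.numeric(d), vol_dim(d)), dim = dim(d))
  cand <- cand & cell_mask
  plat <- cc3(cand, 26L)
  st <- .label_stats(as.integer(plat), vol_dim(plat), logical(0), logical(0),
                     as.numeric(d))
  k <- length(st$n)
  # plateau representative: the voxel attaining the plateau's maximum value
  # (first in scan order -> deterministic)
  rep_idx <- st$d_argmax + 1L
  dims <- dim(d)
  i3 <- (rep_idx - 1L) %/% (dims[1] * dims[2])
  r <- (rep_idx - 1L) %% (dims[1] * dims[2])
  i2 <- r %/% dims[1]
  i1 <- r %% dims[1]
  pos <- cbind(i1 * vs[1], i2 * vs[2], i3 * vs[3])
  vals <- d[rep_idx]
  ord <- order(-vals, rep_idx)
  acc <- integer(0)
  for (i in ord) {
    if (length(acc) == 0L ||
        min(sqrt(rowSums((pos[acc, , drop = FALSE] -
                          matrix(pos[i, ], length(acc), 3,
                                 byrow = TRUE))^2))) >= min_separation_um) {
      acc <- c(acc, i)
    }
  }
  markers <- array(0L, dim = dims)
  markers[rep_idx[acc]] <- seq_along(acc)
  array(.watershed_flood(as.numeric(d), as.integer(markers),
                         as.logical(cell_mask), vol_dim(d)),
        dim = dims)
}

#' Build the skeleton graph from watershed segments
#'
#' One node per watershed segment, placed at the segment's voxel centroid
#' (physical coordinates); an edge for every pair of segments sharing a voxel
#' face, with the straight-line (Euclidean) centroid distance as its length.
#' Node compartments are assigned by majority vote of the segment's voxels
#' against the soma mask; the fraction of nucleus voxels is kept alongside.
#' Nodes are numbered canonically by sorting centroids on (z, y, x).
#'
#' @param labels integer label volume from [watershed_segments()].
#' @param masks a `segmentation_masks` object (used for compartments).
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return An object of class `skeleton_graph`: tibbles `nodes` (id, zyx
#'   centroid in um, volume_um3, compartment, nucleus_frac, degree,
#'   touches matrix of the six stack borders) and `edges` (from, to,
#'   length_um), the relabelled `label_volume`, and `voxel_size`.
#' @export
build_skeleton_graph <- function(labels, masks, voxel_size) {
  st <- .label_stats(as.integer(labels), vol_dim(labels),
                     as.logical(masks$soma_mask),
                     as.logical(masks$nucleus_mask & masks$cell_mask),
                     numeric(0))
  k <- length(st$n)
  if (k == 0L) stop("label volume is empty", call. = FALSE)
  cz <- st$s1 / st$n * voxel_size[1]
  cy <- st$s2 / st$n * voxel_size[2]
  cx <- st$s3 / st$n * voxel_size[3]
  ord <- order(cz, cy, cx)
  new_id <- integer(k)
  new_id[ord] <- seq_len(k)
  nodes <- tibble::tibble(
    id = seq_len(k),
    z_um = cz[ord], y_um = cy[ord], x_um = cx[ord],
    n_vox = st$n[ord],
    volume_um3 = st$n[ord] * prod(voxel_size),
    n_soma_vox = st$n_soma[ord],
    n_nucleus_vox = st$n_nucleus[ord],
    compartment = ifelse(st$n_soma[ord] / st$n[ord] > 0.5, "soma", "branch"),
    nucleus_frac = st$n_nucleus[ord] / st$n[ord])
  touches <- st$touches[ord, , drop = FALSE]
  colnames(touches) <- c("z_lo", "z_hi", "y_lo", "y_hi", "x_lo", "x_hi")
  adj <- .face_adjacency(as.integer(labels), vol_dim(labels))
  edges <- if (nrow(adj) > 0L) {
    a <- new_id[adj[, 1]]
    b <- new_id[adj[, 2]]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    o <- order(lo, hi)
    tibble::tibble(from = lo[o], to = hi[o])
  } else {
    tibble::tibble(from = integer(), to = integer())
  }
  relab <- array(0L, dim = dim(labels))
  nz <- labels > 0L
  relab[nz] <- new_id[labels[nz]]
  g <- structure(
    list(nodes = nodes, edges = edges, touches = touches,
         label_volume = relab, voxel_size = voxel_size),
    class = "skeleton_graph")
  refresh_graph_derived(g)
}

# Recompute edge lengths and node degrees from centroids + edge list.
refresh_graph_derived <- function(g) {
  n <- g$nodes
  e <- g$edges
  if (nrow(e) > 0L) {
    e$length_um <- sqrt(
      (n$z_um[e$from] - n$z_um[e$to])^2 +
      (n$y_um[e$from] - n$y_um[e$to])^2 +
      (n$x_um[e$from] - n$x_um[e$to])^2)
  } else {
    e$length_um <- numeric(0)
  }
  deg <- tabulate(c(e$from, e$to), nbins = nrow(n))
  g$nodes$degree <- deg
  g$edges <- e
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d soma), %d edges\n",
              nrow(x$nodes), sum(x$nodes$compartment == "soma"),
              nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = data.frame(from = g$edges$from, to = g$edges$to,
                   weight = g$edges$length_um),
    directed = FALSE,
    vertices = data.frame(name = g$nodes$id))
}

#' Refine the skeleton graph
#'
#' Two rules applied to a fixpoint: (1) a node whose segment volume is below
#' `min_segment_volume_um3` is merged into its largest face-adjacent
#' neighbour; (2) a degree-1 branch node whose single edge is shorter than
#' `max_spur_length_um` and whose neighbour has degree >= 3 is merged into
#' that neighbour (spur removal). Merging pools voxels, so the sum of node
#' volumes always equals the mask volume; centroids are recomputed
#' volume-weighted and compartments by pooled majority.
#'
#' @param graph a `skeleton_graph`.
#' @param min_segment_volume_um3 default 0.2.
#' @param max_spur_length_um default 0.5.
#' @return A refined `skeleton_graph` with canonical node numbering.
#' @export
refine_skeleton <- function(graph, min_segment_volume_um3 = 0.2,
                            max_spur_length_um = 0.5) {
  g <- graph
  # label-volume ids are rewritten once at the end via this running map
  g$remap <- seq_len(nrow(g$nodes))
  repeat {
    act <- refine_pass(g, min_segment_volume_um3, max_spur_length_um)
    if (!act$changed) break
    g <- act$graph
  }
  renumber_graph(g)
}

refine_pass <- function(g, min_vol, max_spur) {
  n <- g$nodes
  e <- g$edges
  neighbours <- function(id) {
    c(e$to[e$from == id], e$from[e$to == id])
  }
  # rule 1: smallest sub-threshold node first (deterministic)
  small <- which(n$volume_um3 < min_vol & n$degree > 0L)
  victim <- NA_integer_
  target <- NA_integer_
  if (length(small) > 0L) {
    small <- small[order(n$volume_um3[small], small)]
    victim <- small[1]
    nb <- neighbours(victim)
    target <- nb[order(-n$volume_um3[nb], nb)][1]
  } else {
    # rule 2: spur pruning
    spur <- which(n$degree == 1L & n$compartment == "branch")
    for (s in spur) {
      nb <- neighbours(s)
      len <- e$length_um[e$from == s | e$to == s][1]
      if (len < max_spur && n$degree[nb[1]] >= 3L) {
        victim <- s
        target <- nb[1]
        break
      }
    }
  }
  if (is.na(victim)) return(list(changed = FALSE, graph = g))
  list(changed = TRUE, graph = merge_nodes(g, victim, target))
}

# Merge node `a` into node `b`: pool voxels, recompute centroid/compartment,
# rewire edges, drop self-loops and duplicates.
merge_nodes <- function(g, a, b) {
  n <- g$nodes
  wa <- n$n_vox[a]
  wb <- n$n_vox[b]
  n$z_um[b] <- (n$z_um[a] * wa + n$z_um[b] * wb) / (wa + wb)
  n$y_um[b] <- (n$y_um[a] * wa + n$y_um[b] * wb) / (wa + wb)
  n$x_um[b] <- (n$x_um[a] * wa + n$x_um[b] * wb) / (wa + wb)
  n$n_vox[b] <- wa + wb
  n$volume_um3[b] <- n$volume_um3[a] + n$volume_um3[b]
  n$n_soma_vox[b] <- n$n_soma_vox[a] + n$n_soma_vox[b]
  n$n_nucleus_vox[b] <- n$n_nucleus_vox[a] + n$n_nucleus_vox[b]
  n$compartment[b] <- if (n$n_soma_vox[b] / n$n_vox[b] > 0.5) "soma" else "branch"
  n$nucleus_frac[b] <- n$n_nucleus_vox[b] / n$n_vox[b]
  tch <- g$touches
  tch[b, ] <- tch[a, ] | tch[b, ]
  e <- g$edges
  e$from[e$from == a] <- b
  e$to[e$to == a] <- b
  lo <- pmin(e$from, e$to)
  hi <- pmax(e$from, e$to)
  keep <- lo != hi & !duplicated(paste(lo, hi))
  e <- tibble::tibble(from = lo[keep], to = hi[keep])
  # drop node a, shift ids above a down by one
  shift <- function(v) ifelse(v > a, v - 1L, v)
  g$nodes <- n[-a, ]
  g$nodes$id <- seq_len(nrow(g$nodes))
  g$touches <- tch[-a, , drop = FALSE]
  g$edges <- tibble::tibble(from = shift(e$from), to = shift(e$to))
  if (!is.null(g$remap)) {
    g$remap <- shift(ifelse(g$remap == a, b, g$remap))
  } else {
    lv <- g$label_volume
    lv[lv == a] <- b
    pos <- lv > a
    lv[pos] <- lv[pos] - 1L
    g$label_volume <- lv
  }
  refresh_graph_derived(g)
}

# Re-sort nodes canonically by (z, y, x) centroid and relabel everything.
renumber_graph <- function(g) {
  ord <- order(g$nodes$z_um, g$nodes$y_um, g$nodes$x_um)
  new_id <- integer(nrow(g$nodes))
  new_id[ord] <- seq_len(nrow(g$nodes))
  n <- g$nodes[ord, ]
  n$id <- seq_len(nrow(n))
  e <- g$edges
  if (nrow(e) > 0L) {
    a <- new_id[e$from]
    b <- new_id[e$to]
    o <- order(pmin(a, b), pmax(a, b))
    e <- tibble::tibble(from = pmin(a, b)[o], to = pmax(a, b)[o])
  }
  lv <- g$label_volume
  nz <- lv > 0L
  if (!is.null(g$remap)) {
    lv[nz] <- new_id[g$remap[lv[nz]]]
    g$remap <- NULL
  } else {
    lv[nz] <- new_id[lv[nz]]
  }
  g$nodes <- n
  g$touches <- g$touches[ord, , drop = FALSE]
  g$edges <- e
  g$label_volume <- lv
  refresh_graph_derived(g)
}

#' Partition branch nodes into major branches
#'
#' A major branch is a connected component of the branch-node subgraph,
#' entered from the soma; each component is owned by its lowest-id
#' soma-adjacent node (the entry node), which makes the assignment
#' deterministic even when a looped branch touches the soma twice. Branch
#' components with no soma-adjacent node (possible only in disconnected
#' graphs) are not major branches.
#'
#' @param graph a `skeleton_graph`.
#' @param soma_nodes integer ids of soma-compartment nodes; defaults to all
#'   nodes labelled `"soma"`.
#' @return A list with `assignment` (tibble: node_id, branch_id) and
#'   `entries` (tibble: branch_id, entry_node).
#' @export
identify_major_branches <- function(graph, soma_nodes = NULL) {
  n <- graph$nodes
  e <- graph$edges
  if (is.null(soma_nodes)) soma_nodes <- n$id[n$compartment == "soma"]
  branch_ids <- setdiff(n$id, soma_nodes)
  if (length(branch_ids) == 0L) {
    return(list(assignment = tibble::tibble(node_id = integer(),
                                            branch_id = integer()),
                entries = tibble::tibble(branch_id = integer(),
                                         entry_node = integer())))
  }
  sub_e <- e[e$from %in% branch_ids & e$to %in% branch_ids, , drop = FALSE]
  gi <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(sub_e$from),
                   to = as.character(sub_e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(branch_ids)))
  comp <- igraph::components(gi)$membership
  comp <- comp[as.character(branch_ids)]
  # soma-adjacent branch nodes
  adj <- unique(c(e$to[e$from %in% soma_nodes & e$to %in% branch_ids],
                  e$from[e$to %in% soma_nodes & e$from %in% branch_ids]))
  entry_by_comp <- tapply(
    ifelse(branch_ids %in% adj, branch_ids, NA_integer_), comp,
    function(v) if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE))
  keep <- !is.na(entry_by_comp)
  comps <- sort(as.integer(names(entry_by_comp)[keep]))
  entries <- vapply(as.character(comps),
                    function(k) as.integer(entry_by_comp[[k]]), integer(1))
  bo <- order(entries)
  branch_id_of_comp <- stats::setNames(rep(NA_integer_,
                                           length(entry_by_comp)),
                                       names(entry_by_comp))
  branch_id_of_comp[as.character(comps[bo])] <- seq_along(comps)
  assignment <- tibble::tibble(
    node_id = branch_ids,
    branch_id = unname(branch_id_of_comp[as.character(comp)]))
  assignment <- assignment[!is.na(assignment$branch_id), ]
  list(assignment = assignment,
       entries = tibble::tibble(branch_id = seq_along(comps),
                                entry_node = unname(sort(entries))))
}

#' Number of independent cycles in the branches
#'
#' The circuit rank `E - N + C` of the branch-compartment subgraph, where `C`
#' is its number of connected components.
#'
#' @param graph a `skeleton_graph`.
#' @param soma_nodes soma node ids; defaults to the `"soma"` compartment.
#' @return Integer cycle count.
#' @export
count_branch_cycles <- function(graph, soma_nodes = NULL) {
  n <- graph$nodes
  e <- graph$edges
  if (is.null(soma_nodes)) soma_nodes <- n$id[n$compartment == "soma"]
  branch_ids <- setdiff(n$id, soma_nodes)
  if (length(branch_ids) == 0L) return(0L)
  sub_e <- e[e$from %in% branch_ids & e$to %in% branch_ids, , drop = FALSE]
  gi <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(sub_e$from),
                   to = as.character(sub_e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(branch_ids)))
  as.integer(nrow(sub_e) - length(branch_ids) +
             igraph::components(gi)$no)
}

#' Serialize a skeleton graph to node / edge CSV files
#'
#' @param graph a `skeleton_graph`.
#' @param nodes_path,edges_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_skeleton_csv <- function(graph, nodes_path, edges_path) {
  utils::write.csv(
    graph$nodes[, c("id", "z_um", "y_um", "x_um", "volume_um3",
                    "compartment", "nucleus_frac", "degree")],
    nodes_path, row.names = FALSE)
  utils::write.csv(graph$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
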