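# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# Exhaustive anisotropic distance transform: for every foreground voxel, the
# minimum physical distance over all background voxels.
brute_distance_map <- function(mask, voxel_size) {
  dims <- dim(mask)
  out <- array(0, dim = dims)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(out + Inf)
  bgp <- sweep(bg - 1, 2, voxel_size, `*`)
  for (p in which(mask)) {
    fp <- (arrayInd(p, dims) - 1) * voxel_size
    out[p] <- sqrt(min(rowSums(sweep(bgp, 2, as.numeric(fp))^2)))
  }
  out
}

# All simple paths between two nodes of a small undirected weighted graph
# (edge list with columns from, to, w), by depth-first enumeration.
all_simple_paths_brute <- function(n, edges, from, to) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$w[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  paths <- list()
  walk <- function(node, visited, len) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- list(nodes = visited, length = len)
      return()
    }
    for (k in seq_len(NROW(adj[[node]]))) {
      nb <- adj[[node]][k, 1]; w <- adj[[node]][k, 2]
      if (!(nb %in% visited)) walk(nb, c(visited, nb), len + w)
    }
  }
  if (!is.null(adj[[from]])) walk(from, from, 0)
  paths
}

# Shortest-path distance, path count, and per-node pass-through counts by
# exhaustive path enumeration.
brute_shortest <- function(n, edges, from, to, tol = 1e-9) {
  ps <- all_simple_paths_brute(n, edges, from, to)
  if (length(ps) == 0L) return(list(dist = Inf, count = 0, through = rep(0, n)))
  lens <- vapply(ps, `[[`, numeric(1), "length")
  dmin <- min(lens)
  sel <- ps[lens <= dmin + tol]
  through <- rep(0, n)
  for (p in sel) {
    inner <- setdiff(p$nodes, c(from, to))
    through[inner] <- through[inner] + 1
  }
  list(dist = dmin, count = length(sel), through = through)
}

# Closeness (n-1)/sum d and betweenness (fractional, normalised by
# (n-1)(n-2)/2) for every node, from the path-enumeration oracle.
brute_centralities <- function(n, edges) {
  dists <- matrix(Inf, n, n)
  diag(dists) <- 0
  btw <- rep(0, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- brute_shortest(n, edges, i, j)
      dists[i, j] <- dists[j, i] <- r$dist
      if (r$count > 0) btw <- btw + r$through / r$count
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    s <- sum(dists[i, -i])
    if (is.finite(s) && s > 0) (n - 1) / s else 0
  }, numeric(1))
  list(closeness = clo,
       betweenness = if (n >= 3) btw / ((n - 1) * (n - 2) / 2) else rep(0, n),
       dist = dists)
}

# ROC AUC by trapezoidal integration of the empirical ROC curve.
trapezoid_auc <- function(pos, neg) {
  cuts <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Random connected weighted graph for centrality checks.
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    edges <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) {
          edges <- rbind(edges, data.frame(from = i, to = j,
                                           w = round(runif(1, 0.5, 2), 3)))
        }
      }
    }
    if (is.null(edges)) next
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = 1:n))
    if (igraph::is_connected(g)) return(edges)
  }
}
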