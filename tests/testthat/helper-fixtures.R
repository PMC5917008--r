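# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# Digital ball mask: radius in voxels, isotropic.
ball_mask <- function(r, pad = 2L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= r^2, dim = c(n, n, n))
}

# Straight tube along x: physical length and radius, given voxel size.
tube_mask <- function(length_um, radius_um, voxel_size, pad_um = 2) {
  dims <- ceiling(c(2 * (radius_um + pad_um),
                    2 * (radius_um + pad_um),
                    length_um + 2 * pad_um) / voxel_size)
  ctr_zy <- (dims[1:2] - 1) / 2 * voxel_size[1:2]
  x0 <- pad_um
  x1 <- pad_um + length_um
  g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                   x = seq_len(dims[3]))
  zc <- (g$z - 1) * voxel_size[1] - ctr_zy[1]
  yc <- (g$y - 1) * voxel_size[2] - ctr_zy[2]
  xc <- (g$x - 1) * voxel_size[3]
  array(zc^2 + yc^2 <= radius_um^2 & xc >= x0 & xc <= x1, dim = dims)
}

# Hand-built skeleton graph: nodes is a data.frame with z, y, x (um), volume,
# compartment; edges a data.frame with from, to. Label volume is a dummy.
make_skel_graph <- function(nodes, edges,
                            voxel_size = c(1, 1, 1),
                            label_dims = c(4L, 4L, 4L)) {
  n <- nrow(nodes)
  g <- structure(
    list(nodes = tibble::tibble(
           id = seq_len(n),
           z_um = nodes$z, y_um = nodes$y, x_um = nodes$x,
           n_vox = nodes$volume, volume_um3 = nodes$volume,
           n_soma_vox = ifelse(nodes$compartment == "soma", nodes$volume, 0),
           n_nucleus_vox = 0,
           compartment = nodes$compartment,
           nucleus_frac = 0),
         edges = tibble::tibble(from = as.integer(edges$from),
                                to = as.integer(edges$to)),
         touches = matrix(FALSE, n, 6,
                          dimnames = list(NULL, c("z_lo", "z_hi", "y_lo",
                                                  "y_hi", "x_lo", "x_hi"))),
         label_volume = array(0L, dim = label_dims),
         voxel_size = voxel_size),
    class = "skeleton_graph")
  microglia3d:::refresh_graph_derived(g)
}

# Star skeleton: one soma node at the origin with `arms` pendant chains of
# `chain_len` branch nodes spaced 1 um apart.
star_graph <- function(arms = 3, chain_len = 4) {
  dirs <- list(c(0, 0, 1), c(0, 1, 0), c(0, 0, -1), c(0, -1, 0), c(1, 0, 0))
  nodes <- data.frame(z = 0, y = 0, x = 0, volume = 5, compartment = "soma")
  edges <- NULL
  id <- 1L
  for (a in seq_len(arms)) {
    prev <- 1L
    for (k in seq_len(chain_len)) {
      id <- id + 1L
      p <- dirs[[a]] * k
      nodes <- rbind(nodes, data.frame(z = p[1], y = p[2], x = p[3],
                                       volume = 1, compartment = "branch"))
      edges <- rbind(edges, data.frame(from = prev, to = id))
      prev <- id
    }
  }
  make_skel_graph(nodes, edges)
}

# A two-level (no noise, no texture) single-cell phantom stack.
two_level_phantom <- function(preset = amoeboid_spec, seed = 1,
                              dims_um = c(20, 36, 36),
                              voxel_size = c(0.5, 0.5, 0.5),
                              noise = 0, texture = 0) {
  sp <- preset(seed)
  sp$placement_um <- dims_um / 2
  render_stack(list(sp), dims_um, voxel_size,
               noise_sd_fraction = noise, texture_sd_fraction = texture,
               seed = seed)
}

# Frozen study-condition layouts for the K-cell recovery checks.
recovery_dims <- function(k) {
  switch(as.character(k),
         "1" = c(20, 40, 40),
         "3" = c(20, 56, 56),
         "5" = c(20, 74, 74),
         stop("unsupported K"))
}

render_recovery_stack <- function(k, seed) {
  dims_um <- recovery_dims(k)
  specs <- microglia3d:::with_seed(seed, {
    pl <- place_cells_grid(k, dims_um)
    lapply(seq_len(k), function(i) {
      sp <- if (i %% 2 == 1) ramified_spec(seed * 10 + i) else {
        amoeboid_spec(seed * 10 + i)
      }
      sp$placement_um <- pl[i, ]
      sp
    })
  })
  render_stack(specs, dims_um, voxel_size = c(0.5, 0.5, 0.5),
               noise_sd_fraction = 0.05, seed = seed)
}

# One small processed stack, cached per test session (several files assert
# different properties of the same result).
cached_stack_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- render_recovery_stack(3, seed = 7)
      cache <<- list(render = r,
                     result = process_stack(r$stack,
                                            pipeline_config(list(r$stack))))
    }
    cache
  }
})
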