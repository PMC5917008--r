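# The 59-feature roster: percentiles, shape descriptors, skeleton and graph
# features, and the roster contract.

test_that("five-percentile summary uses linear interpolation and stays ordered", {
  expect_equal(unname(percentile_summary(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(percentile_summary(7)), rep(7, 5))
  p <- percentile_summary(c(1, 2, 100))
  expect_equal(unname(p["P50"]), 2)
  expect_equal(unname(p["max"]), 100)
  expect_equal(unname(percentile_summary(numeric(0), sentinel = 0)),
               rep(0, 5))
  for (s in 1:5) {
    v <- microglia3d:::with_seed(s, rnorm(17))
    q <- percentile_summary(v)
    expect_true(all(diff(q) >= 0))
  }
})

test_that("sphericity and circularity match closed forms exactly", {
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1,
               tolerance = 1e-12)
  a <- 2.1
  expect_equal(sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-12)
  expect_error(sphericity(0, 1), "positive")
  expect_error(circularity(1, 0), "positive")
})

test_that("digital shapes stay inside the discretization bands", {
  ball <- ball_mask(20)
  geo <- extract_cell_geometry(ball, c(1, 1, 1))
  sph <- sphericity(geo$volume_um3, geo$surface_area_um2)
  expect_gte(sph, 0.92)
  expect_lte(sph, 1.02)
  disk <- array(FALSE, dim = c(3, 110, 110))
  g <- expand.grid(y = 1:110, x = 1:110)
  inside <- (g$y - 55)^2 + (g$x - 55)^2 <= 50^2
  for (z in 1:3) disk[z, , ] <- array(inside, dim = c(110, 110))
  circ <- circularity_projection(disk, c(1, 1, 1))
  expect_gte(circ, 0.90)
  expect_lte(circ, 1.02)
})

test_that("skeleton features count a star fixture exactly", {
  st <- star_graph(arms = 3, chain_len = 4)
  mb <- identify_major_branches(st)
  sf <- skeleton_features(st, mb)
  expect_equal(sf[["Nodes total"]], 13)
  expect_equal(sf[["Branching nodes"]], 1)
  expect_equal(sf[["End-nodes"]], 3)
  expect_equal(sf[["Nodes in branches"]], 12)
  expect_equal(sf[["Major branches"]], 3)
  expect_equal(sf[["Nodes per branch"]], 4)
  expect_equal(sf[["End-nodes in branches"]], 3)
  expect_equal(sf[["End-nodes per branch"]], 1)
  expect_equal(sf[["Branch cycles"]], 0L)
  expect_equal(sf[["Branch sinuosity P50"]], 1)
})

test_that("a soma-only cell gets zero-sentinel branch features", {
  soma_only <- make_skel_graph(
    data.frame(z = 0, y = 0, x = 0, volume = 5, compartment = "soma"),
    data.frame(from = integer(), to = integer()))
  sf <- skeleton_features(soma_only, identify_major_branches(soma_only))
  expect_equal(sf[["Nodes total"]], 1)
  expect_equal(sf[["Nodes in branches"]], 0)
  expect_equal(sf[["Segments per branch"]], 0)
  expect_equal(sf[["Branch length skeleton P75"]], 0)
})

test_that("branch sinuosity: straight chains, right angles, and the lower bound", {
  chain <- make_skel_graph(
    data.frame(z = 0, y = 0, x = 0:3, volume = 1,
               compartment = c("soma", rep("branch", 3))),
    data.frame(from = 1:3, to = 2:4))
  mb <- identify_major_branches(chain)
  expect_equal(branch_sinuosity(mb$assignment$node_id, 2L, chain), 1,
               tolerance = 1e-12)
  ell <- make_skel_graph(
    data.frame(z = 0, y = c(0, 0, 0, 1), x = c(-1, 0, 1, 1), volume = 1,
               compartment = c("soma", rep("branch", 3))),
    data.frame(from = 1:3, to = 2:4))
  mbe <- identify_major_branches(ell)
  expect_equal(branch_sinuosity(mbe$assignment$node_id, 2L, ell),
               2 / sqrt(2), tolerance = 1e-12)
  for (s in 1:5) {
    pts <- microglia3d:::with_seed(200 + s,
                                   apply(matrix(rnorm(3 * 6), 6, 3), 2,
                                         cumsum))
    nodes <- data.frame(z = c(0, pts[, 1]), y = c(0, pts[, 2]),
                        x = c(0, pts[, 3]), volume = 1,
                        compartment = c("soma", rep("branch", 6)))
    g <- make_skel_graph(nodes, data.frame(from = 1:6, to = 2:7))
    mbs <- identify_major_branches(g)
    expect_gte(branch_sinuosity(mbs$assignment$node_id,
                                mbs$entries$entry_node[1], g), 1 - 1e-9)
  }
})

test_that("graph features match hand-computed and brute-force values", {
  p3 <- make_skel_graph(
    data.frame(z = 0, y = 0, x = 0:2, volume = 1, compartment = "branch"),
    data.frame(from = 1:2, to = 2:3))
  gf <- graph_features(p3)
  expect_equal(gf[["Betweenness max"]], 1)    # middle node
  expect_equal(gf[["Betweenness min"]], 0)
  expect_equal(gf[["Closeness max"]], 1)      # middle node: (n-1)/sum d
  expect_equal(gf[["Closeness min"]], 2 / 3)  # ends
  expect_equal(gf[["Diameter"]], 2)
  k4 <- make_skel_graph(
    data.frame(z = 0, y = c(0, 0, 1, 1), x = c(0, 1, 0, 1), volume = 1,
               compartment = "branch"),
    data.frame(from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4)))
  # force unit edge lengths by overriding centroids after construction
  k4$edges$length_um <- rep(1, 6)
  gfk <- graph_features(k4)
  expect_equal(gfk[["Betweenness max"]], 0)
  expect_equal(gfk[["Closeness min"]], 1)
})

test_that("centralities equal the exhaustive path-enumeration oracle", {
  for (s in 1:4) {
    edges <- microglia3d:::with_seed(300 + s, {
      n <- sample(6:10, 1)
      random_connected_graph(n)
    })
    n <- max(c(edges$from, edges$to))
    g <- make_skel_graph(
      data.frame(z = 0, y = 0, x = seq_len(n), volume = 1,
                 compartment = "branch"),
      edges[, c("from", "to")])
    g$edges$length_um <- edges$w[order(pmin(edges$from, edges$to),
                                       pmax(edges$from, edges$to))]
    gf <- graph_features(g)
    oracle <- brute_centralities(n, edges)
    expect_equal(unname(gf[["Closeness max"]]), max(oracle$closeness),
                 tolerance = 1e-9)
    expect_equal(unname(gf[["Closeness min"]]), min(oracle$closeness),
                 tolerance = 1e-9)
    expect_equal(unname(gf[["Betweenness max"]]), max(oracle$betweenness),
                 tolerance = 1e-9)
    expect_equal(unname(gf[["Betweenness P50"]]),
                 unname(stats::quantile(oracle$betweenness, 0.5)),
                 tolerance = 1e-9)
    expect_equal(unname(gf[["Diameter"]]),
                 max(oracle$dist[is.finite(oracle$dist)]), tolerance = 1e-9)
  }
})

test_that("the roster contract holds: 59 columns, family sizes, Table labels", {
  roster <- feature_roster()
  expect_identical(nrow(roster), 59L)
  counts <- vapply(c("simple", "skeleton", "graph"),
                   function(f) sum(roster$family == f), integer(1))
  expect_identical(unname(counts), c(12L, 29L, 18L))
  table1 <- c("Sphericity", "Circularity", "Volume P75", "Nodes total",
              "Branching nodes", "End-nodes", "Nodes in branches",
              "Nodes per branch", "End-nodes in branches",
              "End-nodes per branch", "Branch segments",
              "Segments per branch", "Branch cycles",
              "Branch length skeleton P75", "Branch sinuosity P50",
              "Closeness P75", "Betweenness P75")
  expect_identical(length(table1), 17L)
  expect_true(all(table1 %in% roster$feature))
  expect_false(anyDuplicated(roster$feature) > 0)
  expect_match(roster_hash(), "^mg59-1-[0-9a-f]{8}$")
})

test_that("assembled feature tables satisfy the roster and ordering invariants", {
  cs <- cached_stack_result()
  ft <- cs$result$features
  roster <- feature_roster()
  expect_identical(setdiff(feature_columns(ft), names(ft)), character(0))
  expect_identical(length(feature_columns(ft)), 59L)
  expect_false(any(is.na(as.matrix(ft[, feature_columns(ft)]))))
  # percentile families are ordered row-wise
  bases <- unique(sub(" (min|P25|P50|P75|max)$", "",
                      roster$feature[roster$percentile_tag != "none"]))
  for (b in bases) {
    cols <- paste(b, c("min", "P25", "P50", "P75", "max"))
    m <- as.matrix(ft[, cols])
    expect_true(all(t(apply(m, 1, diff)) >= -1e-9), label = b)
  }
  # roster mismatch raises a helpful error
  bad <- cs$result$feature_maps
  bad[[1]][["Sphericity"]] <- NULL
  expect_error(
    assemble_feature_table(cs$result$cells, bad),
    "roster mismatch")
})

test_that("features are invariant under translation of the whole cell", {
  vs <- c(0.5, 0.5, 0.5)
  m <- tube_mask(8, 1.0, vs)
  big <- array(FALSE, dim = dim(m) + c(6L, 6L, 6L))
  big1 <- big
  big1[seq_len(dim(m)[1]) + 1L, seq_len(dim(m)[2]) + 1L,
       seq_len(dim(m)[3]) + 1L] <- m
  big2 <- big
  big2[seq_len(dim(m)[1]) + 4L, seq_len(dim(m)[2]) + 3L,
       seq_len(dim(m)[3]) + 2L] <- m
  feats <- lapply(list(big1, big2), function(mm) {
    dm <- distance_map(mm, vs)
    lab <- watershed_segments(dm, mm)
    masks <- structure(list(cell_mask = mm,
                            nucleus_mask = array(FALSE, dim = dim(mm)),
                            soma_mask = array(FALSE, dim = dim(mm)),
                            branch_mask = mm),
                       class = "segmentation_masks")
    g <- refine_skeleton(build_skeleton_graph(lab, masks, vs))
    c(n = nrow(g$nodes), e = nrow(g$edges),
      len = sum(g$edges$length_um),
      vol = sum(g$nodes$volume_um3))
  })
  expect_equal(feats[[1]], feats[[2]], tolerance = 1e-9)
})
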