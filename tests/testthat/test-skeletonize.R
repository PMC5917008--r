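# Distance map, watershed, skeleton graph construction and refinement.

test_that("distance map equals the exhaustive brute-force oracle", {
  vs <- c(0.4, 0.2, 0.3)
  for (s in 1:5) {
    m <- microglia3d:::with_seed(s, {
      dims <- sample(5:10, 3, replace = TRUE)
      array(runif(prod(dims)) > 0.45, dim = dims)
    })
    d <- distance_map(m, vs)
    expect_equal(d$values, brute_distance_map(m, vs), tolerance = 1e-12)
  }
})

test_that("distance map handles canonical single-voxel and cube cases", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  d <- distance_map(m, c(0.4, 0.2, 0.2))
  expect_equal(d$values[3, 3, 3], 0.2)
  cube <- array(FALSE, dim = c(7, 7, 7))
  cube[2:6, 2:6, 2:6] <- TRUE
  d2 <- distance_map(cube, c(0.2, 0.2, 0.2))
  expect_equal(d2$values[4, 4, 4], 0.6)
  empty <- array(FALSE, dim = c(3, 3, 3))
  expect_warning(d3 <- distance_map(empty, c(1, 1, 1)), "empty")
  expect_true(all(d3$values == 0))
})

test_that("a ball yields one watershed segment; labels partition the mask", {
  b <- ball_mask(8)
  vs <- c(0.4, 0.4, 0.4)
  dm <- distance_map(b, vs)
  lab <- watershed_segments(dm, b)
  expect_identical(max(lab), 1L)
  expect_identical(lab > 0L, b)
})

test_that("two balls joined by a tube separate into distinct segments", {
  vs <- c(0.4, 0.4, 0.4)
  dims <- c(26L, 26L, 80L)
  g <- expand.grid(z = 1:dims[1], y = 1:dims[2], x = 1:dims[3])
  pz <- (g$z - 13) * vs[1]
  py <- (g$y - 13) * vs[2]
  px <- (g$x - 1) * vs[3]
  c1 <- 6
  c2 <- 26
  m <- array(pz^2 + py^2 + (px - c1)^2 <= 3^2 |
             pz^2 + py^2 + (px - c2)^2 <= 3^2 |
             (pz^2 + py^2 <= 0.6^2 & px >= c1 & px <= c2), dim = dims)
  dm <- distance_map(m, vs)
  lab <- watershed_segments(dm, m)
  expect_gte(max(lab), 3L)
  l1 <- lab[13, 13, round(c1 / vs[3]) + 1]
  l2 <- lab[13, 13, round(c2 / vs[3]) + 1]
  expect_true(l1 != l2 && l1 > 0 && l2 > 0)
  expect_identical(lab > 0L, m)  # partition
})

dummy_masks <- function(mask) {
  structure(list(cell_mask = mask,
                 nucleus_mask = array(FALSE, dim = dim(mask)),
                 soma_mask = array(FALSE, dim = dim(mask)),
                 branch_mask = mask),
            class = "segmentation_masks")
}

test_that("a straight tube skeletonizes into a path graph of expected length", {
  vs <- c(0.4, 0.4, 0.4)
  tube_len <- 20
  m <- tube_mask(tube_len, 0.8, vs)
  dm <- distance_map(m, vs)
  lab <- watershed_segments(dm, m)
  g <- build_skeleton_graph(lab, dummy_masks(m), vs)
  g <- refine_skeleton(g)
  # path graph: all degrees <= 2, connected, edges = nodes - 1
  expect_true(all(g$nodes$degree <= 2))
  expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
  # total edge length approximates tube length minus the end half-segments
  k <- nrow(g$nodes)
  expected_len <- tube_len * (1 - 1 / k)
  expect_lt(abs(sum(g$edges$length_um) - expected_len),
            0.15 * tube_len)
  # sum of node volumes = mask volume, exactly
  expect_equal(sum(g$nodes$volume_um3), sum(m) * prod(vs), tolerance = 1e-9)
  # single-segment ball: one node, no edges
  b <- ball_mask(6)
  dmb <- distance_map(b, vs)
  gb <- build_skeleton_graph(watershed_segments(dmb, b), dummy_masks(b), vs)
  expect_identical(nrow(gb$nodes), 1L)
  expect_identical(nrow(gb$edges), 0L)
})

test_that("skeleton refinement merges small nodes and conserves volume", {
  # path with a tiny mid node
  nodes <- data.frame(z = c(0, 0, 0), y = c(0, 0, 0), x = c(0, 1, 2),
                      volume = c(5, 0.1, 5),
                      compartment = c("branch", "branch", "branch"))
  edges <- data.frame(from = c(1, 2), to = c(2, 3))
  g <- make_skel_graph(nodes, edges)
  r <- refine_skeleton(g, min_segment_volume_um3 = 0.2,
                       max_spur_length_um = 0.5)
  expect_identical(nrow(r$nodes), 2L)
  expect_identical(nrow(r$edges), 1L)
  expect_equal(sum(r$nodes$volume_um3), 10.1)
  # untouched graph is returned unchanged (idempotence)
  clean <- star_graph()
  r2 <- refine_skeleton(clean)  # canonical renumbering may reorder nodes
  expect_equal(sort(r2$nodes$volume_um3), sort(clean$nodes$volume_um3))
  expect_identical(nrow(r2$edges), nrow(clean$edges))
  # volume conservation on watershed graphs from random blobby masks
  vs <- c(0.5, 0.5, 0.5)
  for (s in 1:3) {
    m <- microglia3d:::with_seed(100 + s, {
      raw <- array(rnorm(16 * 16 * 16), dim = c(16, 16, 16))
      sm <- microglia3d:::gauss3(raw, c(1.5, 1.5, 1.5))
      sm > quantile(sm, 0.7)
    })
    if (!any(m)) next
    dm <- distance_map(m, vs)
    g0 <- build_skeleton_graph(watershed_segments(dm, m), dummy_masks(m), vs)
    r0 <- refine_skeleton(g0)
    expect_equal(sum(r0$nodes$volume_um3), sum(m) * prod(vs),
                 tolerance = 1e-9)
    # label volume stays a partition mapped to surviving node ids
    expect_setequal(unique(as.integer(r0$label_volume[m])), r0$nodes$id)
  }
})

test_that("major branches partition pendant chains, trees, and loops", {
  st <- star_graph(arms = 3, chain_len = 4)
  mb <- identify_major_branches(st)
  expect_identical(length(unique(mb$assignment$branch_id)), 3L)
  expect_identical(nrow(mb$assignment), 12L)
  # bifurcating tree from one entry: a single major branch
  nodes <- data.frame(
    z = 0, y = c(0, 0, 1, -1, 2, -2), x = c(0, 1, 2, 2, 3, 3),
    volume = 1,
    compartment = c("soma", rep("branch", 5)))
  edges <- data.frame(from = c(1, 2, 2, 3, 4), to = c(2, 3, 4, 5, 6))
  tr <- make_skel_graph(nodes, edges)
  mbt <- identify_major_branches(tr)
  expect_identical(length(unique(mbt$assignment$branch_id)), 1L)
  expect_identical(sort(mbt$assignment$node_id), 2:6)
  # loop touching the soma twice: one deterministic branch, full coverage
  nodes2 <- data.frame(
    z = 0, y = c(0, 1, 1, 1), x = c(0, -1, 0, 1),
    volume = 1,
    compartment = c("soma", "branch", "branch", "branch"))
  edges2 <- data.frame(from = c(1, 1, 2, 3), to = c(2, 4, 3, 4))
  lp <- make_skel_graph(nodes2, edges2)
  mbl <- identify_major_branches(lp)
  expect_identical(sort(mbl$assignment$node_id), 2:4)
  expect_identical(length(unique(mbl$assignment$branch_id)), 1L)
  expect_identical(mbl$entries$entry_node, 2L)
  # no branch nodes: empty partition
  soma_only <- make_skel_graph(
    data.frame(z = 0, y = 0, x = 0, volume = 1, compartment = "soma"),
    data.frame(from = integer(), to = integer()))
  expect_identical(nrow(identify_major_branches(soma_only)$assignment), 0L)
})

test_that("branch cycle count is the circuit rank of the branch subgraph", {
  expect_identical(count_branch_cycles(star_graph()), 0L)
  ring <- make_skel_graph(
    data.frame(z = 0, y = c(0, 1, 1, 0), x = c(0, 0, 1, 1), volume = 1,
               compartment = "branch"),
    data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
  expect_identical(count_branch_cycles(ring), 1L)
  # two triangles sharing one edge: 4 nodes, 5 edges, 1 component -> rank 2
  tri2 <- make_skel_graph(
    data.frame(z = 0, y = c(0, 1, 0, 1), x = c(0, 0.5, 1, 1.5),
               volume = 1, compartment = "branch"),
    data.frame(from = c(1, 2, 1, 2, 3), to = c(2, 3, 3, 4, 4)))
  expect_identical(count_branch_cycles(tri2), 2L)
  # independent check: enumerate the cycle space basis size E - N + C
  expect_identical(5L - 4L + 1L, 2L)
})
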