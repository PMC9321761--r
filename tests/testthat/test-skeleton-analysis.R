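test_that("thinning preserves topology on canonical solids", {
  ball <- generate_binary_phantom("ball", 24, r = 7, center = c(12, 12, 12))
  skb <- lkc_skeletonize(ball)
  expect_true(all(skb$data <= ball$data))          # skeleton inside object
  expect_equal(euler_number(skb), 1L)

  torus <- generate_binary_phantom("torus", 36, R = 10, r_tube = 3)
  skt <- lkc_skeletonize(torus)
  expect_equal(euler_number(skt), 0L)
  g <- skeleton_graph(skt)
  expect_equal(g$beta1, 1L)                        # one independent cycle
  expect_equal(nrow(g$ends), 0)

  empty <- binary_volume(array(FALSE, c(5, 5, 5)))
  expect_false(any(lkc_skeletonize(empty)$data))
})

test_that("a straight cylinder thins to its axis", {
  cyl <- generate_binary_phantom("cylinder", c(25, 25, 56), r = 4, length = 40)
  sk <- lkc_skeletonize(cyl)
  pos <- which(sk$data, arr.ind = TRUE)
  expect_lte(max(abs(pos[, 1] - 1 - 12)), 1)       # within 1 voxel of the axis
  expect_lte(max(abs(pos[, 2] - 1 - 12)), 1)
  g <- skeleton_graph(sk)
  expect_equal(nrow(g$ends), 2)
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$branches), 1)
  expect_equal(label_components(sk)$n_labels, 1L)  # single 26-connected curve
  expect_identical(euler_number(sk), euler_number(cyl))
})

test_that("thinning preserves euler number on random connected blobs", {
  for (seed in 1:6) {
    set.seed(seed + 500)
    a <- array(runif(16^3) < 0.6, c(16, 16, 16))
    comp <- label_components(binary_volume(a))
    if (comp$n_labels == 0) next
    big <- comp$data == which.max(tabulate(comp$data[comp$data > 0]))
    b <- binary_volume(array(big, dim(a)))
    sk <- lkc_skeletonize(b)
    expect_identical(euler_number(sk), euler_number(b),
                     info = paste("seed", seed))
    expect_true(all(sk$data <= b$data))
  }
})

test_that("skeleton graph classifies branches as in the fixtures", {
  # straight segment -> one end-to-end branch
  a <- array(FALSE, c(10, 4, 4)); a[2:9, 2, 2] <- TRUE
  sk <- binary_volume(a); class(sk) <- c("skeleton_volume", class(sk))
  g <- skeleton_graph(sk)
  expect_equal(nrow(g$branches), 1)
  expect_equal(g$branches$type, "end-to-end")
  expect_equal(nrow(g$ends), 2); expect_equal(nrow(g$nodes), 0)
  expect_equal(g$branches$length_mm, 7 * 1e-3)
  # H fixture -> 2 nodes, 4 node-to-end, 1 node-to-node
  h <- fixture_h_skeleton()
  gh <- skeleton_graph(h)
  expect_equal(nrow(gh$nodes), 2)
  expect_equal(nrow(gh$ends), 4)
  expect_equal(sum(gh$branches$type == "node-to-end"), 4)
  expect_equal(sum(gh$branches$type == "node-to-node"), 1)
  expect_equal(gh$beta1, 0L)
  # closed ring -> one self-closing branch, no ends/nodes
  rg <- fixture_ring()
  gr <- skeleton_graph(rg)
  expect_equal(nrow(gr$branches), 1)
  expect_true(gr$branches$is_cycle)
  expect_equal(nrow(gr$ends) + nrow(gr$nodes), 0)
  # isolated voxel -> end-to-end branch of length 0
  iso <- array(FALSE, c(4, 4, 4)); iso[2, 2, 2] <- TRUE
  ski <- binary_volume(iso); class(ski) <- c("skeleton_volume", class(ski))
  gi <- skeleton_graph(ski)
  expect_equal(gi$branches$type, "end-to-end")
  expect_equal(gi$branches$length_mm, 0)
  expect_equal(gi$beta1, 0L)
  # every skeleton voxel is covered by exactly one branch or is a terminal
  cover <- unique(unlist(gh$paths))
  expect_setequal(cover, seq_len(sum(h$data)))
})

test_that("pruning removes short spurs, keeps cycles, and is idempotent", {
  y <- fixture_y_spur()
  expect_identical(prune_skeleton(y, 0)$data, y$data)
  p5 <- prune_skeleton(y, 5)
  expect_equal(sum(p5$data), sum(y$data) - 3)      # only the 3-voxel spur
  g <- skeleton_graph(p5)
  expect_equal(nrow(g$branches), 1)                # merged into one path
  expect_true(all(p5$data <= y$data))              # monotone
  expect_identical(prune_skeleton(p5, 5)$data, p5$data)  # idempotent
  # cycle-only skeletons are never pruned
  rg <- fixture_ring()
  expect_identical(prune_skeleton(rg, 100)$data, rg$data)
})

test_that("connectivity density counts independent cycles per volume", {
  # tree-shaped skeleton (H fixture): zero
  gh <- skeleton_graph(fixture_h_skeleton())
  expect_equal(connectivity_density(gh, 2), 0)
  # one ring in a 1 mm^3 VOI (10^3 voxels at 100 um)
  rg <- fixture_ring(voxel_size = 100)
  gr <- skeleton_graph(rg)
  expect_equal(connectivity_density(gr, voxmorph:::voi_volume_mm3(rg)), 1)
  # two disjoint rings: beta1 additive
  a <- fixture_ring(dim3 = 12)$data
  a2 <- array(FALSE, c(12, 12, 12))
  a2[, , 2] <- a[, , 2]; a2[, , 8] <- a[, , 2]
  two <- binary_volume(a2); class(two) <- c("skeleton_volume", class(two))
  expect_equal(skeleton_graph(two)$beta1, 2L)
  # beta1 == 1 - chi for connected cycle-bearing skeletons (no cavities)
  rgg <- fixture_ring()
  expect_equal(skeleton_graph(rgg)$beta1, 1L - euler_number(rgg))
})

test_that("skeleton graphs export as CSV edge lists and GraphML", {
  tmp <- withr::local_tempdir()
  g <- skeleton_graph(fixture_h_skeleton())
  p <- file.path(tmp, "graph.csv")
  export_skeleton_graph(g, p, graphml_path = file.path(tmp, "graph.graphml"))
  back <- read.csv(p)
  expect_equal(nrow(back), 5)
  expect_true(all(c("type", "length_mm", "x1", "z2") %in% names(back)))
  ig <- igraph::read_graph(file.path(tmp, "graph.graphml"), format = "graphml")
  expect_equal(igraph::ecount(ig), 5)
  expect_equal(igraph::vcount(ig), 6)   # 2 nodes + 4 ends
})
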