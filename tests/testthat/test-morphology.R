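test_that("erosion and dilation match the brute-force SE oracle", {
  se <- structuring_element("cube", 3)
  for (seed in 1:8) {
    a <- random_mask(seed, dmax = 10)
    b <- binary_volume(a)
    expect_identical(erode(b, se)$data, oracle_morph(a, se$offsets, TRUE),
                     info = paste("erode seed", seed))
    expect_identical(dilate(b, se)$data, oracle_morph(a, se$offsets, FALSE),
                     info = paste("dilate seed", seed))
  }
})

test_that("erosion/dilation basics: extensivity, duality, ball SE", {
  empty <- binary_volume(array(FALSE, c(8, 8, 8)))
  expect_false(any(erode(empty)$data))
  full <- binary_volume(array(TRUE, c(8, 8, 8)))
  expect_true(all(dilate(full)$data))
  one <- array(FALSE, c(9, 9, 9)); one[5, 5, 5] <- TRUE
  d <- dilate(binary_volume(one), 3)
  expect_equal(sum(d$data), 27)  # 3^3 block
  expect_true(all(d$data[4:6, 4:6, 4:6]))
  # duality on random masks (symmetric SE): dilate(X) == !erode(!X)
  for (seed in 21:25) {
    a <- random_mask(seed, dmax = 9)
    expect_identical(dilate(binary_volume(a))$data,
                     !erode(binary_volume(!a))$data)
  }
  # erosion of a ball shrinks it by about the SE radius
  ball <- generate_binary_phantom("ball", 24, r = 8,
                                  center = c(12, 12, 12))
  er <- erode(ball, structuring_element("cube", 3))
  expect_true(all(er$data[ball$data == FALSE] == FALSE))   # anti-extensive
  inner <- generate_binary_phantom("ball", 24, r = 6, center = c(12, 12, 12))
  expect_true(all(er$data[inner$data]))                    # contains r - 2 ball
})

test_that("opening and closing are idempotent", {
  b <- generate_binary_phantom("boolean_balls", 32, r = 4, vv = 0.35, seed = 9)
  op <- opening(b, 3)
  expect_true(all(op$data <= b$data))                      # anti-extensive
  expect_identical(opening(op, 3)$data, op$data)
  cl <- closing(b, 3)
  expect_true(all(cl$data >= b$data))                      # extensive
  expect_identical(closing(cl, 3)$data, cl$data)
})

test_that("chamfer distance: face neighbours, slab mid-plane, metric bounds", {
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  expect_equal(max(chamfer_distance(binary_volume(a))$data), 1)
  slab <- array(FALSE, c(5, 5, 13)); slab[, , 2:12] <- TRUE
  ds <- chamfer_distance(binary_volume(slab))
  expect_equal(max(ds$data), 6)
  expect_true(all(ds$data[!slab] == 0))
  expect_true(all(ds$data[slab] > 0))
  expect_error(chamfer_distance(binary_volume(array(TRUE, c(3, 3, 3)))),
               "background")
  # metric bounds of the (3,4,5)/3 chamfer against exact Euclidean distance
  for (seed in 31:38) {
    a <- random_mask(seed, dmax = 8)
    if (!any(a) || all(a)) next
    ch <- chamfer_distance(binary_volume(a))$data
    eu <- oracle_euclid(a)
    sel <- a
    expect_true(all(ch[sel] >= 0.94 * eu[sel] - 1e-9),
                info = paste("lower bound seed", seed))
    expect_true(all(ch[sel] <= 1.11 * eu[sel] + 1e-9),
                info = paste("upper bound seed", seed))
  }
})

test_that("h-minima suppresses shallow pits and only those", {
  # 1-D profile embedded in 3D: pits of depth 2 and 10
  prof <- c(10, 10, 8, 10, 10, 10, 0, 10, 10)
  vol <- distance_volume(array(rep(prof, each = 9), c(3, 3, length(prof))))
  out <- h_minima(vol, 4)
  # bounds: f <= out <= f + h
  expect_true(all(out$data >= vol$data - 1e-12))
  expect_true(all(out$data <= vol$data + 4 + 1e-12))
  # the shallow pit (depth 2) is filled flat; the deep pit remains a minimum
  expect_equal(out$data[2, 2, 3], 10)
  expect_lt(out$data[2, 2, 7], min(out$data[2, 2, 6], out$data[2, 2, 8]))
  # h = 0 is the identity; a constant field stays flat (no relief appears)
  expect_identical(h_minima(vol, 0)$data, vol$data)
  const <- distance_volume(array(5, c(4, 4, 4)))
  outc <- h_minima(const, 3)$data
  expect_equal(diff(range(outc)), 0)
  expect_true(all(outc >= 5 & outc <= 8))
  expect_error(h_minima(vol, -1), "non-negative")
})

test_that("watershed separates basins and partitions the mask", {
  # two disjoint balls -> 2 labels coincident with the balls
  two <- fixture_two_balls(r = 6, gap = 20)
  dist <- chamfer_distance(two)
  ws <- watershed(negate_relief(dist), two)
  expect_equal(ws$n_labels, 2L)
  expect_true(all((ws$data > 0) == two$data))  # partition of the mask
  comp <- label_components(two)
  tab <- table(ws$data[two$data], comp$data[two$data])
  expect_equal(sum(tab > 0), 2)                # labels match the components
  # two overlapping balls split near the neck after h-minima
  ov <- fixture_two_balls(r = 10, gap = 16)
  rel <- h_minima(negate_relief(chamfer_distance(ov)), 2)
  ws2 <- watershed(rel, ov)
  expect_equal(ws2$n_labels, 2L)
  expect_true(all((ws2$data > 0) == ov$data))
  # the split plane falls near the neck (centres 16 apart around x mid)
  w <- which(ws2$data == 1L, arr.ind = TRUE)
  w2 <- which(ws2$data == 2L, arr.ind = TRUE)
  expect_true(abs(mean(w[, 1]) - mean(w2[, 1])) > 10)
  # single ball -> one label covering it
  one <- generate_binary_phantom("ball", 24, r = 7)
  ws3 <- watershed(negate_relief(chamfer_distance(one)), one)
  expect_equal(ws3$n_labels, 1L)
  # empty mask -> empty labelling
  e <- binary_volume(array(FALSE, c(4, 4, 4)))
  wse <- watershed(distance_volume(array(0, c(4, 4, 4))), e)
  expect_equal(wse$n_labels, 0L)
})

test_that("connected components equal the flood-fill oracle at 6/18/26", {
  for (seed in 41:48) {
    a <- random_mask(seed, dmax = 10, p = runif(1, 0.15, 0.5))
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(binary_volume(a), conn)
      ref <- oracle_components(a, conn)
      expect_equal(got$n_labels, ref$n,
                   info = paste("seed", seed, "conn", conn))
      # same partition up to label names
      if (ref$n > 0) {
        tab <- table(got$data[a], ref$labels[a])
        expect_equal(sum(tab > 0), ref$n)
      }
    }
  }
  # vertex-sharing voxels: one component at 26, two at 6
  a <- array(FALSE, c(4, 4, 4)); a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE
  expect_equal(label_components(binary_volume(a), 26)$n_labels, 1L)
  expect_equal(label_components(binary_volume(a), 6)$n_labels, 2L)
  expect_equal(label_components(binary_volume(array(FALSE, c(3, 3, 3))))$n_labels, 0L)
})
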