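# Hand-constructed skeleton fixtures.  All lines meet junctions through
# diagonal arms so that every junction is a single voxel under
# 26-connectivity (straight orthogonal crossings create junction clusters).

# "H": two 3-armed junctions joined by a horizontal bar ->
# 2 nodes, 4 node-to-end branches, 1 node-to-node branch
fixture_h_skeleton <- function(voxel_size = 1) {
  a <- array(FALSE, c(12, 12, 3))
  put <- function(x, y) a[x + 1, y + 1, 2] <<- TRUE
  put(6, 6); put(2, 6)                      # junctions J1, J2
  for (p in list(c(7, 7), c(8, 8), c(9, 9))) put(p[1], p[2])   # J1 arm up
  for (p in list(c(7, 5), c(8, 4), c(9, 3))) put(p[1], p[2])   # J1 arm down
  for (p in list(c(5, 6), c(4, 6), c(3, 6))) put(p[1], p[2])   # bar
  for (p in list(c(1, 7), c(0, 8))) put(p[1], p[2])            # J2 arm up
  for (p in list(c(1, 5), c(0, 4))) put(p[1], p[2])            # J2 arm down
  sk <- binary_volume(a, voxel_size)
  class(sk) <- c("skeleton_volume", class(sk))
  sk
}

# "Y" with one short spur: junction at (5,5); two long arms and one 3-voxel
# spur (the spur is strictly shorter than the Table-style pruning length 5)
fixture_y_spur <- function(voxel_size = 1) {
  a <- array(FALSE, c(13, 13, 3))
  put <- function(x, y) a[x + 1, y + 1, 2] <<- TRUE
  put(5, 5)
  for (x in 0:4) put(x, 5)                                   # long arm left
  for (p in list(c(6, 6), c(7, 7), c(8, 8), c(9, 9), c(10, 10)))
    put(p[1], p[2])                                          # long arm up
  for (p in list(c(6, 4), c(7, 3), c(8, 2))) put(p[1], p[2]) # 3-voxel spur
  sk <- binary_volume(a, voxel_size)
  class(sk) <- c("skeleton_volume", class(sk))
  sk
}

# closed diamond ring (degree 2 everywhere under 26-adjacency; a square
# ring would have corner triangles): voxels with |x-c| + |y-c| = R
fixture_ring <- function(R = 3, dim3 = 10, voxel_size = 1) {
  a <- array(FALSE, c(dim3, dim3, dim3))
  cc <- dim3 %/% 2
  for (x in seq_len(dim3)) for (y in seq_len(dim3))
    if (abs(x - cc) + abs(y - cc) == R) a[x, y, 2] <- TRUE
  sk <- binary_volume(a, voxel_size)
  class(sk) <- c("skeleton_volume", class(sk))
  sk
}

# two overlapping digitized balls (radius r, centres `gap` voxels apart on x)
fixture_two_balls <- function(r = 10, gap = 16, voxel_size = 1) {
  shape <- c(gap + 2 * r + 12, 2 * r + 12, 2 * r + 12)
  g <- list(x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
            z = seq_len(shape[3]) - 1)
  cy <- (shape[2] - 1) / 2; cz <- (shape[3] - 1) / 2
  cx1 <- (shape[1] - 1 - gap) / 2; cx2 <- cx1 + gap
  d1 <- outer(outer((g$x - cx1)^2, (g$y - cy)^2, "+"), (g$z - cz)^2, "+") <= r^2
  d2 <- outer(outer((g$x - cx2)^2, (g$y - cy)^2, "+"), (g$z - cz)^2, "+") <= r^2
  binary_volume(d1 | d2, voxel_size)
}
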