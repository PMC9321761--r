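# Brute-force reference implementations, independent of the package's
# kernels: plain loops and exhaustive enumeration on small volumes.

oracle_reflect <- function(i, n) {
  if (n == 1L) return(1L)
  # 1-based half-sample reflection
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# median filter by explicit neighbourhood collection and sort
oracle_median <- function(a, width) {
  d <- dim(a)
  r <- width %/% 2L
  out <- a
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    vals <- integer(0)
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      vals <- c(vals, a[oracle_reflect(i + dx, d[1]),
                       oracle_reflect(j + dy, d[2]),
                       oracle_reflect(k + dz, d[3])])
    }
    out[i, j, k] <- sort(vals)[(length(vals) + 1L) %/% 2L]
  }
  out
}

# exhaustive Otsu: maximise between-class variance over every candidate
# threshold, computed from the raw values (no cumulative-sum shortcut);
# reports the midpoint of the first maximal plateau
oracle_otsu <- function(vals, n_levels) {
  n <- length(vals)
  v <- rep(-Inf, n_levels)
  for (t in 0:(n_levels - 1L)) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) next
    v[t + 1L] <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
  }
  t_lo <- which.max(v)
  t_hi <- t_lo
  while (t_hi < n_levels && v[t_hi + 1L] == v[t_lo]) t_hi <- t_hi + 1L
  as.integer((t_lo + t_hi) %/% 2L - 1L)
}

# erosion/dilation by explicit structuring-element test
oracle_morph <- function(a, offsets, erosion) {
  d <- dim(a)
  out <- array(NA, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    hits <- logical(nrow(offsets))
    for (r in seq_len(nrow(offsets))) {
      hits[r] <- a[oracle_reflect(i + offsets[r, 1], d[1]),
                   oracle_reflect(j + offsets[r, 2], d[2]),
                   oracle_reflect(k + offsets[r, 3], d[3])]
    }
    out[i, j, k] <- if (erosion) all(hits) else any(hits)
  }
  out
}

conn_offsets_r <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  man <- rowSums(abs(off))
  if (connectivity == 6) off[man == 1, , drop = FALSE]
  else if (connectivity == 18) off[man <= 2, , drop = FALSE]
  else off
}

# connected components by breadth-first flood fill
oracle_components <- function(a, connectivity) {
  d <- dim(a)
  off <- conn_offsets_r(connectivity)
  lab <- array(0L, d)
  nl <- 0L
  idx <- which(a)
  for (s in idx) {
    if (lab[s] != 0L) next
    nl <- nl + 1L
    queue <- s; lab[s] <- nl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pc <- arrayInd(p, d)
      for (r in seq_len(nrow(off))) {
        q <- pc + off[r, ]
        if (any(q < 1L) || any(q > d)) next
        ql <- q[1] + d[1] * (q[2] - 1L) + d[1] * d[2] * (q[3] - 1L)
        if (a[ql] && lab[ql] == 0L) { lab[ql] <- nl; queue <- c(queue, ql) }
      }
    }
  }
  list(labels = lab, n = nl)
}

# Euler characteristic by direct enumeration of the closed cubical complex:
# voxel (i,j,k) contributes the 27 double-coordinate cells (2i+a, 2j+b, 2k+c),
# a,b,c in 0..2; a cell with o odd coordinates has dimension o and
# contributes (-1)^o to chi.
oracle_euler <- function(a) {
  w <- which(a, arr.ind = TRUE)
  if (!nrow(w)) return(0L)
  sub <- as.matrix(expand.grid(a = 0:2, b = 0:2, c = 0:2))
  cells <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r) {
    cbind(2L * w[, 1] + sub[r, 1], 2L * w[, 2] + sub[r, 2],
          2L * w[, 3] + sub[r, 3])
  }))
  cells <- unique(cells)
  o <- rowSums(cells %% 2L)
  as.integer(sum((-1L)^o))
}

# exact Euclidean distance to the nearest background voxel (all pairs)
oracle_euclid <- function(a) {
  d <- dim(a)
  obj <- which(a, arr.ind = TRUE)
  bg <- which(!a, arr.ind = TRUE)
  out <- array(0, d)
  for (r in seq_len(nrow(obj))) {
    dd <- sqrt(colSums((t(bg) - obj[r, ])^2))
    out[obj[r, 1], obj[r, 2], obj[r, 3]] <- min(dd)
  }
  out
}

# exact optimal 1-D k-clustering of weighted levels by dynamic programming
# (optimal clusters of sorted scalar data are contiguous)
oracle_kmeans_wss <- function(lev, cnt, k) {
  n <- length(lev)
  cw <- cumsum(cnt); cs <- cumsum(cnt * lev); cq <- cumsum(cnt * lev^2)
  seg_cost <- function(i, j) {  # levels i..j as one cluster
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    q <- cq[j] - if (i > 1) cq[i - 1] else 0
    q - s^2 / w
  }
  D <- matrix(Inf, k, n)
  for (j in seq_len(n)) D[1, j] <- seg_cost(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n)
    D[m, j] <- min(vapply(m:j, function(i)
      D[m - 1, i - 1] + seg_cost(i, j), numeric(1)))
  D[k, n]
}

random_mask <- function(seed, dmax = 12, p = NULL) {
  set.seed(seed)
  d <- sample(3:dmax, 3, replace = TRUE)
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  array(runif(prod(d)) < p, dim = d)
}

random_gray <- function(seed, dmax = 12, levels = 255) {
  set.seed(seed)
  d <- sample(3:dmax, 3, replace = TRUE)
  array(sample.int(levels + 1L, prod(d), replace = TRUE) - 1L, dim = d)
}
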