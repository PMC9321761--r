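# Deterministic, seedable synthetic volumes with analytically known
# properties: the test and acceptance substrate.  Digitisation rule: a voxel
# is object iff its centre (integer 0-based coordinates) satisfies the
# implicit solid inequality — no antialiasing, so voxel-count oracles are
# exact to enumerate.  Every phantom carries its analytic ground truth in
# attr(, "ground_truth").

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

coord_grids <- function(shape) {
  list(x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
       z = seq_len(shape[3]) - 1)
}

sq_dist3 <- function(g, c) {
  outer(outer((g$x - c[1])^2, (g$y - c[2])^2, "+"), (g$z - c[3])^2, "+")
}

#' Generate a binary phantom
#'
#' Implicit-solid phantoms on a voxel grid.  Supported kinds:
#' \describe{
#'   \item{ball}{solid ball; `r`, optional `center` (default volume centre).}
#'   \item{shell}{hollow spherical shell; `r_outer`, `r_inner`.}
#'   \item{torus}{solid torus, ring in the xy-plane; ring radius `R`, tube
#'     radius `r_tube`.}
#'   \item{cylinder}{bundle of `n` parallel solid cylinders along z with caps
#'     inside the volume; `r`, `length`, `n`.}
#'   \item{slab_stack}{parallel plates perpendicular to z; `thickness` and
#'     `period` in voxels.}
#'   \item{boolean_balls}{Poisson Boolean model of balls radius `r` with
#'     periodic wrap-around (stationary); intensity from the target coverage
#'     `vv` via `1 - exp(-lambda * v)`.}
#'   \item{ellipsoid_field}{`n` ellipsoids with semi-axes `a >= b >= c`,
#'     orientations isotropic unless `alignment_axis` is given.}
#' }
#'
#' @param kind Phantom kind (see Details).
#' @param shape Output dimensions, single integer or triple.
#' @param voxel_size Voxel edge, micrometres.
#' @param seed RNG seed (only the random kinds consume it); identical
#'   `kind`/parameters/seed give bitwise-identical output.
#' @param ... Kind-specific geometric parameters, in voxels.
#' @return A [binary_volume()] with an analytic `ground_truth` attribute.
#' @export
generate_binary_phantom <- function(kind, shape, voxel_size = 1, seed = 1, ...) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  p <- list(...)
  g <- coord_grids(shape)
  ctr <- (shape - 1) / 2
  vm <- voxel_size / 1000
  truth <- list(kind = kind)
  mask <- switch(
    kind,
    ball = {
      r <- p$r
      if (is.null(r) || r <= 0) stop("ball needs r > 0", call. = FALSE)
      cen <- if (is.null(p$center)) ctr else p$center
      truth$volume_vox <- 4 / 3 * pi * r^3
      truth$surface_vox2 <- 4 * pi * r^2
      truth$surface_mm2 <- 4 * pi * (r * vm)^2
      truth$mean_curvature_mm <- 4 * pi * r * vm
      truth$chi <- 1L
      sq_dist3(g, cen) <= r^2
    },
    shell = {
      ro <- p$r_outer; ri <- p$r_inner
      if (is.null(ro) || is.null(ri) || ri <= 0 || ro <= ri)
        stop("shell needs r_outer > r_inner > 0", call. = FALSE)
      truth$chi <- 2L
      d2 <- sq_dist3(g, ctr)
      d2 <= ro^2 & d2 > ri^2
    },
    torus = {
      R <- p$R; rt <- p$r_tube
      if (is.null(R) || is.null(rt) || rt <= 0 || R <= rt)
        stop("torus needs R > r_tube > 0", call. = FALSE)
      truth$chi <- 0L
      rho <- sqrt(outer((g$x - ctr[1])^2, (g$y - ctr[2])^2, "+"))
      arr <- outer((rho - R)^2, (g$z - ctr[3])^2, "+")
      arr <= rt^2
    },
    cylinder = {
      r <- p$r; len <- p$length; n <- if (is.null(p$n)) 1L else as.integer(p$n)
      if (is.null(r) || is.null(len) || r <= 0 || len <= 0)
        stop("cylinder needs r > 0 and length > 0", call. = FALSE)
      z0 <- ctr[3] - len / 2; z1 <- ctr[3] + len / 2
      # bundle centres on a square grid in xy, snapped to voxel centres so
      # the medial axis of each cylinder is a lattice line
      side <- ceiling(sqrt(n))
      pitch <- min(shape[1], shape[2]) / (side + 1)
      if (pitch <= 2 * r && n > 1L)
        stop("cylinder bundle does not fit: reduce n or r", call. = FALSE)
      cx <- if (n == 1L) round(ctr[1]) else round((seq_len(side)) * pitch)
      cy <- if (n == 1L) round(ctr[2]) else cx
      centres <- expand.grid(cx = cx, cy = cy)[seq_len(n), , drop = FALSE]
      acc <- array(FALSE, dim = shape)
      zin <- g$z >= z0 & g$z <= z1
      for (i in seq_len(n)) {
        d2 <- outer((g$x - centres$cx[i])^2, (g$y - centres$cy[i])^2, "+")
        acc <- acc | outer(d2 <= r^2, zin, "&")
      }
      truth$chi <- as.integer(n)
      truth$axis <- c(0, 0, 1)
      acc
    },
    slab_stack = {
      t <- p$thickness; per <- p$period
      if (is.null(t) || is.null(per) || t <= 0 || per <= t)
        stop("slab_stack needs period > thickness > 0", call. = FALSE)
      # offset keeps plate faces away from the volume border so the surface
      # estimator sees both faces of every plate
      off <- if (is.null(p$offset)) floor((per - t) / 2) else p$offset
      truth$BvTv <- t / per
      truth$TbTh_mm <- t * vm
      truth$TbSp_mm <- (per - t) * vm
      zin <- ((g$z - off) %% per) < t & g$z >= off
      outer(array(TRUE, dim = shape[1:2]), zin, "&")
    },
    boolean_balls = {
      r <- p$r; vv <- p$vv
      if (is.null(r) || is.null(vv) || r <= 0 || vv <= 0 || vv >= 1)
        stop("boolean_balls needs r > 0 and vv in (0, 1)", call. = FALSE)
      vbar <- 4 / 3 * pi * r^3
      lambda <- -log(1 - vv) / vbar       # coverage 1 - exp(-lambda * vbar)
      truth$vv_expected <- vv
      truth$lambda <- lambda
      N <- prod(shape)
      with_seed(seed, {
        nb <- rpois(1, lambda * N)
        acc <- array(FALSE, dim = shape)
        rr <- ceiling(r)
        for (i in seq_len(nb)) {
          cen <- runif(3) * shape
          xs <- floor(cen[1] - rr):ceiling(cen[1] + rr)
          ys <- floor(cen[2] - rr):ceiling(cen[2] + rr)
          zs <- floor(cen[3] - rr):ceiling(cen[3] + rr)
          d2 <- outer(outer((xs - cen[1])^2, (ys - cen[2])^2, "+"),
                      (zs - cen[3])^2, "+")
          sel <- which(d2 <= r^2, arr.ind = TRUE)
          if (!nrow(sel)) next
          ix <- (xs[sel[, 1]] %% shape[1]) + 1L   # periodic wrap
          iy <- (ys[sel[, 2]] %% shape[2]) + 1L
          iz <- (zs[sel[, 3]] %% shape[3]) + 1L
          acc[cbind(ix, iy, iz)] <- TRUE
        }
        acc
      })
    },
    ellipsoid_field = {
      a <- p$a; b <- p$b; cc <- p$c; n <- if (is.null(p$n)) 10L else as.integer(p$n)
      if (is.null(a) || is.null(b) || is.null(cc) || cc <= 0 || b < cc || a < b)
        stop("ellipsoid_field needs semi-axes a >= b >= c > 0", call. = FALSE)
      align <- p$alignment_axis
      truth$n <- n
      if (!is.null(align)) truth$axis <- align / sqrt(sum(align^2))
      with_seed(seed, {
        acc <- array(FALSE, dim = shape)
        rr <- ceiling(a)
        for (i in seq_len(n)) {
          cen <- runif(3) * (shape - 2 * rr) + rr
          if (is.null(align)) {
            Q <- qr.Q(qr(matrix(rnorm(9), 3)))
          } else {
            w <- align / sqrt(sum(align^2))
            u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
            v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
                   w[1] * u[2] - w[2] * u[1])
            Q <- cbind(w, u, v)        # long axis along the alignment axis
          }
          xs <- max(0, floor(cen[1] - rr)):min(shape[1] - 1, ceiling(cen[1] + rr))
          ys <- max(0, floor(cen[2] - rr)):min(shape[2] - 1, ceiling(cen[2] + rr))
          zs <- max(0, floor(cen[3] - rr)):min(shape[3] - 1, ceiling(cen[3] + rr))
          gr <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
          rel <- sweep(gr, 2, cen)
          loc <- rel %*% Q
          inside <- (loc[, 1] / a)^2 + (loc[, 2] / b)^2 + (loc[, 3] / cc)^2 <= 1
          if (any(inside))
            acc[gr[inside, , drop = FALSE] + 1L] <- TRUE
        }
        acc
      })
    },
    stop("unknown phantom kind: ", kind, call. = FALSE)
  )
  out <- binary_volume(mask, voxel_size)
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a gray-level phantom
#'
#' Assigns a mean gray level per phase of a binary or labelled geometry
#' phantom, adds Gaussian noise of standard deviation `sigma`, and clips and
#' rounds to the dtype range.  With a binary base and two means this is the
#' bimodal gray phantom used for threshold testing.
#'
#' @param base A [binary_volume()] (two phases) or [label_volume()]
#'   (`n_labels + 1` phases including background 0).
#' @param means Phase mean gray levels, one per phase in label order
#'   (background first).
#' @param sigma Gaussian noise standard deviation in gray levels.
#' @param seed RNG seed (used only when `sigma > 0`).
#' @param bits Output bit depth, 8 or 16.
#' @return A [gray_volume()].
#' @export
generate_gray_phantom <- function(base, means, sigma = 0, seed = 1, bits = 8) {
  maxg <- 2^bits - 1
  if (any(means < 0) || any(means > maxg))
    stop("phase means outside the ", bits, "-bit range", call. = FALSE)
  if (inherits(base, "binary_volume")) {
    phase <- array(as.integer(base$data), dim = dim(base$data))
    nphase <- 2L
  } else if (inherits(base, "label_volume")) {
    phase <- base$data
    nphase <- max(phase) + 1L
  } else stop("base must be a binary or label volume", call. = FALSE)
  if (length(means) != nphase)
    stop("need ", nphase, " phase means, got ", length(means), call. = FALSE)
  vals <- means[phase + 1L]
  if (sigma > 0)
    vals <- with_seed(seed, vals + rnorm(length(vals), sd = sigma))
  vals <- pmin(pmax(round(vals), 0), maxg)
  gray_volume(array(as.integer(vals), dim = dim(phase)),
              voxel_size = base$voxel_size, bits = bits)
}

#' Ground truth of a phantom
#'
#' @param phantom A phantom from [generate_binary_phantom()].
#' @return The analytic ground-truth list recorded at generation time.
#' @export
phantom_truth <- function(phantom) attr(phantom, "ground_truth")
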