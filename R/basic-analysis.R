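# "Basic Analysis": Minkowski functionals (volume density, specific surface,
# specific integral of mean curvature, specific Euler characteristic) and
# mean-intercept-length fabric anisotropy (isotropy and elongation indices).
#
# All estimators are linear functionals of local 2x2x2 voxel configuration
# counts, evaluated as vectorised shifted-array statistics:
#  - Euler characteristic: exact closed-cubical-complex count chi = V-E+F-C
#    (26-object / 6-background convention: solid ball 1, torus 0, shell 2);
#  - surface area: discrete Crofton quadrature over the 13 lattice directions
#    of the 2x2x2 cell with Ohser-Muecklich spherical weights;
#  - integral of mean curvature: 2*pi times the section Euler density averaged
#    over the three axis-aligned section stacks.

# accumulate "any object voxel adjacent" over a set of binary shifts
shift_or_count <- function(a, shifts) {
  d <- dim(a)
  span <- apply(abs(shifts), 2, max)
  acc <- array(FALSE, dim = d + span)
  for (r in seq_len(nrow(shifts))) {
    s <- shifts[r, ]
    acc[s[1] + seq_len(d[1]), s[2] + seq_len(d[2]), s[3] + seq_len(d[3])] <-
      acc[s[1] + seq_len(d[1]), s[2] + seq_len(d[2]), s[3] + seq_len(d[3])] | a
  }
  sum(acc)
}

shifts_grid <- function(dx, dy, dz) as.matrix(expand.grid(dx, dy, dz))

#' Euler characteristic of a binary volume
#'
#' Exact integer Euler characteristic of the union of closed unit voxel cubes
#' (chi = vertices - edges + faces - cubes), which realises 26-connectivity
#' for the object and 6-connectivity for the background.  Everything outside
#' the volume is background.
#'
#' @param bin A [binary_volume()].
#' @return Integer Euler characteristic.
#' @export
euler_number <- function(bin) {
  a <- bin$data
  V  <- shift_or_count(a, shifts_grid(0:1, 0:1, 0:1))
  Ex <- shift_or_count(a, shifts_grid(0,   0:1, 0:1))
  Ey <- shift_or_count(a, shifts_grid(0:1, 0,   0:1))
  Ez <- shift_or_count(a, shifts_grid(0:1, 0:1, 0))
  Fxy <- shift_or_count(a, shifts_grid(0, 0, 0:1))
  Fxz <- shift_or_count(a, shifts_grid(0, 0:1, 0))
  Fyz <- shift_or_count(a, shifts_grid(0:1, 0, 0))
  C <- sum(a)
  as.integer(V - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C)
}

# summed 2D Euler characteristic of all sections perpendicular to `axis`
# (closed-square complex, 8-connected foreground within each section)
euler2d_stack <- function(a, axis) {
  perm <- switch(axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2), `3` = c(1, 2, 3))
  b <- aperm(a, perm)  # sections are b[, , k]
  V  <- shift_or_count(b, shifts_grid(0:1, 0:1, 0))
  Ex <- shift_or_count(b, shifts_grid(0,   0:1, 0))
  Ey <- shift_or_count(b, shifts_grid(0:1, 0,   0))
  F  <- sum(b)
  V - (Ex + Ey) + F
}

# the 13 lattice directions of the 2x2x2 cell with Ohser-Muecklich weights
crofton_directions <- function() {
  d <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  w <- c(rep(0.045778, 3), rep(0.036981, 6), rep(0.035196, 4))
  list(dirs = d, weights = w / sum(w))
}

# boundary crossings and sampled pair count along a lattice offset,
# minus-sampling: only voxel pairs fully inside the volume are counted
crossings_along <- function(a, s) {
  d <- dim(a)
  ix <- if (s[1] >= 0) seq_len(d[1] - s[1]) else seq(1 - s[1], d[1])
  iy <- if (s[2] >= 0) seq_len(d[2] - s[2]) else seq(1 - s[2], d[2])
  iz <- if (s[3] >= 0) seq_len(d[3] - s[3]) else seq(1 - s[3], d[3])
  a1 <- a[ix, iy, iz, drop = FALSE]
  a2 <- a[ix + s[1], iy + s[2], iz + s[3], drop = FALSE]
  c(crossings = sum(a1 != a2), pairs = length(a1))
}

#' Volume density
#'
#' Fraction of object voxels in the VOI (`VV`); for a pore mask this is the
#' porosity.
#'
#' @param bin A [binary_volume()].
#' @return A number in 0..1.
#' @export
volume_density <- function(bin) mean(bin$data)

#' Minkowski functionals
#'
#' Surface area, integral of mean curvature and Euler characteristic of the
#' object phase, as totals (mm^2, mm, dimensionless) and as densities per VOI
#' volume (`SV` mm^-1, `MV` mm^-2, `chi_v` mm^-3).
#'
#' @param bin A [binary_volume()].
#' @return A list with `surface_area_mm2`, `mean_curvature_mm`, `euler`,
#'   `SV`, `MV`, `chi_v`.
#' @export
minkowski_functionals <- function(bin) {
  a <- bin$data
  vm <- voxel_mm(bin)
  Vtot <- voi_volume_mm3(bin)
  cd <- crofton_directions()
  IL <- numeric(nrow(cd$dirs))
  for (i in seq_len(nrow(cd$dirs))) {
    s <- cd$dirs[i, ]
    cr <- crossings_along(a, s)
    steplen <- sqrt(sum(s^2)) * vm
    IL[i] <- if (cr["pairs"] > 0) cr["crossings"] / (cr["pairs"] * steplen) else 0
  }
  SV <- 2 * sum(cd$weights * IL)              # stereology: S_V = 2 <I_L>
  chi2d <- mean(vapply(1:3, function(ax) euler2d_stack(a, ax), numeric(1)))
  M_tot <- 2 * pi * chi2d * vm                # M = 2*pi * integral of chi_A
  chi <- euler_number(bin)
  list(surface_area_mm2 = SV * Vtot,
       mean_curvature_mm = M_tot,
       euler = chi,
       SV = SV,
       MV = M_tot / Vtot,
       chi_v = chi / Vtot)
}

#' Full basic analysis
#'
#' Convenience wrapper returning the six indices of the basic analysis
#' report: `VV`, `SV` (mm^-1), `MV` (mm^-2), `chi_v` (mm^-3) and the MIL
#' anisotropy indices `I` and `EA`.
#'
#' @param bin A [binary_volume()].
#' @param n_directions,line_spacing,seed Passed to [mil_fabric()]; anisotropy
#'   indices are `NA` if the MIL fit is infeasible (e.g. empty phase).
#' @return A named list.
#' @export
basic_analysis <- function(bin, n_directions = 512, line_spacing = 2, seed = 1) {
  mk <- minkowski_functionals(bin)
  anis <- list(I = NA_real_, EA = NA_real_)
  if (any(bin$data) && !all(bin$data)) {
    fab <- tryCatch(mil_fabric(bin, n_directions, line_spacing, seed),
                    error = function(e) NULL)
    if (!is.null(fab)) anis <- anisotropy_indices(fab)
  }
  list(VV = volume_density(bin), SV = mk$SV, MV = mk$MV, chi_v = mk$chi_v,
       I = anis$I, EA = anis$EA,
       surface_area_mm2 = mk$surface_area_mm2,
       mean_curvature_mm = mk$mean_curvature_mm, euler = mk$euler)
}

# quasi-uniform unit directions: spherical Fibonacci lattice, optionally
# randomly rotated (seeded) for sampling-stability studies
fibonacci_directions <- function(n, seed = NULL) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    d <- d %*% Q
  }
  d
}

#' MIL fabric tensor
#'
#' Mean-intercept-length analysis: for each of `n_directions` quasi-uniform
#' directions (spherical Fibonacci lattice, randomly rotated under `seed`),
#' parallel test lines spaced `line_spacing` voxels apart are traced through
#' the VOI; MIL(w) = total sampled line length / number of
#' object-background crossings.  The symmetric fabric matrix H is fitted by
#' least squares to 1/MIL(w)^2 = w' H w and the MIL ellipsoid semi-axes are
#' the eigenvalue-derived lengths m1 >= m2 >= m3.
#'
#' @param bin A [binary_volume()] with both phases non-empty.
#' @param n_directions Number of test directions (default 512).
#' @param line_spacing Transverse line spacing in voxels (default 2).
#' @param seed Seed for the random rotation of the direction lattice.
#' @return A `fabric_tensor`: `H`, `mil_axes` (mm, descending),
#'   `axis_directions` (unit columns matching `mil_axes`), `directions_used`.
#' @export
mil_fabric <- function(bin, n_directions = 512, line_spacing = 2, seed = 1) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$data) || all(bin$data))
    stop("MIL needs both object and background voxels", call. = FALSE)
  dirs <- fibonacci_directions(n_directions, seed)
  tr <- cpp_mil_trace(as.logical(bin$data), dim(bin$data), dirs,
                      as.numeric(line_spacing), 0.5)
  ok <- tr[, 2] > 0 & tr[, 1] > 0
  if (any(!ok))
    warning(sum(!ok), " direction(s) with zero crossings dropped")
  if (sum(ok) < 9)
    stop("fewer than 9 usable directions: MIL fit underdetermined", call. = FALSE)
  mil <- tr[ok, 1] / tr[ok, 2] * voxel_mm(bin)   # mm
  w <- dirs[ok, , drop = FALSE]
  X <- cbind(w[, 1]^2, w[, 2]^2, w[, 3]^2,
             2 * w[, 1] * w[, 2], 2 * w[, 1] * w[, 3], 2 * w[, 2] * w[, 3])
  y <- 1 / mil^2
  b <- solve(crossprod(X), crossprod(X, y))
  H <- matrix(c(b[1], b[4], b[5],
                b[4], b[2], b[6],
                b[5], b[6], b[3]), 3, 3)
  e <- eigen(H, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("degenerate fabric tensor (non-positive eigenvalue)", call. = FALSE)
  axes <- 1 / sqrt(e$values)          # eigen() sorts values decreasing,
  ordd <- order(axes, decreasing = TRUE)  # so axes come out ascending
  structure(list(H = H, mil_axes = axes[ordd],
                 axis_directions = e$vectors[, ordd, drop = FALSE],
                 directions_used = sum(ok)),
            class = "fabric_tensor")
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat("<fabric_tensor> MIL semi-axes (mm):",
      paste(signif(x$mil_axes, 5), collapse = " >= "), "\n")
  cat("  directions used:", x$directions_used, "\n")
  invisible(x)
}

#' Isotropy and elongation indices
#'
#' Benn-style indices on the sorted MIL ellipsoid axes m1 >= m2 >= m3:
#' isotropy I = m3/m1 (1 for a perfectly isotropic fabric) and elongation
#' EA = 1 - m2/m1 (0 for no preferred elongation).
#'
#' @param fab A `fabric_tensor` from [mil_fabric()], or a numeric vector of
#'   three MIL axes.
#' @return A list with `I` and `EA`, both in 0..1.
#' @export
anisotropy_indices <- function(fab) {
  m <- if (inherits(fab, "fabric_tensor")) fab$mil_axes
       else sort(as.numeric(fab), decreasing = TRUE)
  if (length(m) != 3L || any(!is.finite(m)) || any(m <= 0))
    stop("degenerate fabric tensor", call. = FALSE)
  list(I = m[3] / m[1], EA = 1 - m[2] / m[1])
}
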