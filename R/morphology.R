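# Binary morphology, chamfer distance transform, H-minima suppression,
# seeded morphological watershed, connected-component labelling.
#
# Connectivity convention (used package-wide, including Euler and skeleton
# code): object 26-connected, background 6-connected — the standard
# complementary pair that avoids topological paradoxes.

#' Structuring element
#'
#' @param shape `"cube"` (full width^3 block) or `"ball"` (voxel centres
#'   within Euclidean radius (width - 1)/2).
#' @param width Odd edge/diameter in voxels (>= 1).
#' @return A `structuring_element`: matrix of integer offsets.
#' @export
structuring_element <- function(shape = c("cube", "ball"), width = 3) {
  shape <- match.arg(shape)
  width <- as.integer(width)
  if (is.na(width) || width < 1L || width %% 2L == 0L)
    stop("width must be odd and >= 1, got ", width, call. = FALSE)
  r <- width %/% 2L
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  if (shape == "ball")
    g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
  off <- as.matrix(g)
  storage.mode(off) <- "integer"
  structure(list(shape = shape, width = width, offsets = off),
            class = "structuring_element")
}

as_se <- function(se) {
  if (inherits(se, "structuring_element")) return(se)
  structuring_element("cube", se)
}

#' Binary erosion
#'
#' A voxel stays object iff the structuring element centred there fits
#' entirely inside the object (reflect-padded border).  Anti-extensive.
#'
#' @param bin A [binary_volume()].
#' @param se A [structuring_element()] or an odd cube width.
#' @return The eroded [binary_volume()].
#' @export
erode <- function(bin, se = 3) {
  stopifnot(inherits(bin, "binary_volume"))
  se <- as_se(se)
  out <- cpp_morph(as.logical(bin$data), dim(bin$data), se$offsets, TRUE)
  binary_volume(array(out, dim = dim(bin$data)), bin$voxel_size)
}

#' Binary dilation
#'
#' Dual of [erode()]: a voxel becomes object iff the structuring element
#' centred there hits the object.  Extensive; for the symmetric elements used
#' here `dilate(X) == !erode(!X)` exactly.
#'
#' @inheritParams erode
#' @return The dilated [binary_volume()].
#' @export
dilate <- function(bin, se = 3) {
  stopifnot(inherits(bin, "binary_volume"))
  se <- as_se(se)
  out <- cpp_morph(as.logical(bin$data), dim(bin$data), se$offsets, FALSE)
  binary_volume(array(out, dim = dim(bin$data)), bin$voxel_size)
}

#' Morphological opening / closing
#'
#' @inheritParams erode
#' @return A [binary_volume()].
#' @export
opening <- function(bin, se = 3) dilate(erode(bin, se), se)

#' @rdname opening
#' @export
closing <- function(bin, se = 3) erode(dilate(bin, se), se)

#' Chamfer distance transform
#'
#' Two-pass (3, 4, 5) chamfer propagation; the integer result is divided by
#' the face weight so distances approximate Euclidean voxel distance to the
#' nearest in-volume background voxel (an object voxel face-adjacent to
#' background gets distance 1).
#'
#' @param bin A [binary_volume()] with at least one background voxel.
#' @param weights Integer (face, edge, vertex) weights, default `c(3, 4, 5)`.
#' @return A [distance_volume()] (voxel units), zero exactly on background.
#' @export
chamfer_distance <- function(bin, weights = c(3, 4, 5)) {
  stopifnot(inherits(bin, "binary_volume"))
  if (all(bin$data))
    stop("no background voxel: chamfer distance undefined", call. = FALSE)
  weights <- as.integer(weights)
  stopifnot(length(weights) == 3L, all(weights > 0L))
  d <- cpp_chamfer(as.logical(bin$data), dim(bin$data),
                   weights[1], weights[2], weights[3])
  distance_volume(array(d / weights[1], dim = dim(bin$data)), bin$voxel_size)
}

#' H-minima transform
#'
#' Suppresses all regional minima of depth < `h` by morphological
#' reconstruction by erosion of `f` from the marker `f + h`
#' (26-neighbourhood).  Minima of depth >= h survive (raised by at most h);
#' `h = 0` is the identity.  In the watershed pipeline this is applied to the
#' negated distance transform (catchment formulation).
#'
#' @param vol A [distance_volume()] or any volume with numeric data (e.g. a
#'   negated distance relief).
#' @param h Non-negative suppression depth.
#' @return A volume of the same class with the filtered field.
#' @export
h_minima <- function(vol, h) {
  if (!is.numeric(h) || length(h) != 1L || h < 0)
    stop("h must be a single non-negative number", call. = FALSE)
  f <- as.numeric(vol$data)
  if (h == 0) return(vol)
  g <- cpp_reconstruct_erosion(f + h, f, dim(vol$data))
  out <- vol
  out$data <- array(g, dim = dim(vol$data))
  out
}

#' Negate a distance relief
#'
#' Convenience for the watershed pipeline: catchment basins of the watershed
#' are the maxima of the distance transform, so flooding runs on `-distance`.
#'
#' @param dist A [distance_volume()].
#' @return A [distance_volume()] holding the negated field.
#' @export
negate_relief <- function(dist) {
  out <- dist
  out$data <- -dist$data
  out
}

#' Seeded morphological watershed
#'
#' Meyer-style priority flooding of the relief restricted to `mask`, seeded at
#' the regional minima of the relief (26-connected plateaus with no lower
#' neighbour).  Seeds are labelled in increasing linear voxel index order and
#' ties in relief value are broken by queue insertion order, so the result is
#' deterministic.  Watershed ridge voxels are assigned to the first-flooding
#' label: the labels partition the mask.
#'
#' @param relief A [distance_volume()] (typically the negated, H-minima
#'   filtered distance transform) or any numeric-data volume.
#' @param mask A [binary_volume()]; flooding is confined to it.  An empty mask
#'   yields an empty labelling.
#' @return A [label_volume()]; the number of labels equals the number of
#'   regional minima of the relief within the mask.
#' @export
watershed <- function(relief, mask) {
  stopifnot(inherits(mask, "binary_volume"))
  if (!identical(dim(relief$data), dim(mask$data)))
    stop("relief and mask dimensions differ", call. = FALSE)
  if (!any(mask$data))
    return(label_volume(array(0L, dim = dim(mask$data)), mask$voxel_size))
  f <- as.numeric(relief$data)
  seeds <- cpp_regional_minima(f, as.logical(mask$data), dim(mask$data))
  lab <- cpp_watershed(f, as.logical(mask$data), seeds, dim(mask$data))
  label_volume(array(lab, dim = dim(mask$data)), mask$voxel_size,
               compact = FALSE)
}

#' Connected-component labelling
#'
#' @param bin A [binary_volume()].
#' @param connectivity 6, 18 or 26 (default 26 — the package's object
#'   connectivity).
#' @return A [label_volume()] with compact labels 1..n; two object voxels
#'   share a label iff they are connected under the chosen adjacency.
#' @export
label_components <- function(bin, connectivity = 26) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  lab <- cpp_label_components(as.logical(bin$data), dim(bin$data),
                              as.integer(connectivity))
  out <- label_volume(array(lab, dim = dim(bin$data)), bin$voxel_size,
                      compact = FALSE)
  out$n_labels <- attr(lab, "n_labels")
  out
}
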