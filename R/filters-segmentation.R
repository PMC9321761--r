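# Gray-level denoising and segmentation: 3D median filter, automatic Otsu
# threshold on the full 3D histogram, 1-D k-means gray clustering, phase-mask
# extraction.

#' 3D median filter
#'
#' Replaces each voxel by the median of its cubic neighbourhood.  Borders are
#' handled by half-sample reflection, so a constant volume passes through
#' unchanged at any width.
#'
#' @param vol A [gray_volume()].
#' @param width Odd cubic window edge in voxels (>= 1).
#' @return A filtered [gray_volume()] of the same shape and bit depth.
#' @export
median_filter_3d <- function(vol, width = 3) {
  stopifnot(inherits(vol, "gray_volume"))
  width <- as.integer(width)
  if (is.na(width) || width < 1L || width %% 2L == 0L)
    stop("width must be an odd positive integer, got ", width, call. = FALSE)
  out <- cpp_median3d(as.integer(vol$data), dim(vol$data), width)
  gray_volume(array(out, dim = dim(vol$data)), voxel_size = vol$voxel_size,
              bits = vol$bits)
}

segmentation_result <- function(method, labels, threshold = NULL,
                                centroids = NULL, mask = NULL) {
  structure(list(method = method, threshold = threshold, centroids = centroids,
                 labels = labels, mask = mask),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method: %s\n", x$method))
  if (!is.null(x$threshold)) cat("  threshold:", x$threshold, "\n")
  if (!is.null(x$centroids))
    cat("  centroids:", paste(signif(x$centroids, 6), collapse = ", "), "\n")
  cat("  classes:", x$labels$n_labels, "\n")
  invisible(x)
}

# histogram of native gray levels: counts[g + 1] for g in 0..(2^bits - 1)
gray_hist <- function(vol) {
  tabulate(as.integer(vol$data) + 1L, nbins = 2L^vol$bits)
}

#' Automatic Otsu threshold
#'
#' Exhaustive search over all native gray levels of the full 3D-volume
#' histogram (256 bins for 8-bit data, 65536 for 16-bit; no rebinning) for the
#' threshold maximising the between-class variance.  The maximiser is a
#' plateau whenever empty bins separate the classes; the reported threshold
#' is the midpoint of the first maximal plateau, so a noiseless bimodal
#' volume gets a threshold midway between its two modes.
#'
#' @param vol A [gray_volume()] with at least two distinct gray levels.
#' @param polarity `"above"` (default): voxels strictly greater than the
#'   threshold are object; `"below"`: voxels <= threshold are object.  Pores
#'   may be darker or brighter than the matrix depending on modality.
#' @return A `segmentation_result` with fields `threshold`, `mask` (a
#'   [binary_volume()]) and `labels` (object = 1).
#' @export
otsu_threshold <- function(vol, polarity = c("above", "below")) {
  stopifnot(inherits(vol, "gray_volume"))
  polarity <- match.arg(polarity)
  h <- gray_hist(vol)
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: volume has fewer than 2 distinct gray levels",
         call. = FALSE)
  lev <- seq_along(h) - 1L
  n <- sum(h)
  w0 <- cumsum(h)                   # voxels with level <= t
  s0 <- cumsum(h * lev)
  st <- s0[length(s0)]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (st - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  t_lo <- which.max(bcv)            # first maximiser
  t_hi <- t_lo
  while (t_hi < length(bcv) && bcv[t_hi + 1L] == bcv[t_lo]) t_hi <- t_hi + 1L
  t <- lev[(t_lo + t_hi) %/% 2L]    # midpoint of the first maximal plateau
  obj <- if (polarity == "above") vol$data > t else vol$data <= t
  mask <- binary_volume(array(obj, dim = dim(vol$data)), vol$voxel_size)
  labs <- label_volume(array(as.integer(obj), dim = dim(vol$data)),
                       vol$voxel_size, compact = FALSE)
  segmentation_result("otsu", labs, threshold = t, mask = mask)
}

#' k-means gray-level clustering
#'
#' Lloyd iterations on the scalar gray values (weighted by the level
#' histogram).  Initialisation is deterministic: centroids at evenly spaced
#' quantiles of the gray distribution, so identical data give identical
#' results; the `seed` argument is kept in the interface for protocol
#' plumbing but has no effect.  Classes are relabelled by ascending centroid;
#' a voxel equidistant between two centroids is assigned to the
#' lower-centroid class.
#'
#' @param vol A [gray_volume()].
#' @param k Number of classes (1 <= k <= number of distinct gray levels).
#' @param seed Unused (deterministic initialisation); kept for interface
#'   stability.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Convergence threshold on the largest centroid shift.
#' @return A `segmentation_result` with sorted `centroids` and `labels`
#'   assigning every voxel to a class 1..k.
#' @export
kmeans_segment <- function(vol, k, seed = 1, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(vol, "gray_volume"))
  k <- as.integer(k)
  h <- gray_hist(vol)
  lev <- which(h > 0) - 1L
  cnt <- h[h > 0]
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(lev))
    stop("k = ", k, " exceeds the ", length(lev), " distinct gray levels",
         call. = FALSE)
  # quantile initialisation on the weighted level distribution (type 1)
  cum <- cumsum(cnt) / sum(cnt)
  probs <- (seq_len(k) - 0.5) / k
  cen <- vapply(probs, function(p) lev[which(cum >= p)[1]], numeric(1))
  if (anyDuplicated(cen))  # collapse onto evenly spaced distinct levels instead
    cen <- lev[unique(round(seq(1, length(lev), length.out = k)))]
  cen <- sort(as.numeric(cen))
  assign_levels <- function(cen) {
    d <- abs(outer(lev, cen, "-"))
    # ties to the lower-centroid class: max.col over negated distance with
    # ties.method "first" picks the lowest index
    max.col(-d, ties.method = "first")
  }
  for (it in seq_len(max_iter)) {
    cls <- assign_levels(cen)
    new_cen <- vapply(seq_len(k), function(j) {
      sel <- cls == j
      if (!any(sel)) cen[j] else sum(lev[sel] * cnt[sel]) / sum(cnt[sel])
    }, numeric(1))
    new_cen <- sort(new_cen)
    shift <- max(abs(new_cen - cen))
    cen <- new_cen
    if (shift < tol) break
  }
  cls <- assign_levels(cen)
  # map every native level to its class
  level_map <- integer(2L^vol$bits)
  level_map[lev + 1L] <- cls
  lab <- array(level_map[as.integer(vol$data) + 1L], dim = dim(vol$data))
  labs <- label_volume(lab, vol$voxel_size, compact = FALSE)
  labs$n_labels <- k
  segmentation_result("kmeans", labs, centroids = cen)
}

#' Within-class sum of squares of a segmentation
#'
#' @param vol The gray volume the segmentation came from.
#' @param seg A `segmentation_result` from [kmeans_segment()].
#' @return Total within-class sum of squared deviations from the centroids.
#' @export
kmeans_wss <- function(vol, seg) {
  stopifnot(inherits(seg, "segmentation_result"), seg$method == "kmeans")
  x <- as.numeric(vol$data)
  cls <- as.integer(seg$labels$data)
  sum((x - seg$centroids[cls])^2)
}

#' Extract a phase mask from a segmentation
#'
#' @param seg A `segmentation_result`.
#' @param class_ids Class labels to keep (subset of the existing classes).
#'   An empty selection yields an all-false mask (documented choice).
#' @return A [binary_volume()], true exactly on voxels of the selected classes.
#' @export
extract_phase_mask <- function(seg, class_ids) {
  stopifnot(inherits(seg, "segmentation_result"))
  existing <- sort(unique(as.integer(seg$labels$data)))
  class_ids <- as.integer(class_ids)
  bad <- setdiff(class_ids, existing)
  if (length(bad))
    stop("unknown class id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- array(seg$labels$data %in% class_ids, dim = dim(seg$labels$data))
  binary_volume(m, seg$labels$voxel_size)
}
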