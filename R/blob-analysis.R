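# Per-component (blob) descriptors: voxel count, physical volume, equivalent
# sphere diameter, maximum-inscribed-sphere diameter, sphericity.

#' Blob metrics table
#'
#' For every labelled component: `voxel_count`; `volume_mm3 = voxel_count *
#' voxel_size^3`; equivalent-sphere diameter `d_eq_mm = (6 V / pi)^(1/3)`;
#' maximum-inscribed-sphere diameter `d_ins_mm` from the chamfer distance
#' transform restricted to the blob (the inscribed radius is the deepest
#' chamfer distance minus half a voxel, i.e. distance from that voxel centre
#' to the blob boundary surface); `sphericity = d_ins / d_eq`.  A single-voxel
#' blob is a degenerate sphere: `d_ins := d_eq`, sphericity 1.  Blobs touching
#' the VOI border are flagged in `touches_border` but kept.
#'
#' @param labels A [label_volume()] (e.g. from [label_components()] or
#'   [watershed()]).
#' @param min_voxels Drop blobs smaller than this many voxels (default 1,
#'   i.e. no size filter).
#' @return A data.frame with one row per blob; empty labelling gives an empty
#'   table.
#' @export
blob_metrics <- function(labels, min_voxels = 1) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$data
  d <- dim(lab)
  vm <- voxel_mm(labels)
  n <- if (any(lab > 0L)) max(lab) else 0L
  empty <- data.frame(blob_id = integer(), voxel_count = integer(),
                      volume_mm3 = numeric(), d_eq_mm = numeric(),
                      d_ins_mm = numeric(), sphericity = numeric(),
                      touches_border = logical())
  if (n == 0L) return(empty)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  rows <- vector("list", n)
  for (id in seq_len(n)) {
    if (counts[id] < min_voxels || counts[id] == 0L) next
    w <- which(lab == id, arr.ind = TRUE)
    tb <- any(w == 1L) || any(w[, 1] == d[1]) || any(w[, 2] == d[2]) ||
      any(w[, 3] == d[3])
    vol_mm3 <- counts[id] * vm^3
    d_eq <- (6 * vol_mm3 / pi)^(1 / 3)
    if (counts[id] == 1L) {
      d_ins <- d_eq
    } else {
      # chamfer within the padded bounding box: everything that is not this
      # blob (including touching neighbour blobs) is background
      lo <- pmax(apply(w, 2, min) - 1L, 1L)
      hi <- pmin(apply(w, 2, max) + 1L, d)
      sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == id
      pd <- dim(sub) + 2L
      padded <- array(FALSE, dim = pd)
      padded[2:(pd[1] - 1L), 2:(pd[2] - 1L), 2:(pd[3] - 1L)] <- sub
      dt <- cpp_chamfer(as.logical(padded), pd, 3L, 4L, 5L) / 3
      r_ins <- max(dt) - 0.5
      d_ins <- 2 * r_ins * vm
    }
    rows[[id]] <- data.frame(blob_id = id, voxel_count = counts[id],
                             volume_mm3 = vol_mm3, d_eq_mm = d_eq,
                             d_ins_mm = d_ins, sphericity = d_ins / d_eq,
                             touches_border = tb)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a blob table to CSV
#'
#' One row per blob, units carried in the column names
#' (`volume_mm3`, `d_eq_mm`, ...).  Round-trips through [utils::read.csv()].
#'
#' @param table A blob table from [blob_metrics()].
#' @param path Output CSV path.
#' @param sort_by_volume If TRUE, rows are written in descending volume order.
#' @return `path`, invisibly.
#' @export
export_blob_table <- function(table, path, sort_by_volume = FALSE) {
  if (sort_by_volume && nrow(table))
    table <- table[order(-table$volume_mm3), , drop = FALSE]
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
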