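#' @useDynLib voxmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm rpois runif
#' @importFrom utils read.csv write.csv
NULL

# Coordinate convention (used everywhere in the package): 0-based voxel
# indices in the user-facing API, axis order (x, y, z) with z the slice
# index.  R arrays are column-major, so array index [i, j, k] corresponds to
# voxel (x = i - 1, y = j - 1, z = k - 1) and the flat vector is x-fastest,
# matching the raw on-disk layout.

new_volume <- function(data, voxel_size, class) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometres)", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = c(class, "voxvolume"))
}

#' Gray-level volume
#'
#' Container for a 3D scalar field of unsigned 8- or 16-bit gray levels with
#' an isotropic voxel size.
#'
#' @param data 3D integer array of gray levels.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param bits Bit depth, 8 or 16. If `NULL`, inferred from the data range
#'   (<= 255 gives 8).
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_size = 1, bits = NULL) {
  storage.mode(data) <- "integer"
  if (anyNA(data)) stop("gray volume must not contain NA", call. = FALSE)
  rng <- range(data)
  if (rng[1] < 0) stop("gray levels must be non-negative", call. = FALSE)
  if (is.null(bits)) bits <- if (rng[2] <= 255L) 8L else 16L
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L))
    stop("unsupported bit depth: ", bits, " (must be 8 or 16)", call. = FALSE)
  if (rng[2] > 2^bits - 1)
    stop("gray levels exceed declared bit depth", call. = FALSE)
  v <- new_volume(data, voxel_size, "gray_volume")
  v$bits <- bits
  v
}

#' Binary volume
#'
#' Object/background mask; `TRUE` voxels are object.
#'
#' @param data 3D logical array.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size = 1) {
  if (is.numeric(data)) data <- array(data != 0, dim = dim(data))
  if (!is.logical(data)) stop("binary volume data must be logical", call. = FALSE)
  if (anyNA(data)) stop("binary volume must not contain NA", call. = FALSE)
  new_volume(data, voxel_size, "binary_volume")
}

#' Labelled volume
#'
#' Non-negative integer component/phase labels, 0 = background.  Labels are
#' compacted to `{0} U {1..n_labels}`.
#'
#' @param data 3D non-negative integer array.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param compact Relabel positive values to a dense 1..n range (default TRUE).
#' @return An object of class `label_volume` with field `n_labels`.
#' @export
label_volume <- function(data, voxel_size = 1, compact = TRUE) {
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  if (compact) {
    u <- sort(unique(data[data > 0L]))
    if (length(u) && !identical(u, seq_along(u))) {
      map <- integer(max(u)); map[u] <- seq_along(u)
      pos <- data > 0L
      data[pos] <- map[data[pos]]
    }
    n_labels <- length(u)
  } else {
    n_labels <- if (any(data > 0L)) max(data) else 0L
  }
  v <- new_volume(data, voxel_size, "label_volume")
  v$n_labels <- as.integer(n_labels)
  v
}

#' Distance volume
#'
#' Non-negative scalar chamfer distances in voxel units (after weight
#' normalisation); zero exactly on background.
#'
#' @param data 3D numeric array of distances.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @return An object of class `distance_volume`.
#' @export
distance_volume <- function(data, voxel_size = 1) {
  storage.mode(data) <- "double"
  new_volume(data, voxel_size, "distance_volume")
}

#' @export
dim.voxvolume <- function(x) dim(x$data)

#' @export
print.voxvolume <- function(x, ...) {
  d <- dim(x$data)
  kind <- class(x)[1]
  cat(sprintf("<%s> %d x %d x %d voxels, voxel size %g um\n",
              kind, d[1], d[2], d[3], x$voxel_size))
  if (kind == "gray_volume") cat(sprintf("  bit depth: %d\n", x$bits))
  if (kind == "binary_volume") cat(sprintf("  object fraction: %.4f\n", mean(x$data)))
  if (kind == "label_volume") cat(sprintf("  labels: %d\n", x$n_labels))
  invisible(x)
}

raw_sidecar_path <- function(path) paste0(path, ".json")

#' Read a 3D volume
#'
#' Reads a gray-level volume from a headerless little-endian raw file
#' (x-fastest ordering, with a JSON sidecar `{nx, ny, nz, bits,
#' voxel_size_um}`) or from a multipage grayscale TIFF stack.  Voxel size is
#' required metadata: all downstream quantities carry physical units, so it is
#' never inferred from TIFF tags.
#'
#' @param path File path (`.tif`/`.tiff` for TIFF, anything else raw).
#' @param meta Named list. For raw input without a sidecar: `nx, ny, nz, bits,
#'   voxel_size_um`. For TIFF: `voxel_size_um` only.
#' @return A [gray_volume()].
#' @export
read_volume <- function(path, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vs <- meta$voxel_size_um
    if (is.null(vs)) stop("meta$voxel_size_um is required for TIFF input", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nzl <- length(pages)
    d1 <- dim(pages[[1]])
    if (length(d1) != 2L)
      stop("unsupported format: only single-channel grayscale TIFF is supported",
           call. = FALSE)
    # TIFF page rows are y, columns are x; internal layout is [x, y, z]
    arr <- array(0L, dim = c(d1[2], d1[1], nzl))
    for (k in seq_len(nzl)) {
      if (!identical(dim(pages[[k]]), d1))
        stop("malformed input: TIFF pages differ in size", call. = FALSE)
      arr[, , k] <- t(pages[[k]])
    }
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- if (max(arr) <= 255L) 8L else 16L
    if (!bits %in% c(8L, 16L))
      stop("unsupported format: bit depth ", bits, call. = FALSE)
    return(gray_volume(arr, voxel_size = vs, bits = bits))
  }
  # raw + sidecar
  sc <- raw_sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta <- utils::modifyList(side, meta)
  }
  need <- c("nx", "ny", "nz", "bits", "voxel_size_um")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("raw input needs metadata fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nx <- as.integer(meta$nx); ny <- as.integer(meta$ny); nz <- as.integer(meta$nz)
  bits <- as.integer(meta$bits)
  if (!bits %in% c(8L, 16L))
    stop("unsupported format: bit depth ", bits, call. = FALSE)
  nbytes <- as.numeric(nx) * ny * nz * (bits / 8)
  actual <- file.info(path)$size
  if (actual != nbytes)
    stop(sprintf("malformed input: file has %d bytes but %d x %d x %d @ %d-bit needs %d",
                 actual, nx, ny, nz, bits, nbytes), call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "integer", n = nx * ny * nz, size = bits / 8,
                  signed = FALSE, endian = "little")
  gray_volume(array(vals, dim = c(nx, ny, nz)),
              voxel_size = meta$voxel_size_um, bits = bits)
}

#' Write a 3D volume
#'
#' Writes gray, binary or labelled volumes losslessly.  Binary masks are
#' written as 0/255 8-bit; labels use the smallest sufficient unsigned width
#' (8-bit up to 255 labels, 16-bit up to 65535).  Raw output gets a JSON
#' sidecar `<path>.json` with `{nx, ny, nz, bits, voxel_size_um}`.
#'
#' @param vol A [gray_volume()], [binary_volume()] or [label_volume()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"raw"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "raw", "tiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  if (inherits(vol, "binary_volume")) {
    data <- array(ifelse(vol$data, 255L, 0L), dim = dim(vol$data))
    bits <- 8L
  } else if (inherits(vol, "label_volume")) {
    mx <- max(vol$data)
    if (mx > 65535L)
      stop("overflow: ", mx, " labels exceed the 16-bit container", call. = FALSE)
    bits <- if (mx <= 255L) 8L else 16L
    data <- vol$data
  } else if (inherits(vol, "gray_volume")) {
    data <- vol$data
    bits <- vol$bits
  } else stop("unsupported volume kind: ", class(vol)[1], call. = FALSE)
  d <- dim(data)
  if (format == "raw") {
    con <- file(path, "wb")
    writeBin(as.integer(data), con, size = bits / 8, endian = "little")
    close(con)
    jsonlite::write_json(
      list(nx = d[1], ny = d[2], nz = d[3], bits = bits,
           voxel_size_um = vol$voxel_size),
      raw_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    denom <- 2^bits - 1
    pages <- lapply(seq_len(d[3]), function(k) t(data[, , k]) / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  }
  invisible(path)
}

#' Crop a volume of interest
#'
#' Extracts the axis-aligned sub-volume starting at 0-based voxel `origin`
#' with extent `shape`.  No clamping: out-of-bounds requests are an error.
#'
#' @param vol Any volume object.
#' @param origin Integer triple, 0-based corner (x, y, z).
#' @param shape Integer triple, extent in voxels.
#' @return A volume of the same kind with dimensions `shape`.
#' @export
crop_voi <- function(vol, origin, shape) {
  origin <- as.integer(origin); shape <- as.integer(shape)
  if (length(origin) != 3L || length(shape) != 3L)
    stop("origin and shape must be integer triples", call. = FALSE)
  d <- dim(vol$data)
  if (any(origin < 0L) || any(shape < 1L) || any(origin + shape > d))
    stop("VOI out of bounds: origin ", paste(origin, collapse = ","),
         " shape ", paste(shape, collapse = ","), " in volume ",
         paste(d, collapse = "x"), call. = FALSE)
  sub <- vol$data[origin[1] + seq_len(shape[1]),
                  origin[2] + seq_len(shape[2]),
                  origin[3] + seq_len(shape[3]), drop = FALSE]
  out <- vol
  out$data <- sub
  if (inherits(vol, "label_volume"))
    out$n_labels <- length(unique(sub[sub > 0L]))
  out
}

# physical voxel edge in mm
voxel_mm <- function(vol) vol$voxel_size / 1000

# total VOI volume in mm^3
voi_volume_mm3 <- function(vol) prod(dim(vol$data)) * voxel_mm(vol)^3
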