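# The three analysis protocols as configurable, logged pipelines:
# pore analysis (median -> Otsu -> opening -> basic/blob/skeleton analysis),
# multiphase separation (k-means -> mask -> chamfer -> H-minima -> watershed),
# bone morphometry.  Config + input fully determine the output: no unseeded
# randomness anywhere, and reports carry no timestamps, so identical runs are
# bit-identical.

#' Read a flat key-value protocol configuration
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are parsed
#' as numbers, logicals (`true`/`false`) or comma-separated numeric triples
#' where possible, else kept as strings.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_protocol_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val)) {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (!anyNA(num)) val <- num
    } else if (tolower(val) %in% c("true", "false")) {
      val <- tolower(val) == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    cfg[[key]] <- val
  }
  cfg
}

proto_log <- function(state, ...) {
  msg <- paste0(...)
  state$lines <- c(state$lines, msg)
  if (state$verbose) cat(msg, "\n", sep = "")
  state
}

finish_log <- function(state, out_dir) {
  if (!is.null(out_dir))
    writeLines(state$lines, file.path(out_dir, "run.log"))
}

#' Write an analysis report
#'
#' JSON plus a flat `field,value` CSV; numbers are written at full precision
#' and without timestamps so identical analyses produce identical files.
#'
#' @param report A named list (possibly nested) of scalars.
#' @param path_base Output path without extension.
#' @return `path_base`, invisibly.
#' @export
write_report <- function(report, path_base) {
  jsonlite::write_json(report, paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flat <- unlist(report)
  write.csv(data.frame(field = names(flat), value = as.character(flat)),
            paste0(path_base, ".csv"), row.names = FALSE)
  invisible(path_base)
}

# resolve cfg$volume (in-memory) or cfg$input (+ metadata) to a gray volume,
# then crop the VOI if requested
load_input <- function(cfg) {
  vol <- if (!is.null(cfg$volume)) cfg$volume
  else read_volume(cfg$input, meta = cfg[intersect(
    names(cfg), c("nx", "ny", "nz", "bits", "voxel_size_um"))])
  if (!is.null(cfg$voi_origin) || !is.null(cfg$voi_shape)) {
    if (is.null(cfg$voi_origin) || is.null(cfg$voi_shape))
      stop("voi_origin and voi_shape must be given together", call. = FALSE)
    vol <- crop_voi(vol, cfg$voi_origin, cfg$voi_shape)
  }
  vol
}

cfg_get <- function(cfg, key, default) if (is.null(cfg[[key]])) default else cfg[[key]]

save_stage <- function(vol, out_dir, name) {
  if (!is.null(out_dir)) write_volume(vol, file.path(out_dir, paste0(name, ".raw")))
}

#' Pore analysis protocol
#'
#' Median filter, automatic Otsu segmentation, morphological opening
#' (erosion then dilation; `closing = TRUE` swaps the order), then the three
#' analyses on the processed mask: basic analysis (VV, SV, MV, chi_v, I, EA),
#' blob analysis (on the opened mask, before any watershed separation) and
#' skeleton analysis (thinning, pruning, graph, connectivity density).
#'
#' @param cfg Named list (or file read by [read_protocol_config()]):
#'   `volume` (in-memory gray volume) or `input` path with raw metadata;
#'   optional `voi_origin`/`voi_shape`; `median_width` (3), `polarity`
#'   ("above"), `morph_width` (3), `closing` (FALSE), `pruning` (5),
#'   `n_directions` (512), `line_spacing` (2), `seed` (1), `min_voxels` (1),
#'   `out_dir` (optional: stage-indexed intermediates, blob table, report,
#'   log), `verbose` (FALSE).
#' @return A list: the `report` (scalars), `mask` (processed binary volume),
#'   `blobs` (blob table), `graph` (skeleton graph).
#' @export
run_pore_protocol <- function(cfg) {
  st <- list(lines = character(), verbose = isTRUE(cfg$verbose))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    st <<- proto_log(st, "[pore] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pore protocol failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  median_width <- cfg_get(cfg, "median_width", 3)
  polarity <- cfg_get(cfg, "polarity", "above")
  morph_width <- cfg_get(cfg, "morph_width", 3)
  use_closing <- isTRUE(cfg$closing)
  pruning <- cfg_get(cfg, "pruning", 5)
  n_directions <- cfg_get(cfg, "n_directions", 512)
  line_spacing <- cfg_get(cfg, "line_spacing", 2)
  seed <- cfg_get(cfg, "seed", 1)
  min_voxels <- cfg_get(cfg, "min_voxels", 1)
  st <- proto_log(st, "[pore] parameters: median_width=", median_width,
                  " polarity=", polarity, " morph_width=", morph_width,
                  " closing=", use_closing, " pruning=", pruning,
                  " n_directions=", n_directions, " line_spacing=", line_spacing,
                  " seed=", seed, " min_voxels=", min_voxels)
  vol <- run_stage("input", load_input(cfg))
  med <- run_stage("median", median_filter_3d(vol, median_width))
  save_stage(med, out_dir, "01_median")
  seg <- run_stage("otsu", otsu_threshold(med, polarity = polarity))
  st <- proto_log(st, "[pore] otsu threshold: ", seg$threshold)
  save_stage(seg$mask, out_dir, "02_otsu")
  mask <- run_stage("morphology", {
    if (use_closing) closing(seg$mask, morph_width)
    else opening(seg$mask, morph_width)
  })
  save_stage(mask, out_dir, "03_opened")
  basic <- run_stage("basic_analysis",
                     basic_analysis(mask, n_directions = n_directions,
                                    line_spacing = line_spacing, seed = seed))
  labs <- run_stage("components", label_components(mask, 26))
  blobs <- run_stage("blob_analysis", blob_metrics(labs, min_voxels = min_voxels))
  skel <- run_stage("skeletonize", lkc_skeletonize(mask))
  save_stage(skel, out_dir, "04_skeleton")
  skel <- run_stage("prune", prune_skeleton(skel, pruning))
  graph <- run_stage("skeleton_graph", skeleton_graph(skel))
  cd <- connectivity_density(graph, voi_volume_mm3(mask))
  report <- list(
    protocol = "pore",
    parameters = list(median_width = median_width, otsu_threshold = seg$threshold,
                      polarity = polarity, morph_width = morph_width,
                      closing = use_closing, pruning = pruning,
                      n_directions = n_directions, line_spacing = line_spacing,
                      seed = seed, min_voxels = min_voxels,
                      voxel_size_um = vol$voxel_size,
                      voi = paste(dim(vol$data), collapse = "x")),
    basic = basic[c("VV", "SV", "MV", "chi_v", "I", "EA")],
    blob = list(n_blobs = nrow(blobs)),
    skeleton = list(n_nodes = nrow(graph$nodes), n_ends = nrow(graph$ends),
                    n_branches = nrow(graph$branches),
                    connectivity_density = cd))
  if (!is.null(out_dir)) {
    export_blob_table(blobs, file.path(out_dir, "blobs.csv"))
    export_skeleton_graph(graph, file.path(out_dir, "skeleton_graph.csv"))
    write_report(report, file.path(out_dir, "report"))
  }
  finish_log(st, out_dir)
  list(report = report, mask = mask, blobs = blobs, graph = graph)
}

#' Multiphase separation protocol
#'
#' k-means gray clustering, phase-mask extraction, chamfer distance
#' transform, relief negation, H-minima suppression, seeded watershed, label
#' compaction and blob metrics — the touching-grain separation pipeline.
#'
#' @param cfg Named list: input as in [run_pore_protocol()]; `k` (>= 2,
#'   default 4), `phase_classes` (classes forming the phase of interest;
#'   default the brightest class), `h` (H-minima depth, default 4),
#'   `min_voxels` (1), `seed` (1), `out_dir`, `verbose`.
#' @return A list: `report`, `labels` (separated [label_volume()]), `blobs`,
#'   `segmentation`.
#' @export
run_multiphase_protocol <- function(cfg) {
  st <- list(lines = character(), verbose = isTRUE(cfg$verbose))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    st <<- proto_log(st, "[multiphase] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("multiphase protocol failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  k <- cfg_get(cfg, "k", 4)
  if (k < 2) stop("multiphase protocol needs k >= 2", call. = FALSE)
  h <- cfg_get(cfg, "h", 4)
  seed <- cfg_get(cfg, "seed", 1)
  min_voxels <- cfg_get(cfg, "min_voxels", 1)
  st <- proto_log(st, "[multiphase] parameters: k=", k, " h=", h, " seed=", seed)
  vol <- run_stage("input", load_input(cfg))
  seg <- run_stage("kmeans", kmeans_segment(vol, k = k, seed = seed))
  st <- proto_log(st, "[multiphase] centroids: ",
                  paste(signif(seg$centroids, 6), collapse = ", "))
  phase <- cfg_get(cfg, "phase_classes", k)
  mask <- run_stage("phase_mask", extract_phase_mask(seg, phase))
  save_stage(mask, out_dir, "01_phase_mask")
  dist <- run_stage("chamfer", chamfer_distance(mask))
  relief <- run_stage("negate", negate_relief(dist))
  relief <- run_stage("h_minima", h_minima(relief, h))
  labs <- run_stage("watershed", watershed(relief, mask))
  labs <- run_stage("compact", label_volume(labs$data, labs$voxel_size))
  save_stage(labs, out_dir, "02_labels")
  blobs <- run_stage("blob_analysis", blob_metrics(labs, min_voxels = min_voxels))
  st <- proto_log(st, "[multiphase] objects found: ", labs$n_labels)
  report <- list(
    protocol = "multiphase",
    parameters = list(k = k, phase_classes = phase, h = h, seed = seed,
                      min_voxels = min_voxels, voxel_size_um = vol$voxel_size,
                      voi = paste(dim(vol$data), collapse = "x")),
    kmeans_centroids = seg$centroids,
    n_objects = labs$n_labels,
    phase_fraction = volume_density(mask))
  if (!is.null(out_dir)) {
    export_blob_table(blobs, file.path(out_dir, "blobs.csv"))
    write_report(report, file.path(out_dir, "report"))
  }
  finish_log(st, out_dir)
  list(report = report, labels = labs, blobs = blobs, segmentation = seg)
}

#' Bone morphometry protocol
#'
#' Scalar mode (`BvTv` and `BsBv` given) applies the plate-model identities
#' directly; volume mode segments the input if it is gray (Otsu) and runs
#' [bone_morphometry()] on the solid mask.
#'
#' @param cfg Named list: either `BvTv` + `BsBv`, or an input volume/path
#'   (binary or gray; gray is Otsu-thresholded with `polarity`, default
#'   "above"); `out_dir`, `verbose`.
#' @return A list: `report` and the `morphometry_result`.
#' @export
run_morphometry_protocol <- function(cfg) {
  st <- list(lines = character(), verbose = isTRUE(cfg$verbose))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$BvTv) || !is.null(cfg$BsBv)) {
    if (is.null(cfg$BvTv) || is.null(cfg$BsBv))
      stop("scalar mode needs both BvTv and BsBv", call. = FALSE)
    st <- proto_log(st, "[morphometry] scalar mode: BvTv=", cfg$BvTv,
                    " BsBv=", cfg$BsBv)
    res <- morphometry_from_scalars(cfg$BvTv, cfg$BsBv)
  } else {
    vol <- load_input(cfg)
    if (inherits(vol, "gray_volume")) {
      st <- proto_log(st, "[morphometry] segmenting gray input with Otsu")
      vol <- otsu_threshold(vol, polarity = cfg_get(cfg, "polarity", "above"))$mask
    }
    save_stage(vol, out_dir, "01_bone_mask")
    res <- bone_morphometry(vol)
  }
  report <- list(protocol = "morphometry",
                 BvTv = res$BvTv, BsBv = res$BsBv,
                 TbTh = res$TbTh, TbN = res$TbN, TbSp = res$TbSp,
                 units = as.list(res$units))
  if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report"))
  finish_log(st, out_dir)
  list(report = report, morphometry = res)
}
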