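# Topology-preserving thinning, end-branch pruning, skeleton-graph extraction
# with the three branch classes (node-to-node, node-to-end, end-to-end), and
# connectivity density (first Betti number per unit volume).

#' Topology-preserving curve skeletonisation
#'
#' Iterative directional thinning: six sub-cycles per pass in the fixed order
#' U, D, N, S, E, W; in each sub-cycle the border voxels in that direction
#' that are simple points (removal preserves 26-object/6-background topology,
#' Malandain-Bertrand characterisation) and are not curve endpoints (<= 1
#' object neighbour) are deleted sequentially, re-checking simplicity at
#' deletion time.  Deterministic: a fixed sub-cycle order and linear-index
#' scan order; the published thinning family leaves these choices open and
#' different orders yield different — equally valid — skeletons.
#'
#' @param bin A [binary_volume()].
#' @return A `skeleton_volume` (also a [binary_volume()]): a unit-width
#'   skeleton, subset of the object, with the object's Euler characteristic.
#' @export
lkc_skeletonize <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  out <- cpp_thin(as.logical(bin$data), dim(bin$data))
  sk <- binary_volume(array(out, dim = dim(bin$data)), bin$voxel_size)
  class(sk) <- c("skeleton_volume", class(sk))
  sk
}

# 26-neighbour adjacency list over skeleton voxels; returns list(idx, pos,
# adj) with adj[[i]] the skeleton-voxel ids adjacent to voxel i
skeleton_adjacency <- function(skel) {
  d <- dim(skel$data)
  idx <- which(skel$data)
  nvox <- length(idx)
  lookup <- integer(prod(d))
  lookup[idx] <- seq_len(nvox)
  pos <- arrayInd(idx, d)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  adj <- vector("list", nvox)
  if (nvox == 0) return(list(idx = idx, pos = pos, adj = adj))
  for (i in seq_len(nvox)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(off))) {
    px <- pos[, 1] + off[r, 1]; py <- pos[, 2] + off[r, 2]; pz <- pos[, 3] + off[r, 3]
    ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
    if (!any(ok)) next
    nb <- lookup[(px[ok] - 1L) + d[1] * ((py[ok] - 1L) + d[2] * (pz[ok] - 1L)) + 1L]
    hit <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (j in seq_along(hit)) adj[[hit[j]]] <- c(adj[[hit[j]]], nb[j])
  }
  adj <- lapply(adj, sort)
  list(idx = idx, pos = pos, adj = adj)
}

step_weight <- function(p, q) sqrt(sum((p - q)^2))

#' Skeleton graph extraction
#'
#' Classifies skeleton voxels by their 26-neighbour count within the skeleton
#' (1 = end, 2 = branch interior, >= 3 = node) and walks maximal interior
#' chains between terminals into branches, typed by their two terminals.
#' Degenerate conventions: a pure cycle (no terminal voxel) is one
#' self-closing node-to-node branch carrying one phantom graph vertex; an
#' isolated voxel is one end-to-end branch of length 0.  Branch length is the
#' sum of inter-voxel steps weighted 1/sqrt(2)/sqrt(3) times the voxel size.
#'
#' @param skel A `skeleton_volume` (or any [binary_volume()]).
#' @return A `skeleton_graph`: data.frames `nodes`, `ends`, `branches`, the
#'   voxel `paths` of each branch, `n_components`, and the first Betti number
#'   `beta1 = E - V + C` of the graph.
#' @export
skeleton_graph <- function(skel) {
  sa <- skeleton_adjacency(skel)
  nvox <- length(sa$idx)
  vm <- voxel_mm(skel)
  deg <- vapply(sa$adj, length, integer(1))
  terminal <- deg == 1L | deg >= 3L
  isolated <- deg == 0L
  branches <- list(); paths <- list(); nb <- 0L
  edge_seen <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "-", max(a, b))
  voxel_in_branch <- logical(nvox)
  path_len_mm <- function(path) {
    if (length(path) < 2) return(0)
    s <- 0
    for (i in seq_len(length(path) - 1L))
      s <- s + step_weight(sa$pos[path[i], ], sa$pos[path[i + 1L], ])
    s * vm
  }
  add_branch <- function(path, t1, t2, cycle = FALSE) {
    nb <<- nb + 1L
    type <- if (cycle) "node-to-node"
    else if (length(path) == 1L) "end-to-end"   # isolated voxel convention
    else if (deg[t1] >= 3L && deg[t2] >= 3L) "node-to-node"
    else if (deg[t1] == 1L && deg[t2] == 1L) "end-to-end"
    else "node-to-end"
    branches[[nb]] <<- data.frame(branch_id = nb, type = type,
                                  length_mm = path_len_mm(path),
                                  n_voxels = length(unique(path)),
                                  is_cycle = cycle)
    paths[[nb]] <<- path
    voxel_in_branch[path] <<- TRUE
  }
  for (t in which(terminal)) {
    for (n0 in sa$adj[[t]]) {
      k <- ekey(t, n0)
      if (!is.null(edge_seen[[k]])) next
      edge_seen[[k]] <- TRUE
      path <- c(t, n0); prev <- t; cur <- n0
      while (!terminal[cur]) {
        nxt <- setdiff(sa$adj[[cur]], prev)[1]
        edge_seen[[ekey(cur, nxt)]] <- TRUE
        path <- c(path, nxt); prev <- cur; cur <- nxt
      }
      add_branch(path, t, cur)
    }
  }
  # pure cycles: leftover interior voxels not reachable from any terminal
  for (s in which(deg == 2L & !voxel_in_branch)) {
    if (voxel_in_branch[s]) next
    prev <- s; cur <- sa$adj[[s]][1]; path <- c(s, cur)
    while (cur != s) {
      nxt <- setdiff(sa$adj[[cur]], prev)[1]
      path <- c(path, nxt); prev <- cur; cur <- nxt
    }
    add_branch(path, s, s, cycle = TRUE)
  }
  for (s in which(isolated)) add_branch(s, s, s)
  br <- if (nb) do.call(rbind, branches)
  else data.frame(branch_id = integer(), type = character(),
                  length_mm = numeric(), n_voxels = integer(),
                  is_cycle = logical())
  rownames(br) <- NULL
  # connected components of the skeleton voxel graph
  comp <- integer(nvox); ncomp <- 0L
  for (s in seq_len(nvox)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    stack <- s; comp[s] <- ncomp
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (q in sa$adj[[p]]) if (comp[q] == 0L) { comp[q] <- ncomp; stack <- c(stack, q) }
    }
  }
  n_cycles <- sum(br$is_cycle)
  n_iso <- sum(isolated)
  E <- nb - n_iso                       # isolated voxels carry no edge
  V <- sum(terminal) + n_cycles + n_iso # phantom vertex per pure cycle
  beta1 <- E - V + ncomp
  mk_df <- function(sel) {
    if (!any(sel)) return(data.frame(x = integer(), y = integer(),
                                     z = integer(), degree = integer()))
    data.frame(x = sa$pos[sel, 1] - 1L, y = sa$pos[sel, 2] - 1L,
               z = sa$pos[sel, 3] - 1L, degree = deg[sel])
  }
  structure(list(nodes = mk_df(deg >= 3L), ends = mk_df(deg == 1L),
                 branches = br, paths = paths, positions = sa$pos,
                 degree = deg, n_components = ncomp, beta1 = beta1,
                 voxel_size = skel$voxel_size, dim = dim(skel$data)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d ends, %d branches, beta1 = %d\n",
              nrow(x$nodes), nrow(x$ends), nrow(x$branches), x$beta1))
  if (nrow(x$branches))
    print(table(x$branches$type))
  invisible(x)
}

#' Prune short end branches
#'
#' Iteratively removes node-to-end branches whose voxel path length (number
#' of voxels beyond the junction node) is strictly shorter than `min_length`,
#' re-extracting the graph after each pass until no such branch remains.
#' Node-to-node and end-to-end branches are never removed, so cycles and
#' free-standing segments survive; `min_length = 0` is the identity.
#'
#' @param skel A `skeleton_volume`.
#' @param min_length Threshold in voxels (Table-style pruning parameters are
#'   unitless voxel counts).
#' @return The pruned `skeleton_volume` (subset of the input).
#' @export
prune_skeleton <- function(skel, min_length) {
  stopifnot(min_length >= 0)
  data <- skel$data
  repeat {
    cur <- skel; cur$data <- data
    g <- skeleton_graph(cur)
    spur <- which(g$branches$type == "node-to-end" & !g$branches$is_cycle)
    removed <- FALSE
    for (b in spur) {
      path <- g$paths[[b]]
      # keep the junction-node terminal; everything else is the spur
      keep <- path[g$degree[path] >= 3L]
      drop <- setdiff(path, keep)
      if (length(drop) < min_length) {
        pos <- g$positions[drop, , drop = FALSE]
        data[cbind(pos[, 1], pos[, 2], pos[, 3])] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  out <- skel
  out$data <- data
  out
}

#' Connectivity density
#'
#' First Betti number of the skeleton graph (independent cycles of the pore
#' or trabecular network) per unit VOI volume.
#'
#' @param skel_graph A `skeleton_graph`.
#' @param voi_volume VOI volume in mm^3.
#' @return Connectivity density in mm^-3.
#' @export
connectivity_density <- function(skel_graph, voi_volume) {
  stopifnot(inherits(skel_graph, "skeleton_graph"), voi_volume > 0)
  skel_graph$beta1 / voi_volume
}

#' Export a skeleton graph
#'
#' Writes the branch list as CSV (id, type, length in mm, endpoint voxel
#' coordinates) and optionally the terminal-vertex graph in GraphML.
#'
#' @param graph A `skeleton_graph`.
#' @param csv_path Output CSV path.
#' @param graphml_path Optional GraphML output path.
#' @return `csv_path`, invisibly.
#' @export
export_skeleton_graph <- function(graph, csv_path, graphml_path = NULL) {
  br <- graph$branches
  ep <- t(vapply(seq_len(nrow(br)), function(b) {
    p <- graph$paths[[b]]
    c(graph$positions[p[1], ] - 1L, graph$positions[p[length(p)], ] - 1L)
  }, integer(6)))
  if (nrow(br)) {
    colnames(ep) <- c("x1", "y1", "z1", "x2", "y2", "z2")
    br <- cbind(br, ep)
  }
  write.csv(br, csv_path, row.names = FALSE)
  if (!is.null(graphml_path) && nrow(br)) {
    vkey <- unique(c(paste(ep[, 1], ep[, 2], ep[, 3]),
                     paste(ep[, 4], ep[, 5], ep[, 6])))
    g <- igraph::graph_from_edgelist(
      cbind(match(paste(ep[, 1], ep[, 2], ep[, 3]), vkey),
            match(paste(ep[, 4], ep[, 5], ep[, 6]), vkey)),
      directed = FALSE)
    igraph::V(g)$name <- vkey
    igraph::E(g)$type <- br$type
    igraph::E(g)$length_mm <- br$length_mm
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(csv_path)
}
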