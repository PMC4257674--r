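#' Vessel centerline skeleton
#'
#' A spatial graph of centerline points: `nodes` are physical-um
#' positions, `edges` connect node indices. Vessel trees are forests;
#' cycles (anastomoses or segmentation artifacts) are allowed but flagged.
#'
#' @param nodes n x 3 matrix, um.
#' @param edges m x 2 integer matrix of node indices.
#' @return An object of class `vessel_skeleton`.
#' @export
vessel_skeleton <- function(nodes, edges) {
  nodes <- as_point_matrix(nodes)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L &&
      (min(edges) < 1L || max(edges) > nrow(nodes))) {
    stop("edge endpoint outside node range", call. = FALSE)
  }
  has_cycle <- nrow(edges) > 0L &&
    nrow(unique(t(apply(edges, 1, sort)))) >
      nrow(nodes) - n_components(nrow(nodes), edges)
  if (has_cycle) {
    warning("skeleton contains cycles (not a forest)", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, has_cycle = has_cycle),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  deg <- skeleton_degree(x)
  cat(sprintf(
    "<vessel_skeleton> %d nodes, %d edges, %d branch point(s)%s\n",
    nrow(x$nodes), nrow(x$edges), sum(deg >= 3L),
    if (x$has_cycle) " [cyclic]" else ""))
  invisible(x)
}

#' Node degrees of a skeleton
#' @param skeleton a [vessel_skeleton()].
#' @return integer vector, one degree per node.
#' @export
skeleton_degree <- function(skeleton) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  tabulate(c(skeleton$edges[, 1], skeleton$edges[, 2]),
           nbins = nrow(skeleton$nodes))
}

# connected component count of an undirected graph (union-find)
n_components <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1])
    b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n_nodes), find, 1L)))
}

#' Skeletonize a binary vessel mask
#'
#' Reduces a binary tubular mask to its 1-voxel-wide centerline by 3D
#' topological thinning (sequential simple-point peeling with endpoint
#' preservation), then converts the surviving voxels to a physical-um
#' graph: one node per skeleton voxel, one edge per 26-adjacent voxel
#' pair.
#'
#' @param mask logical (or 0/1) 3D array, dimensions `[x, y, z]`.
#' @param geometry a [volume_geometry()] matching `mask` (supplies voxel
#'   spacing).
#' @return A [vessel_skeleton()].
#' @export
skeletonize_mask <- function(mask, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3D array", call. = FALSE)
  if (!all(dims == geometry$dimensions)) {
    stop("mask dimensions do not match the volume geometry", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dims)
  if (!any(mask)) stop("empty mask: no foreground voxels", call. = FALSE)
  thin <- .thin3d(as.vector(mask), as.integer(dims))
  idx <- which(array(thin, dim = dims), arr.ind = TRUE) # 1-based voxels
  vox <- idx - 1L
  nodes <- to_physical(vox, geometry)
  edges <- voxel_adjacency_edges(vox)
  suppressWarnings(vessel_skeleton(nodes, edges))
}

# 26-adjacency edges between rows of a 0-based voxel coordinate matrix
voxel_adjacency_edges <- function(vox) {
  n <- nrow(vox)
  if (n < 2L) return(matrix(integer(), 0, 2))
  key <- function(v) {
    paste(v[, 1], v[, 2], v[, 3], sep = ",")
  }
  lut <- seq_len(n)
  names(lut) <- key(vox)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[r, ], `+`)
    hit <- lut[key(nb)]
    ok <- !is.na(hit)
    if (any(ok)) {
      e <- cbind(which(ok), unname(hit[ok]))
      edges[[length(edges) + 1L]] <- e[e[, 1] < e[, 2], , drop = FALSE]
    }
  }
  if (!length(edges)) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, edges))
}
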