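#' Rasterize a synthetic tissue channel to a binary voxel stack
#'
#' Voxelizes one structural channel of a generated tissue on the grid of
#' `geometry`: vessels as tubes of their edge radii, fibers as thin tubes
#' of the fiber radius, cells as ellipsoids. A voxel is foreground when
#' its centre lies within the structure. Deterministic.
#'
#' @param tissue a [generate_tissue()] result.
#' @param geometry a [volume_geometry()] whose physical extent covers the
#'   tissue extent.
#' @param channel `"vessels"`, `"fibers"` or `"cells"`.
#' @return logical 3D array `[x, y, z]` of dimensions
#'   `geometry$dimensions`.
#' @export
rasterize <- function(tissue, geometry,
                      channel = c("vessels", "fibers", "cells")) {
  stopifnot(inherits(tissue, "synthetic_tissue"),
            inherits(geometry, "volume_geometry"))
  channel <- match.arg(channel)
  if (any(physical_extent(geometry) < tissue$extent - 1e-9)) {
    stop("geometry extent smaller than the tissue extent", call. = FALSE)
  }
  min_radius <- switch(channel,
                       vessels = if (nrow(tissue$vessel_edges)) {
                         min(tissue$vessel_edges$radius)
                       } else Inf,
                       fibers = tissue$params$fiber_radius,
                       cells = if (nrow(tissue$cells)) {
                         min(as.matrix(tissue$cells[, c("a", "b", "c")]))
                       } else Inf)
  if (is.finite(min_radius) &&
      max(geometry$voxel_spacing) > min_radius) {
    warning("voxel spacing is coarser than the smallest structure radius; ",
            "rasterization may miss structures", call. = FALSE)
  }
  dims <- geometry$dimensions
  vol <- array(FALSE, dim = dims)
  if (channel == "vessels") {
    nodes <- as.matrix(tissue$vessel_nodes[, c("x", "y", "z")])
    for (k in seq_len(nrow(tissue$vessel_edges))) {
      e <- tissue$vessel_edges[k, ]
      idx <- tube_voxels(nodes[e$from, ], nodes[e$to, ], e$radius,
                         geometry, dims)
      if (nrow(idx)) vol[idx] <- TRUE
    }
  } else if (channel == "fibers") {
    for (p in tissue$fibers$polylines) {
      for (k in seq_len(nrow(p) - 1L)) {
        idx <- tube_voxels(p[k, ], p[k + 1L, ], tissue$params$fiber_radius,
                           geometry, dims)
        if (nrow(idx)) vol[idx] <- TRUE
      }
    }
  } else {
    for (k in seq_len(nrow(tissue$cells))) {
      cc <- tissue$cells[k, ]
      idx <- ellipsoid_voxels(c(cc$x, cc$y, cc$z), c(cc$a, cc$b, cc$c),
                              geometry, dims)
      if (nrow(idx)) vol[idx] <- TRUE
    }
  }
  vol
}

# 1-based voxel index matrix of voxels whose centre lies within `radius`
# of the segment p1-p2; only the segment's bounding box is evaluated.
tube_voxels <- function(p1, p2, radius, geometry, dims) {
  sp <- geometry$voxel_spacing
  lo <- pmax(floor((pmin(p1, p2) - radius) / sp), 0)
  hi <- pmin(ceiling((pmax(p1, p2) + radius) / sp), dims - 1)
  if (any(hi < lo)) return(matrix(integer(), 0, 3))
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                             z = lo[3]:hi[3]))
  pts <- sweep(g, 2, sp, `*`)
  inside <- point_segment_distance(pts, p1, p2) <= radius
  g[inside, , drop = FALSE] + 1L
}

ellipsoid_voxels <- function(center, semi, geometry, dims) {
  sp <- geometry$voxel_spacing
  lo <- pmax(floor((center - semi) / sp), 0)
  hi <- pmin(ceiling((center + semi) / sp), dims - 1)
  if (any(hi < lo)) return(matrix(integer(), 0, 3))
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                             z = lo[3]:hi[3]))
  pts <- sweep(g, 2, sp, `*`)
  u <- sweep(sweep(pts, 2, center), 2, semi, `/`)
  g[rowSums(u^2) <= 1, , drop = FALSE] + 1L
}

# Distance from each row of pts to segment p1-p2.
point_segment_distance <- function(pts, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, p1)^2)))
  }
  t <- pmin(pmax((sweep(pts, 2, p1) %*% d) / len2, 0), 1)
  proj <- sweep(t %*% t(d), 2, p1, `+`)
  sqrt(rowSums((pts - proj)^2))
}

#' Write a binary stack as a multi-page TIFF
#'
#' One page per z-slice, black/white. Physical spacing is not written to
#' tags; supply it alongside via a [volume_geometry()].
#'
#' @param vol logical or numeric 3D array `[x, y, z]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  dims <- dim(vol)
  stopifnot(length(dims) == 3L)
  pages <- lapply(seq_len(dims[3]), function(z) {
    # TIFF rows are y, columns x
    t(matrix(as.numeric(vol[, , z]), dims[1], dims[2]))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack()]
#'
#' @param path file path.
#' @return logical 3D array `[x, y, z]` (foreground = value > 0.5).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  vol <- array(FALSE, dim = dims)
  for (z in seq_along(pages)) {
    vol[, , z] <- t(pages[[z]]) > 0.5
  }
  vol
}
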