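#' Volume geometry: voxel spacing, dimensions, and modality
#'
#' Describes the sampling grid of one imaged volume. All physical
#' coordinates in the package are micrometres (um), with the origin at a
#' stack corner on the skin surface and z increasing with depth into the
#' tissue. Spacing may be anisotropic: intravital two-photon stacks are
#' typically sampled more coarsely (and may be stretched) in z relative to
#' serial-section EM reconstructions, so spacing is always supplied
#' explicitly per modality and never inferred.
#'
#' @param voxel_spacing numeric length-3, um per voxel along x, y, z; all > 0.
#' @param dimensions integer length-3, voxel counts per axis; all >= 1.
#' @param modality one of `"LM_2PEM"` (light/two-photon frame) or
#'   `"EM_SERIAL"` (serial-section EM frame).
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry(c(0.5, 0.5, 2), c(512, 512, 75), "LM_2PEM")
#' physical_extent(g)
#' @export
volume_geometry <- function(voxel_spacing, dimensions,
                            modality = c("LM_2PEM", "EM_SERIAL")) {
  modality <- match.arg(modality)
  voxel_spacing <- as.numeric(voxel_spacing)
  dimensions <- as.integer(dimensions)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be 3 finite positive values (um/voxel)",
         call. = FALSE)
  }
  if (length(dimensions) != 3L || any(is.na(dimensions)) ||
      any(dimensions < 1L)) {
    stop("`dimensions` must be 3 positive voxel counts", call. = FALSE)
  }
  structure(
    list(voxel_spacing = voxel_spacing, dimensions = dimensions,
         modality = modality),
    class = "volume_geometry"
  )
}

#' @export
print.volume_geometry <- function(x, ...) {
  ext <- physical_extent(x)
  cat(sprintf(
    "<volume_geometry> %s: %d x %d x %d voxels, spacing (%g, %g, %g) um, extent %.1f x %.1f x %.1f um\n",
    x$modality, x$dimensions[1], x$dimensions[2], x$dimensions[3],
    x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3],
    ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Physical extent of a volume in micrometres
#'
#' @param geometry a [volume_geometry()].
#' @return numeric length-3, spacing x dimensions per axis (um).
#' @export
physical_extent <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  geometry$voxel_spacing * geometry$dimensions
}

#' Convert voxel indices to physical coordinates
#'
#' Voxel indexing is 0-based and a voxel's physical position is its centre
#' offset, i.e. index times spacing; `(0,0,0)` maps to the physical origin.
#'
#' @param voxel_coords integer matrix (n x 3) or length-3 vector of 0-based
#'   voxel indices.
#' @param geometry a [volume_geometry()].
#' @return numeric matrix (n x 3) of um coordinates (columns x, y, z).
#' @seealso [to_voxel()]
#' @export
to_physical <- function(voxel_coords, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  v <- as_point_matrix(voxel_coords)
  for (ax in 1:3) {
    bad <- v[, ax] < 0 | v[, ax] > geometry$dimensions[ax] - 1L
    if (any(bad)) {
      stop(sprintf("voxel index out of bounds on axis %s (allowed 0..%d)",
                   c("x", "y", "z")[ax], geometry$dimensions[ax] - 1L),
           call. = FALSE)
    }
  }
  p <- sweep(v, 2, geometry$voxel_spacing, `*`)
  colnames(p) <- c("x", "y", "z")
  p
}

#' Convert physical coordinates to nearest voxel indices
#'
#' Inverse of [to_physical()] on the voxel lattice (rounds to the nearest
#' voxel centre).
#'
#' @param points numeric matrix (n x 3) or length-3 vector, um.
#' @param geometry a [volume_geometry()].
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
to_voxel <- function(points, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  p <- as_point_matrix(points)
  v <- round(sweep(p, 2, geometry$voxel_spacing, `/`))
  for (ax in 1:3) {
    bad <- v[, ax] < 0 | v[, ax] > geometry$dimensions[ax] - 1L
    if (any(bad)) {
      stop(sprintf("physical coordinate outside the volume on axis %s",
                   c("x", "y", "z")[ax]), call. = FALSE)
    }
  }
  storage.mode(v) <- "integer"
  colnames(v) <- c("x", "y", "z")
  v
}

# Coerce a length-3 vector / data.frame / matrix to an n x 3 numeric matrix,
# insisting on finite values.
as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    points <- if (length(cols) == 3L) as.matrix(points[, cols]) else
      as.matrix(points)
  }
  if (is.null(dim(points))) {
    if (length(points) != 3L) {
      stop("points must be a length-3 vector or an n x 3 matrix",
           call. = FALSE)
    }
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)",
                               call. = FALSE)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite coordinate", call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  points
}
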