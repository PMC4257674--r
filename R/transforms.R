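#' Spatial transforms between the two volume frames
#'
#' Four transform families map the in-vivo (LM) frame into the EM block
#' frame, in increasing order of flexibility:
#' \describe{
#'   \item{rigid}{translation + proper rotation only — no deformation.}
#'   \item{similarity}{rigid plus one global scale, capturing the uniform
#'     shrinkage/swelling of chemical fixation.}
#'   \item{affine}{arbitrary invertible linear map + translation
#'     (anisotropic stretch and shear).}
#'   \item{thin-plate spline (Bookstein)}{affine part plus a radial-kernel
#'     bending term that interpolates the paired landmarks exactly at
#'     `lambda = 0`.}
#' }
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric length-3, um.
#' @return A transform object (classes `rigid_transform`,
#'   `similarity_transform`, `affine_transform`, `tps_transform`; all also
#'   `spatial_transform`).
#' @name spatial_transforms
NULL

#' @rdname spatial_transforms
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation(rotation)
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = c("rigid_transform", "spatial_transform"))
}

#' @rdname spatial_transforms
#' @param scale positive scalar.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  check_rotation(rotation)
  if (!is.finite(scale) || scale <= 0) {
    stop("scale must be a positive scalar", call. = FALSE)
  }
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = c("similarity_transform", "spatial_transform"))
}

#' @rdname spatial_transforms
#' @param linear 3x3 invertible matrix.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- as.matrix(linear)
  stopifnot(all(dim(linear) == c(3L, 3L)))
  if (abs(det(linear)) <= 1e-12) {
    stop("affine linear part is singular", call. = FALSE)
  }
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = c("affine_transform", "spatial_transform"))
}

#' @rdname spatial_transforms
#' @param control_points n x 3 matrix of source landmark positions (um).
#' @param affine_part an [affine_transform()].
#' @param warp_coefficients n x 3 matrix, one 3-vector per control point.
#' @param lambda regularization used at fit time (>= 0).
#' @export
tps_transform <- function(control_points, affine_part, warp_coefficients,
                          lambda = 0) {
  control_points <- as_point_matrix(control_points)
  warp_coefficients <- as.matrix(warp_coefficients)
  stopifnot(inherits(affine_part, "affine_transform"),
            nrow(warp_coefficients) == nrow(control_points),
            ncol(warp_coefficients) == 3L, lambda >= 0)
  # side conditions: sum w = 0 and sum w * c = 0 per output axis, so the
  # warp vanishes at infinity relative to the affine part
  s0 <- colSums(warp_coefficients)
  s1 <- crossprod(control_points, warp_coefficients)
  if (max(abs(s0)) > 1e-8 * (1 + max(abs(warp_coefficients))) ||
      max(abs(s1)) > 1e-6 * (1 + max(abs(control_points)) *
                               max(abs(warp_coefficients)))) {
    stop("TPS side conditions violated", call. = FALSE)
  }
  structure(list(control_points = control_points, affine_part = affine_part,
                 warp_coefficients = warp_coefficients, lambda = lambda),
            class = c("tps_transform", "spatial_transform"))
}

check_rotation <- function(rotation) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation is not orthonormal", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("rotation has determinant -1 (a reflection)", call. = FALSE)
  }
  invisible(rotation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation angle %.3f deg, translation (%.3g, %.3g, %.3g) um\n",
              rotation_angle_deg(x$rotation), x$translation[1],
              x$translation[2], x$translation[3]))
  invisible(x)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6f, rotation angle %.3f deg, translation (%.3g, %.3g, %.3g) um\n",
              x$scale, rotation_angle_deg(x$rotation), x$translation[1],
              x$translation[2], x$translation[3]))
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> det %.6f, translation (%.3g, %.3g, %.3g) um\n",
              det(x$linear), x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d control points, lambda %g, bending energy %.4g\n",
              nrow(x$control_points), x$lambda, tps_bending_energy(x)))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a spatial transform to points
#'
#' @param transform any `spatial_transform`.
#' @param points n x 3 numeric matrix (or length-3 vector), um; order is
#'   preserved.
#' @return n x 3 matrix of transformed coordinates, um.
#' @export
apply_transform <- function(transform, points) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.rigid_transform <- function(transform, points) {
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' @export
apply_transform.similarity_transform <- function(transform, points) {
  p <- as_point_matrix(points)
  sweep(transform$scale * (p %*% t(transform$rotation)), 2,
        transform$translation, `+`)
}

#' @export
apply_transform.affine_transform <- function(transform, points) {
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$linear), 2, transform$translation, `+`)
}

#' @export
apply_transform.tps_transform <- function(transform, points) {
  p <- as_point_matrix(points)
  out <- apply_transform(transform$affine_part, p)
  # U(r) = r: 3D biharmonic kernel
  K <- cross_dist(p, transform$control_points)
  out + K %*% transform$warp_coefficients
}

#' Invert a linear-family transform
#'
#' Defined for rigid, similarity and affine transforms; the thin-plate
#' spline has no closed-form inverse (refit with source and target swapped
#' instead).
#'
#' @param transform a rigid, similarity, or affine transform.
#' @return The inverse transform, same class.
#' @export
invert_transform <- function(transform) {
  UseMethod("invert_transform")
}

#' @export
invert_transform.rigid_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @export
invert_transform.similarity_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(1 / transform$scale, Rt,
                       -as.numeric(Rt %*% transform$translation) /
                         transform$scale)
}

#' @export
invert_transform.affine_transform <- function(transform) {
  Ai <- solve(transform$linear)
  affine_transform(Ai, -as.numeric(Ai %*% transform$translation))
}

#' @export
invert_transform.tps_transform <- function(transform) {
  stop("a thin-plate spline has no closed-form inverse; refit with the ",
       "pairing direction swapped", call. = FALSE)
}

#' Bending energy of a thin-plate spline
#'
#' The quadratic form of the warp coefficients under the radial kernel,
#' summed over output axes; zero exactly when the mapping is affine.
#'
#' @param transform a `tps_transform`.
#' @return non-negative scalar.
#' @export
tps_bending_energy <- function(transform) {
  stopifnot(inherits(transform, "tps_transform"))
  K <- cross_dist(transform$control_points, transform$control_points)
  # -W' K W >= 0 on the side-condition subspace for U(r) = r
  e <- -sum(transform$warp_coefficients * (K %*% transform$warp_coefficients))
  max(e, 0)
}

# Euclidean cross-distance matrix between two point sets. Computed from
# coordinate differences (not the expanded inner-product form, which loses
# precision for nearby points far from the origin).
cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], `-`)^2 +
         outer(a[, 2], b[, 2], `-`)^2 +
         outer(a[, 3], b[, 3], `-`)^2)
}

#' Serialize a transform to a JSON file
#'
#' Stores the kind, all parameters (including TPS control points and
#' lambda), and creation metadata, for reuse by the `dock` command.
#'
#' @param transform any `spatial_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  kind <- transform_kind(transform)
  payload <- list(kind = kind,
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  tool = paste0("clemdock ",
                                as.character(utils::packageVersion("clemdock"))))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  payload <- c(payload, strip(transform))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#'
#' @param path file path.
#' @return A `spatial_transform`.
#' @export
read_transform <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(p$kind,
    rigid = rigid_transform(as.matrix(p$rotation), p$translation),
    similarity = similarity_transform(p$scale, as.matrix(p$rotation),
                                      p$translation),
    affine = affine_transform(as.matrix(p$linear), p$translation),
    tps = tps_transform(as.matrix(p$control_points),
                        affine_transform(as.matrix(p$affine_part$linear),
                                         p$affine_part$translation),
                        as.matrix(p$warp_coefficients), p$lambda),
    stop("unknown transform kind: ", p$kind, call. = FALSE))
}

transform_kind <- function(transform) {
  if (inherits(transform, "rigid_transform")) "rigid"
  else if (inherits(transform, "similarity_transform")) "similarity"
  else if (inherits(transform, "affine_transform")) "affine"
  else if (inherits(transform, "tps_transform")) "tps"
  else stop("not a spatial_transform", call. = FALSE)
}
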