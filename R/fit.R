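#' Fit a rigid transform (translation + rotation) to paired landmarks
#'
#' Least-squares rigid alignment of the source onto the target landmarks:
#' both sets are centred on their centroids and the optimal proper rotation
#' is taken from the orthogonal-Procrustes (Kabsch) solution of the
#' cross-covariance SVD. If the unconstrained optimum is a reflection —
#' which would mean one modality's axes are flipped relative to the other —
#' the smallest singular direction is flipped to give a proper rotation and
#' a warning is emitted, because an axis flip should be fixed upstream.
#'
#' @param pairing a `landmark_pairing` with at least 3 non-collinear pairs.
#' @return A [rigid_transform()].
#' @family landmark fitting
#' @export
fit_rigid <- function(pairing) {
  xy <- fit_input(pairing, min_pairs = 3L, degeneracy = "collinear")
  k <- kabsch(xy$source, xy$target, allow_scale = FALSE)
  rigid_transform(k$rotation, k$translation)
}

#' Fit a similarity transform (rigid + one global scale)
#'
#' The Umeyama extension of the Procrustes fit: the optimal scale is the
#' ratio of the rotated cross-covariance trace to the source variance. A
#' fitted scale below 1 corresponds to global specimen shrinkage during EM
#' processing (glutaraldehyde fixation shrinks tissue on the order of a few
#' percent); above 1 to swelling.
#'
#' @inheritParams fit_rigid
#' @return A [similarity_transform()].
#' @family landmark fitting
#' @export
fit_similarity <- function(pairing) {
  xy <- fit_input(pairing, min_pairs = 3L, degeneracy = "collinear")
  k <- kabsch(xy$source, xy$target, allow_scale = TRUE)
  similarity_transform(k$scale, k$rotation, k$translation)
}

#' Fit an affine transform to paired landmarks
#'
#' Ordinary least squares on homogeneous coordinates; captures anisotropic
#' stretch and shear (the global part of the embedding deformation).
#'
#' @param pairing a `landmark_pairing` with at least 4 non-coplanar pairs.
#' @return An [affine_transform()].
#' @family landmark fitting
#' @export
fit_affine <- function(pairing) {
  xy <- fit_input(pairing, min_pairs = 4L, degeneracy = "coplanar")
  X <- cbind(xy$source, 1)
  beta <- qr.solve(X, xy$target)           # 4 x 3
  affine_transform(t(beta[1:3, , drop = FALSE]), beta[4, ])
}

#' Fit a Bookstein thin-plate-spline transform
#'
#' Solves the standard TPS system per output axis with the 3D radial kernel
#' `U(r) = r` (the biharmonic fundamental solution in 3D; the 2D
#' `r^2 log r` kernel does not apply). With `lambda = 0` the spline
#' interpolates: every control point is mapped exactly onto its paired
#' target, forcing the paired landmarks to overlap. `lambda > 0` trades
#' control-point fidelity for smoothness and is appropriate for noisy
#' pairings.
#'
#' The constrained system is solved via a QR null-space reduction of the
#' polynomial constraint block, which enforces the side conditions
#' (vanishing total and first-moment warp coefficients) exactly.
#'
#' @param pairing a `landmark_pairing` with at least 5 pairs, not all
#'   coplanar.
#' @param lambda regularization weight, >= 0, in um kernel units.
#' @return A [tps_transform()].
#' @family landmark fitting
#' @export
fit_tps <- function(pairing, lambda = 0) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  xy <- fit_input(pairing, min_pairs = 5L, degeneracy = "coplanar")
  src <- xy$source
  n <- nrow(src)
  K <- cross_dist(src, src)
  if (any(K[upper.tri(K)] < 1e-9)) {
    idx <- which(K < 1e-9 & upper.tri(K), arr.ind = TRUE)[1, ]
    stop(sprintf("coincident source control points: '%s' and '%s'",
                 pairing$pairs$source_id[idx[1]],
                 pairing$pairs$source_id[idx[2]]), call. = FALSE)
  }
  P <- cbind(1, src)                       # n x 4
  qrP <- qr(P)
  Q <- qr.Q(qrP, complete = TRUE)
  Q2 <- Q[, 5:n, drop = FALSE]             # null space of t(P)
  # with the sign-positive kernel U(r) = r the quadratic form W'KW is
  # conditionally negative (bending energy = -W'KW), so the smoothing
  # term enters as -lambda: this is the classical (K~ + lambda I) system
  # rewritten from the K~ = -r convention, and keeps the lambda trade-off
  # monotone
  A <- K - lambda * diag(n)
  M <- crossprod(Q2, A %*% Q2)
  cn <- kappa(M, exact = FALSE)
  if (is.finite(cn) && cn > 1e12) {
    warning("near-singular TPS system (condition estimate ",
            format(cn, digits = 3),
            "); consider raising lambda", call. = FALSE)
  }
  solve_constrained <- function(Y) {
    gamma <- solve(M, crossprod(Q2, Y))
    W <- Q2 %*% gamma                      # satisfies t(P) W = 0
    # affine part from the remaining least-squares problem P B ~ Y - A W
    B <- qr.coef(qrP, Y - A %*% W)
    list(W = W, B = B)
  }
  sol <- solve_constrained(xy$target)
  # one step of iterative refinement against the full system, to keep the
  # coefficients accurate despite the um-scale conditioning of the kernel
  resid <- xy$target - (A %*% sol$W + P %*% sol$B)
  corr <- solve_constrained(resid)
  W <- sol$W + corr$W
  B <- sol$B + corr$B
  tps_transform(src,
                affine_transform(t(B[2:4, , drop = FALSE]), B[1, ]),
                W, lambda)
}

#' Fit any transform family by name
#'
#' @param pairing a `landmark_pairing`.
#' @param method `"rigid"`, `"similarity"`, `"affine"` or `"tps"`.
#' @param lambda TPS regularization (ignored otherwise).
#' @return A fitted `spatial_transform`.
#' @family landmark fitting
#' @export
fit_transform <- function(pairing,
                          method = c("tps", "rigid", "similarity", "affine"),
                          lambda = 0) {
  method <- match.arg(method)
  switch(method,
         rigid = fit_rigid(pairing),
         similarity = fit_similarity(pairing),
         affine = fit_affine(pairing),
         tps = fit_tps(pairing, lambda = lambda))
}

#' Minimum pair count required by a transform family
#'
#' @param method transform kind.
#' @return integer: 3 (rigid/similarity), 4 (affine), or 5 (TPS).
#' @export
min_pairs_for <- function(method = c("rigid", "similarity", "affine",
                                     "tps")) {
  method <- match.arg(method)
  c(rigid = 3L, similarity = 3L, affine = 4L, tps = 5L)[[method]]
}

# Validate the pairing for fitting and return paired coordinate matrices.
# Degeneracy (collinear / coplanar source points) is detected from the
# singular-value ratio of the centred source coordinates.
fit_input <- function(pairing, min_pairs, degeneracy) {
  stopifnot(inherits(pairing, "landmark_pairing"))
  n <- n_pairs(pairing)
  if (n < min_pairs) {
    stop(sprintf("at least %d landmark pairs required, got %d",
                 min_pairs, n), call. = FALSE)
  }
  xy <- pairing_coords(pairing)
  ctr <- sweep(xy$source, 2, colMeans(xy$source))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  rank_needed <- if (degeneracy == "collinear") 2L else 3L
  if (sv[1] <= 0 || sv[rank_needed] / sv[1] < 1e-8) {
    stop(sprintf("degenerate landmark configuration: source points are %s",
                 degeneracy), call. = FALSE)
  }
  xy
}

# Kabsch / Umeyama point-set alignment on paired n x 3 matrices.
kabsch <- function(source, target, allow_scale = FALSE) {
  mu_s <- colMeans(source)
  mu_t <- colMeans(target)
  Xc <- sweep(source, 2, mu_s)
  Yc <- sweep(target, 2, mu_t)
  H <- crossprod(Xc, Yc)                   # 3 x 3 cross-covariance * n
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d < 0) {
    warning("optimal alignment is a reflection; corrected to a proper ",
            "rotation -- check for an axis flip between modalities",
            call. = FALSE)
  }
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  scale <- if (allow_scale) {
    sum(sv$d * c(1, 1, d)) / sum(Xc^2)
  } else 1
  list(rotation = R, scale = scale,
       translation = as.numeric(mu_t - scale * R %*% mu_s))
}
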