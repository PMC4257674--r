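#' EM-processing deformation model
#'
#' Parametric model of what chemical fixation, dehydration and resin
#' embedding do to a tissue block: a global anisotropic scaling about the
#' volume centroid (glutaraldehyde fixation shrinks tissue by around 5%;
#' osmium fixation can swell it) plus a sum of smooth Gaussian
#' displacement bumps representing the non-homogeneous local distortions
#' that make the two volumes disagree with any purely linear map. With
#' unit scales and no bumps the model is the identity. The model also
#' carries the landmark observation parameters: isotropic localization
#' noise and a detection dropout rate.
#'
#' @param global_scales numeric length-3 `(sx, sy, sz)` applied about
#'   `center`.
#' @param bump_centers k x 3 matrix, um (or NULL for none).
#' @param bump_amplitudes k x 3 matrix of displacement vectors, um.
#' @param bump_widths length-k Gaussian widths, um.
#' @param detection_noise_sd landmark localization noise sd per axis, um.
#' @param dropout_rate probability a landmark is missed in one modality.
#' @return An object of class `deformation_model`.
#' @export
deformation_model <- function(global_scales = c(1, 1, 1),
                              bump_centers = NULL,
                              bump_amplitudes = NULL,
                              bump_widths = NULL,
                              detection_noise_sd = 0,
                              dropout_rate = 0) {
  global_scales <- as.numeric(global_scales)
  stopifnot(length(global_scales) == 3L, all(global_scales > 0),
            detection_noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1)
  k <- 0L
  if (!is.null(bump_centers)) {
    bump_centers <- as_point_matrix(bump_centers)
    bump_amplitudes <- as_point_matrix(bump_amplitudes)
    bump_widths <- as.numeric(bump_widths)
    k <- nrow(bump_centers)
    stopifnot(nrow(bump_amplitudes) == k, length(bump_widths) == k,
              all(bump_widths > 0))
  }
  structure(list(global_scales = global_scales,
                 bump_centers = bump_centers,
                 bump_amplitudes = bump_amplitudes,
                 bump_widths = bump_widths,
                 n_bumps = k,
                 detection_noise_sd = detection_noise_sd,
                 dropout_rate = dropout_rate),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat(sprintf(
    "<deformation_model> scales (%.3f, %.3f, %.3f), %d bump(s), noise sd %g um, dropout %g\n",
    x$global_scales[1], x$global_scales[2], x$global_scales[3], x$n_bumps,
    x$detection_noise_sd, x$dropout_rate))
  invisible(x)
}

#' Default EM-processing deformation for a given volume
#'
#' The standard test-bed distortion: 5% isotropic shrinkage (the reported
#' magnitude of glutaraldehyde fixation) about the volume centroid, plus 3
#' random smooth bumps (amplitude up to 8 um per axis, width 120 um) that
#' make the deformation non-homogeneous, with 2 um landmark localization
#' noise and a 10% detection dropout.
#'
#' @param extent volume extent (x, y, z), um; bump centers are drawn
#'   inside it.
#' @param n_bumps number of Gaussian bumps.
#' @param bump_amplitude maximum per-axis bump displacement, um.
#' @param bump_width Gaussian width, um.
#' @param shrinkage fractional global shrinkage (0.05 = 5%).
#' @param detection_noise_sd,dropout_rate observation parameters.
#' @return A [deformation_model()]; bump placement uses the current RNG
#'   stream.
#' @export
default_deformation <- function(extent = c(400, 400, 150), n_bumps = 3L,
                                bump_amplitude = 8, bump_width = 120,
                                shrinkage = 0.05,
                                detection_noise_sd = 2,
                                dropout_rate = 0.1) {
  centers <- cbind(stats::runif(n_bumps, 0, extent[1]),
                   stats::runif(n_bumps, 0, extent[2]),
                   stats::runif(n_bumps, 0, extent[3]))
  amps <- matrix(stats::runif(3 * n_bumps, -bump_amplitude, bump_amplitude),
                 n_bumps, 3)
  deformation_model(global_scales = rep(1 - shrinkage, 3),
                    bump_centers = centers,
                    bump_amplitudes = amps,
                    bump_widths = rep(bump_width, n_bumps),
                    detection_noise_sd = detection_noise_sd,
                    dropout_rate = dropout_rate)
}

#' Map points through a deformation model
#'
#' `q = center + S (p - center) + sum_k a_k exp(-|p - c_k|^2 / (2 w_k^2))`
#'
#' @param model a [deformation_model()].
#' @param points n x 3 matrix, um.
#' @param center scaling fixed point (the volume centroid), um.
#' @return n x 3 matrix of deformed coordinates, um.
#' @export
deform_points <- function(model, points, center) {
  stopifnot(inherits(model, "deformation_model"))
  p <- as_point_matrix(points)
  center <- as.numeric(center)
  out <- sweep(sweep(p, 2, center), 2, model$global_scales, `*`)
  out <- sweep(out, 2, center, `+`)
  if (model$n_bumps > 0L) {
    for (k in seq_len(model$n_bumps)) {
      d2 <- rowSums(sweep(p, 2, model$bump_centers[k, ])^2)
      g <- exp(-d2 / (2 * model$bump_widths[k]^2))
      out <- out + outer(g, model$bump_amplitudes[k, ])
    }
  }
  out
}

#' Apply EM processing to a synthetic tissue
#'
#' Maps every ground-truth point of the tissue through the deformation
#' (about the volume centroid) and returns both frames plus the exact
#' point-to-point correspondence — the oracle for registration tests.
#'
#' @param tissue a [generate_tissue()] result (the in-vivo frame).
#' @param model a [deformation_model()].
#' @return list of class `em_processed`: `lm_tissue` (input),
#'   `em_tissue` (deformed copy), `correspondence` (data.frame `id`,
#'   `feature_class`, LM and EM coordinates of every ground-truth point),
#'   `center` (fixed point used), `model`.
#' @export
apply_em_processing <- function(tissue, model) {
  stopifnot(inherits(tissue, "synthetic_tissue"),
            inherits(model, "deformation_model"))
  center <- tissue$extent / 2
  warp <- function(m) deform_points(model, m, center)

  em <- tissue
  vn <- as.matrix(tissue$vessel_nodes[, c("x", "y", "z")])
  em$vessel_nodes[, c("x", "y", "z")] <- warp(vn)
  em$bifurcations <- warp(tissue$bifurcations)
  em$fibers <- fiber_set(lapply(tissue$fibers$polylines, warp))
  if (nrow(tissue$fiber_crossings)) {
    em$fiber_crossings <- warp(tissue$fiber_crossings)
  }
  if (nrow(tissue$cells)) {
    em$cells[, c("x", "y", "z")] <- warp(as.matrix(
      tissue$cells[, c("x", "y", "z")]))
  }
  em$nirb_frame <- warp(tissue$nirb_frame)

  truth <- true_landmarks(tissue)$landmarks
  lm_xyz <- as.matrix(truth[, c("x", "y", "z")])
  em_xyz <- warp(lm_xyz)
  correspondence <- data.frame(
    id = truth$id, feature_class = truth$feature_class,
    lm_x = lm_xyz[, 1], lm_y = lm_xyz[, 2], lm_z = lm_xyz[, 3],
    em_x = em_xyz[, 1], em_y = em_xyz[, 2], em_z = em_xyz[, 3],
    stringsAsFactors = FALSE)

  structure(list(lm_tissue = tissue, em_tissue = em,
                 correspondence = correspondence, center = center,
                 model = model),
            class = "em_processed")
}

#' Observe a landmark set with localization noise and dropout
#'
#' Adds independent zero-mean Gaussian noise (sd per axis =
#' `detection_noise_sd`) to each landmark and drops each independently
#' with probability `dropout_rate`. Ids are preserved for kept landmarks,
#' so the ground-truth pairing between modalities remains known.
#'
#' @param set a [landmark_set()] of true positions.
#' @param model a [deformation_model()] (supplies noise sd and dropout), or
#'   NULL to use the explicit arguments.
#' @param detection_noise_sd,dropout_rate overrides when `model` is NULL.
#' @return A noisy [landmark_set()] (possibly smaller); draws from the
#'   current RNG stream.
#' @export
observe_landmarks <- function(set, model = NULL, detection_noise_sd = 0,
                              dropout_rate = 0) {
  stopifnot(inherits(set, "landmark_set"))
  if (!is.null(model)) {
    stopifnot(inherits(model, "deformation_model"))
    detection_noise_sd <- model$detection_noise_sd
    dropout_rate <- model$dropout_rate
  }
  lm <- set$landmarks
  keep <- stats::runif(nrow(lm)) >= dropout_rate
  lm <- lm[keep, , drop = FALSE]
  if (nrow(lm) && detection_noise_sd > 0) {
    lm[, c("x", "y", "z")] <- lm[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(lm), 0, detection_noise_sd),
             nrow(lm), 3)
  }
  landmark_set(lm, geometry = set$geometry,
               name = paste0(set$name, " (observed)"),
               min_separation = 0, nirb_surface_band = Inf)
}
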