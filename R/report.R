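#' Per-landmark offset vectors and summary residuals of a fit
#'
#' For every pair, the offset vector is `target - transform(source)`:
#' the magnitude (um) and direction of the remaining misalignment at each
#' landmark after registration. Rigid fits on EM-processed tissue leave
#' visible offsets because the embedding deformation is non-uniform; an
#' interpolating thin-plate spline reduces control-point offsets to zero.
#'
#' @param transform a fitted `spatial_transform`.
#' @param pairing the `landmark_pairing` to evaluate against.
#' @return An object of class `registration_report`: data.frame `offsets`
#'   (`source_id`, `target_id`, `dx`, `dy`, `dz`, `magnitude`), plus
#'   `rms`, `max`, `kind`, `n_pairs`.
#' @export
residual_report <- function(transform, pairing) {
  stopifnot(inherits(transform, "spatial_transform"),
            inherits(pairing, "landmark_pairing"))
  xy <- pairing_coords(pairing)
  pred <- apply_transform(transform, xy$source)
  off <- xy$target - pred
  mag <- sqrt(rowSums(off^2))
  structure(
    list(offsets = data.frame(source_id = pairing$pairs$source_id,
                              target_id = pairing$pairs$target_id,
                              dx = off[, 1], dy = off[, 2], dz = off[, 3],
                              magnitude = mag, stringsAsFactors = FALSE),
         rms = sqrt(mean(mag^2)),
         max = max(mag),
         kind = transform_kind(transform),
         n_pairs = nrow(off)),
    class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf(
    "<registration_report> %s fit, %d pairs: RMS offset %.3f um, max %.3f um\n",
    x$kind, x$n_pairs, x$rms, x$max))
  invisible(x)
}

#' Leave-one-out docking error per landmark
#'
#' Cross-validated proxy for the accuracy with which a structure can be
#' predicted inside the block: each landmark pair in turn is held out, the
#' transform is refitted on the remaining pairs, and the held-out source
#' point is predicted and compared to its true target position. The median
#' of these errors is the accuracy estimate attached to a docking.
#'
#' @param pairing a `landmark_pairing` with at least one pair more than the
#'   fitting minimum of `method`.
#' @param method transform kind (see [fit_transform()]).
#' @param lambda TPS regularization.
#' @return An object of class `loo_errors`: data.frame `errors`
#'   (`source_id`, `error`, um, in pairing order), plus `median` and `max`.
#' @export
loo_docking_error <- function(pairing,
                              method = c("tps", "rigid", "similarity",
                                         "affine"),
                              lambda = 0) {
  method <- match.arg(method)
  n <- n_pairs(pairing)
  need <- min_pairs_for(method) + 1L
  if (n < need) {
    stop(sprintf(
      "leave-one-out with method '%s' needs at least %d pairs, got %d",
      method, need, n), call. = FALSE)
  }
  errs <- vapply(seq_len(n), function(i) {
    sub <- landmark_pairing(pairing$source, pairing$target,
                            pairing$pairs[-i, , drop = FALSE])
    tf <- fit_transform(sub, method = method, lambda = lambda)
    src_i <- landmark_coords(pairing$source, pairing$pairs$source_id[i])
    tgt_i <- landmark_coords(pairing$target, pairing$pairs$target_id[i])
    sqrt(sum((apply_transform(tf, src_i) - tgt_i)^2))
  }, numeric(1))
  structure(list(errors = data.frame(source_id = pairing$pairs$source_id,
                                     error = errs,
                                     stringsAsFactors = FALSE),
                 median = stats::median(errs),
                 max = max(errs),
                 method = method),
            class = "loo_errors")
}

#' @export
print.loo_errors <- function(x, ...) {
  cat(sprintf(
    "<loo_errors> %s, %d landmarks: median %.2f um, max %.2f um\n",
    x$method, nrow(x$errors), x$median, x$max))
  invisible(x)
}
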