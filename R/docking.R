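#' Region of interest in the in-vivo frame
#'
#' @param label name of the ROI (e.g. the tracked tumor cell).
#' @param points n x 3 matrix (um, LM frame): the cell centroid and any
#'   outline/surface points.
#' @return An object of class `region_of_interest`.
#' @export
region_of_interest <- function(label, points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 1L) stop("ROI needs at least one point", call. = FALSE)
  structure(list(label = as.character(label), points = points),
            class = "region_of_interest")
}

#' @export
print.region_of_interest <- function(x, ...) {
  cat(sprintf("<region_of_interest> '%s': %d point(s)\n", x$label,
              nrow(x$points)))
  invisible(x)
}

#' Dock a region of interest into the EM block frame
#'
#' Projects the ROI through the fitted transform and attaches an accuracy
#' estimate: the median leave-one-out docking error of the same transform
#' family on the same pairing. The boolean `within_claimed_accuracy`
#' compares that estimate against the 20 um reference accuracy reported for
#' landmark-based targeting in EM-processed tissue. ROI points far outside
#' the landmark cloud (beyond `extrapolation_margin` of the bounding-box
#' diagonal) trigger an extrapolation flag, because a thin-plate spline is
#' only trustworthy inside the region spanned by its control points.
#'
#' @param transform transform fitted on `pairing`.
#' @param roi a [region_of_interest()] in the source (LM) frame.
#' @param pairing the `landmark_pairing` the transform was fitted on.
#' @param lambda TPS regularization used (for the LOO estimate).
#' @param reference_accuracy accuracy reference line, um (default 20).
#' @param extrapolation_margin allowed excursion outside the landmark
#'   bounding box, as a fraction of its diagonal (default 0.25).
#' @return An object of class `docking_result`: `predicted_points` (n x 3,
#'   EM frame), `predicted_z_range`, `accuracy_estimate` (um),
#'   `within_claimed_accuracy`, `extrapolation_flag`, `loo`.
#' @export
dock_roi <- function(transform, roi, pairing, lambda = 0,
                     reference_accuracy = 20, extrapolation_margin = 0.25) {
  stopifnot(inherits(transform, "spatial_transform"),
            inherits(roi, "region_of_interest"),
            inherits(pairing, "landmark_pairing"))
  pred <- apply_transform(transform, roi$points)
  loo <- loo_docking_error(pairing, method = transform_kind(transform),
                           lambda = lambda)
  src <- pairing_coords(pairing)$source
  lo <- apply(src, 2, min)
  hi <- apply(src, 2, max)
  diag_len <- sqrt(sum((hi - lo)^2))
  margin <- extrapolation_margin * diag_len
  extrapolation <- any(roi$points < matrix(lo - margin, nrow(roi$points), 3,
                                           byrow = TRUE) |
                       roi$points > matrix(hi + margin, nrow(roi$points), 3,
                                           byrow = TRUE))
  if (extrapolation) {
    warning("ROI extends beyond the landmark hull margin; docking is an ",
            "extrapolation and its accuracy estimate may be optimistic",
            call. = FALSE)
  }
  structure(
    list(label = roi$label,
         predicted_points = pred,
         predicted_z_range = range(pred[, 3]),
         accuracy_estimate = loo$median,
         within_claimed_accuracy = loo$median <= reference_accuracy,
         extrapolation_flag = extrapolation,
         transform_kind = transform_kind(transform),
         loo = loo),
    class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf(
    "<docking_result> '%s': %d point(s), z range %.2f-%.2f um, accuracy est. %.2f um (%s 20 um reference)%s\n",
    x$label, nrow(x$predicted_points), x$predicted_z_range[1],
    x$predicted_z_range[2], x$accuracy_estimate,
    if (x$within_claimed_accuracy) "within" else "beyond",
    if (x$extrapolation_flag) " [extrapolated]" else ""))
  invisible(x)
}

#' Coarse in-plane alignment from surface branding marks
#'
#' Near-infrared branding (NIRB) burns a frame at the skin surface: the
#' marks give the xy position of the region with high precision but carry
#' no depth information. This fit therefore estimates translation and
#' rotation about the z axis only, with the z translation fixed to zero;
#' any residual z offset between the mark sets is reported, never
#' corrected. Use the result to initialize landmark pair suggestion — not
#' for final docking depth.
#'
#' @param source_marks,target_marks [landmark_set()]s with at least 2
#'   `NIRB_MARK` landmarks each; marks are paired by shared id.
#' @return A [rigid_transform()] (rotation about z, z translation 0) with
#'   attribute `residual_z_offset` (um).
#' @export
coarse_align_nirb <- function(source_marks, target_marks) {
  get_marks <- function(s) {
    lm <- s$landmarks[s$landmarks$feature_class == "NIRB_MARK", ,
                      drop = FALSE]
    if (nrow(lm) < 2L) {
      stop("need at least 2 NIRB_MARK landmarks per side", call. = FALSE)
    }
    lm
  }
  a <- get_marks(source_marks)
  b <- get_marks(target_marks)
  shared <- intersect(a$id, b$id)
  if (length(shared) < 2L) {
    stop("need at least 2 NIRB marks with shared ids", call. = FALSE)
  }
  A <- as.matrix(a[match(shared, a$id), c("x", "y")])
  B <- as.matrix(b[match(shared, b$id), c("x", "y")])
  mu_a <- colMeans(A)
  mu_b <- colMeans(B)
  H <- crossprod(sweep(A, 2, mu_a), sweep(B, 2, mu_b))
  # closed-form 2D rotation angle maximizing alignment
  theta <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
  R2 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t2 <- mu_b - as.numeric(R2 %*% mu_a)
  R <- diag(3)
  R[1:2, 1:2] <- R2
  res_z <- mean(b$z[match(shared, b$id)]) - mean(a$z[match(shared, a$id)])
  out <- rigid_transform(R, c(t2, 0))
  attr(out, "residual_z_offset") <- res_z
  out
}

#' Translate a docking prediction into serial-section guidance
#'
#' Converts the predicted depth range of a docked ROI into the range of
#' section indices an operator must collect. A safety margin equal to the
#' docking accuracy estimate is added on both sides of the predicted z
#' range, and `approach_offset` (depth already removed by trimming or
#' approach sections before the scheme starts) is subtracted first.
#'
#' @param docking a [dock_roi()] result.
#' @param scheme a [sectioning_scheme()] whose origin is the block face.
#' @param approach_offset depth removed before the scheme starts, um.
#' @return list: `first_section`, `last_section` (1-based indices),
#'   `z_window` (um, block frame), and `sections` — a per-section depth
#'   table (`index`, `z_start`, `z_end`, `kind`) over the returned range.
#' @export
depth_to_sections <- function(docking, scheme, approach_offset = 0) {
  stopifnot(inherits(docking, "docking_result"),
            inherits(scheme, "sectioning_scheme"))
  acc <- docking$accuracy_estimate
  z_lo <- docking$predicted_z_range[1] - acc - approach_offset
  z_hi <- docking$predicted_z_range[2] + acc - approach_offset
  total <- total_depth(scheme)
  if (z_hi > total) {
    stop(sprintf(
      "sectioning scheme too shallow: covers %.2f um but the docking window reaches %.2f um (missing %.2f um)",
      total, z_hi, z_hi - total), call. = FALSE)
  }
  tab <- section_table(scheme)
  z_lo <- max(z_lo, 0)
  if (z_hi <= z_lo) {
    # point query: a z exactly on a section boundary goes to the deeper
    # section
    hit <- tab$z_start <= z_lo & z_lo < tab$z_end
    if (!any(hit)) hit <- seq_len(nrow(tab)) == nrow(tab)  # z at full depth
  } else {
    hit <- tab$z_end > z_lo & tab$z_start < z_hi
  }
  idx <- which(hit)
  if (length(idx) == 0L) {
    stop("docking window lies outside the sectioning scheme", call. = FALSE)
  }
  list(first_section = min(idx),
       last_section = max(idx),
       z_window = c(max(z_lo, 0), z_hi),
       sections = tab[idx, , drop = FALSE])
}
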