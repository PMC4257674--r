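FEATURE_CLASSES <- c("VESSEL_BIFURCATION", "FIBER_CROSSING", "NIRB_MARK",
                     "CELL", "OTHER")

#' Labeled 3D landmark set for one modality
#'
#' A landmark set holds uniquely labeled 3D points (um) observed in one
#' volume: vessel bifurcations, collagen-fiber cross-points, near-infrared
#' branding (NIRB) surface marks, cells, or other features. NIRB marks are
#' burned at the skin surface and therefore must lie within a shallow
#' surface band in z; two landmarks closer than `min_separation` signal a
#' digitization error and are rejected.
#'
#' @param landmarks data.frame with columns `id` (unique character),
#'   `x`, `y`, `z` (um), and optionally `feature_class` (one of
#'   `r paste(FEATURE_CLASSES, collapse = ", ")`, default `"OTHER"`) and
#'   `confidence` (in `[0, 1]`, default 1).
#' @param geometry a [volume_geometry()] describing the source volume.
#' @param name free-text label for the set.
#' @param min_separation minimum pairwise distance between landmarks, um.
#' @param nirb_surface_band maximum depth (um) allowed for `NIRB_MARK`
#'   landmarks.
#' @return An object of class `landmark_set` (a validated data.frame plus
#'   geometry).
#' @export
landmark_set <- function(landmarks, geometry = NULL, name = "",
                         min_separation = 1, nirb_surface_band = 10) {
  lm <- as.data.frame(landmarks, stringsAsFactors = FALSE)
  req <- c("id", "x", "y", "z")
  miss <- setdiff(req, names(lm))
  if (length(miss)) {
    stop("landmark table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lm$id <- as.character(lm$id)
  if (anyDuplicated(lm$id)) {
    dup <- unique(lm$id[duplicated(lm$id)])
    stop("duplicate landmark id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    lm[[cc]] <- as.numeric(lm[[cc]])
    if (any(!is.finite(lm[[cc]]))) {
      stop("non-finite coordinate in column ", cc, call. = FALSE)
    }
  }
  if (is.null(lm$feature_class)) lm$feature_class <- rep("OTHER", nrow(lm))
  lm$feature_class <- as.character(lm$feature_class)
  unknown <- !(lm$feature_class %in% FEATURE_CLASSES)
  if (any(unknown)) {
    warning("unknown feature_class mapped to OTHER: ",
            paste(unique(lm$feature_class[unknown]), collapse = ", "),
            call. = FALSE)
    lm$feature_class[unknown] <- "OTHER"
  }
  if (is.null(lm$confidence)) lm$confidence <- rep(1, nrow(lm))
  lm$confidence <- as.numeric(lm$confidence)
  lm$confidence[is.na(lm$confidence)] <- 1
  if (any(lm$confidence < 0 | lm$confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(lm) >= 2L && min_separation > 0) {
    d <- stats::dist(lm[, c("x", "y", "z")])
    if (any(d < min_separation)) {
      idx <- which(as.matrix(d) < min_separation & upper.tri(as.matrix(d)),
                   arr.ind = TRUE)[1, ]
      stop(sprintf(
        "landmarks '%s' and '%s' are closer than the minimum separation (%g um)",
        lm$id[idx[1]], lm$id[idx[2]], min_separation), call. = FALSE)
    }
  }
  nirb <- lm$feature_class == "NIRB_MARK"
  if (any(nirb) && any(lm$z[nirb] > nirb_surface_band)) {
    bad <- lm$id[nirb & lm$z > nirb_surface_band]
    stop(sprintf(
      "NIRB_MARK landmark(s) deeper than the %g um surface band: %s",
      nirb_surface_band, paste(bad, collapse = ", ")), call. = FALSE)
  }
  lm <- lm[, c("id", "x", "y", "z", "feature_class", "confidence")]
  rownames(lm) <- NULL
  structure(list(landmarks = lm, geometry = geometry, name = name),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  tab <- table(factor(x$landmarks$feature_class, levels = FEATURE_CLASSES))
  cat(sprintf("<landmark_set> '%s': %d landmarks (%s)\n",
              x$name, nrow(x$landmarks),
              paste(sprintf("%s: %d", names(tab)[tab > 0], tab[tab > 0]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$landmarks)

#' Extract landmark coordinates as a matrix
#'
#' @param set a [landmark_set()].
#' @param ids optional character vector selecting landmarks in the given
#'   order.
#' @return numeric matrix (n x 3), um; rownames are landmark ids.
#' @export
landmark_coords <- function(set, ids = NULL) {
  stopifnot(inherits(set, "landmark_set"))
  lm <- set$landmarks
  if (!is.null(ids)) {
    pos <- match(ids, lm$id)
    if (anyNA(pos)) {
      stop("unknown landmark id(s): ",
           paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    lm <- lm[pos, , drop = FALSE]
  }
  m <- as.matrix(lm[, c("x", "y", "z")])
  rownames(m) <- lm$id
  m
}

#' Pair two landmark sets by shared ids
#'
#' Builds the ordered correspondences ("paired landmark-sets") that drive
#' registration: ids present in both sets are paired, in the order of the
#' source set; ids present on only one side are reported in the result but
#' not paired.
#'
#' @param source [landmark_set()] in the in-vivo (LM) frame.
#' @param target [landmark_set()] in the EM block frame.
#' @return An object of class `landmark_pairing` with elements `source`,
#'   `target`, `pairs` (data.frame `source_id`, `target_id`),
#'   `unmatched_source`, `unmatched_target`.
#' @export
pair_by_id <- function(source, target) {
  stopifnot(inherits(source, "landmark_set"),
            inherits(target, "landmark_set"))
  if (length(source) == 0L || length(target) == 0L) {
    stop("cannot pair empty landmark sets", call. = FALSE)
  }
  shared <- intersect(source$landmarks$id, target$landmarks$id)
  shared <- source$landmarks$id[source$landmarks$id %in% shared]
  if (length(shared) == 0L) {
    stop("no shared landmark ids between the two sets", call. = FALSE)
  }
  landmark_pairing(source, target,
                   data.frame(source_id = shared, target_id = shared,
                              stringsAsFactors = FALSE))
}

#' Construct a landmark pairing from explicit correspondences
#'
#' @param source,target [landmark_set()] objects.
#' @param pairs data.frame with columns `source_id`, `target_id`; the
#'   mapping must be injective on both sides.
#' @return A `landmark_pairing`.
#' @export
landmark_pairing <- function(source, target, pairs) {
  stopifnot(inherits(source, "landmark_set"),
            inherits(target, "landmark_set"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("source_id", "target_id") %in% names(pairs)))
  pairs$source_id <- as.character(pairs$source_id)
  pairs$target_id <- as.character(pairs$target_id)
  if (anyDuplicated(pairs$source_id) || anyDuplicated(pairs$target_id)) {
    stop("pairing must be injective: an id is used more than once",
         call. = FALSE)
  }
  # validates ids exist
  landmark_coords(source, pairs$source_id)
  landmark_coords(target, pairs$target_id)
  structure(
    list(source = source, target = target, pairs = pairs,
         unmatched_source = setdiff(source$landmarks$id, pairs$source_id),
         unmatched_target = setdiff(target$landmarks$id, pairs$target_id)),
    class = "landmark_pairing")
}

#' @export
print.landmark_pairing <- function(x, ...) {
  cat(sprintf(
    "<landmark_pairing> %d pairs ('%s' -> '%s'); unmatched: %d source, %d target\n",
    nrow(x$pairs), x$source$name, x$target$name,
    length(x$unmatched_source), length(x$unmatched_target)))
  invisible(x)
}

#' Number of pairs in a pairing
#' @param pairing a `landmark_pairing`.
#' @return integer pair count.
#' @export
n_pairs <- function(pairing) {
  stopifnot(inherits(pairing, "landmark_pairing"))
  nrow(pairing$pairs)
}

# Paired coordinate matrices (n x 3 each), in pairing order.
pairing_coords <- function(pairing) {
  list(source = landmark_coords(pairing$source, pairing$pairs$source_id),
       target = landmark_coords(pairing$target, pairing$pairs$target_id))
}
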