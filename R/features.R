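#' Collagen fiber set
#'
#' @param polylines list of ordered n x 3 matrices (um), one per fiber;
#'   each with at least 2 points and strictly positive segment lengths.
#' @return An object of class `fiber_set`.
#' @export
fiber_set <- function(polylines) {
  stopifnot(is.list(polylines), length(polylines) >= 1L)
  polylines <- lapply(polylines, as_point_matrix)
  for (i in seq_along(polylines)) {
    p <- polylines[[i]]
    if (nrow(p) < 2L) {
      stop("fiber ", i, " has fewer than 2 points", call. = FALSE)
    }
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    if (any(seg <= 0)) {
      stop("fiber ", i, " has a zero-length segment", call. = FALSE)
    }
  }
  if (is.null(names(polylines))) {
    names(polylines) <- sprintf("F%d", seq_along(polylines))
  }
  structure(list(polylines = polylines), class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers, %d points total\n",
              length(x$polylines),
              sum(vapply(x$polylines, nrow, 1L))))
  invisible(x)
}

#' Detect collagen-fiber cross-points
#'
#' Fibers rarely touch exactly in 3D, so a "crossing" is the midpoint of
#' the closest approach between two different fibers, emitted when that
#' closest-approach distance is below `gate`. One candidate is emitted per
#' fiber pair (at the global minimum over all segment pairs); candidates
#' closer than `merge_radius` are merged to their centroid.
#'
#' @param fibers a [fiber_set()] with at least 2 fibers.
#' @param gate maximum closest-approach distance, um (> 0).
#' @param merge_radius merge distance for nearby candidates, um.
#' @return A [landmark_set()] of `FIBER_CROSSING` landmarks, ids `C1..Cn`
#'   ordered by z then x.
#' @export
detect_fiber_crossings <- function(fibers, gate = 2, merge_radius = 3) {
  stopifnot(inherits(fibers, "fiber_set"), gate > 0)
  if (length(fibers$polylines) < 2L) {
    stop("need at least 2 fibers", call. = FALSE)
  }
  pts <- fiber_crossing_points(fibers, gate = gate)$points
  candidates_to_landmarks(pts, merge_radius, "FIBER_CROSSING", "C")
}

# All closest-approach midpoints below `gate`, one per fiber pair, with a
# bounding-box prefilter; returns the points and the contributing pair
# indices.
fiber_crossing_points <- function(fibers, gate) {
  pl <- fibers$polylines
  nf <- length(pl)
  boxes <- lapply(pl, function(p) rbind(apply(p, 2, min), apply(p, 2, max)))
  pts <- list()
  pairs <- list()
  if (nf < 2L) {
    return(list(points = matrix(numeric(), 0, 3,
                                dimnames = list(NULL, c("x", "y", "z"))),
                pairs = matrix(integer(), 0, 2)))
  }
  for (i in 1:(nf - 1)) {
    for (j in (i + 1):nf) {
      # fibers whose bounding boxes are farther apart than gate cannot
      # cross
      gap <- pmax(boxes[[i]][1, ] - boxes[[j]][2, ],
                  boxes[[j]][1, ] - boxes[[i]][2, ], 0)
      if (sqrt(sum(gap^2)) >= gate) next
      cl <- closest_approach(pl[[i]], pl[[j]])
      if (cl$distance < gate) {
        pts[[length(pts) + 1L]] <- cl$midpoint
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  points <- if (length(pts)) as_point_matrix(do.call(rbind, pts)) else
    matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  list(points = points,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(integer(), 0, 2))
}

# Global closest approach between two polylines: minimum over all segment
# pairs of the segment-segment distance; returns distance and midpoint of
# the closest-approach connector.
closest_approach <- function(a, b) {
  best <- list(distance = Inf, midpoint = NULL)
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq_len(nrow(b) - 1L)) {
      s <- segment_segment_distance(a[i, ], a[i + 1L, ], b[j, ],
                                    b[j + 1L, ])
      if (s$distance < best$distance) best <- s
    }
  }
  best
}

# Minimum distance between 3D segments [p1,p2] and [q1,q2] with clamped
# parameters (Eberly's closed form), plus the connector midpoint.
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1)
  e <- sum(d2 * d2)
  f <- sum(d2 * r)
  c_ <- sum(d1 * r)
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-14 * a * e) {
    max(0, min(1, (b * f - c_ * e) / denom))
  } else 0  # near-parallel
  t <- if (e > 0) (b * s + f) / e else 0
  if (t < 0) {
    t <- 0
    s <- max(0, min(1, -c_ / a))
  } else if (t > 1) {
    t <- 1
    s <- max(0, min(1, (b - c_) / a))
  }
  pa <- p1 + s * d1
  pb <- q1 + t * d2
  list(distance = sqrt(sum((pa - pb)^2)), midpoint = (pa + pb) / 2)
}

#' Propose landmark candidates from vessel-skeleton branch points
#'
#' Every skeleton node of degree >= 3 is a bifurcation candidate; nodes
#' closer than `merge_radius` (voxel-scale junction clusters) are merged
#' to their centroid. Because thinning displaces the junction voxel by up
#' to roughly the vessel radius, each merged candidate is then refined:
#' 3D lines are fitted to the incident skeleton branches within
#' `refine_radius` and the landmark is moved to their least-squares
#' intersection (the centerline meeting point). Ids are assigned `V1..Vn`
#' ordered by z then x.
#'
#' @param skeleton a [vessel_skeleton()].
#' @param merge_radius merge distance, um.
#' @param refine_radius branch length used for centerline-intersection
#'   refinement, um; 0 disables refinement.
#' @return A [landmark_set()] of `VESSEL_BIFURCATION` landmarks (possibly
#'   empty).
#' @export
detect_bifurcations <- function(skeleton, merge_radius = 3,
                                refine_radius = 20) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  deg <- skeleton_degree(skeleton)
  cand <- skeleton$nodes[deg >= 3L, , drop = FALSE]
  out <- candidates_to_landmarks(cand, merge_radius,
                                 "VESSEL_BIFURCATION", "V")
  if (refine_radius > 0 && length(out) > 0L) {
    xyz <- landmark_coords(out)
    for (i in seq_len(nrow(xyz))) {
      xyz[i, ] <- refine_junction(skeleton, xyz[i, ],
                                  max(merge_radius, 5), refine_radius)
    }
    lm <- out$landmarks
    lm[, c("x", "y", "z")] <- xyz
    out <- landmark_set(lm, min_separation = 0)
  }
  out
}

# Move a junction estimate to the least-squares intersection of the
# centerlines of its incident branches. Branches are the connected
# components of the skeleton nodes at distance (exclusion, radius] from
# the raw junction; each gets a PCA line fit. Falls back to the raw
# estimate when fewer than 3 clean branches are found or the system is
# ill-conditioned.
refine_junction <- function(skeleton, center, exclusion, radius) {
  d <- sqrt(rowSums(sweep(skeleton$nodes, 2, center)^2))
  sel <- which(d > exclusion & d <= radius)
  if (length(sel) < 6L) return(center)
  # branch membership via connectivity among the selected nodes
  sub_edges <- skeleton$edges[skeleton$edges[, 1] %in% sel &
                                skeleton$edges[, 2] %in% sel, ,
                              drop = FALSE]
  remap <- match(seq_len(nrow(skeleton$nodes)), sel)
  comp <- component_labels(length(sel),
                           cbind(remap[sub_edges[, 1]],
                                 remap[sub_edges[, 2]]))
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  n_lines <- 0L
  for (g in unique(comp)) {
    pts <- skeleton$nodes[sel[comp == g], , drop = FALSE]
    if (nrow(pts) < 3L) next
    m <- colMeans(pts)
    v <- svd(sweep(pts, 2, m), nu = 0, nv = 1)$v[, 1]
    P <- diag(3) - tcrossprod(v)
    A <- A + P
    b <- b + as.numeric(P %*% m)
    n_lines <- n_lines + 1L
  }
  if (n_lines < 3L || kappa(A) > 1e8) return(center)
  refined <- as.numeric(solve(A, b))
  # refuse a refinement that leaves the junction neighborhood
  if (sqrt(sum((refined - center)^2)) > radius) center else refined
}

# connected-component labels of an undirected graph given edge list
component_labels <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1])
      b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n_nodes), find, 1L)
}

# Merge candidate points within merge_radius (single linkage) to their
# centroids and wrap as a landmark set ordered by z then x.
candidates_to_landmarks <- function(points, merge_radius, feature_class,
                                    prefix) {
  if (is.null(points) || nrow(points) == 0L) {
    return(landmark_set(data.frame(id = character(), x = numeric(),
                                   y = numeric(), z = numeric(),
                                   feature_class = character(),
                                   stringsAsFactors = FALSE),
                        min_separation = 0))
  }
  points <- as_point_matrix(points)
  n <- nrow(points)
  cl <- seq_len(n)
  if (merge_radius > 0 && n > 1L) {
    d <- as.matrix(stats::dist(points))
    # single-linkage union of all pairs within the radius
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] < merge_radius) {
          old <- cl[j]
          cl[cl == old] <- cl[i]
        }
      }
    }
  }
  centroids <- do.call(rbind, lapply(unique(cl), function(g) {
    colMeans(points[cl == g, , drop = FALSE])
  }))
  ord <- order(centroids[, 3], centroids[, 1])
  centroids <- centroids[ord, , drop = FALSE]
  landmark_set(data.frame(id = sprintf("%s%d", prefix,
                                       seq_len(nrow(centroids))),
                          x = centroids[, 1], y = centroids[, 2],
                          z = centroids[, 3],
                          feature_class = feature_class,
                          stringsAsFactors = FALSE),
               min_separation = 0)
}

#' Suggest cross-modality landmark pairs by mutual nearest neighbors
#'
#' Given a coarse alignment (e.g. from the surface branding frame), a pair
#' `(a, b)` is proposed when `b` is the nearest target landmark to
#' `coarse(a)`, `a` is in turn the nearest source landmark to `b` under
#' the same alignment, their distance is below `gate`, and the feature
#' classes match. Proposals replace nothing: the result is marked as
#' requiring review.
#'
#' @param source,target [landmark_set()]s.
#' @param coarse a `spatial_transform` mapping source into target frame.
#' @param gate maximum residual distance after coarse alignment, um.
#' @return A `landmark_pairing` with attribute `requires_review = TRUE`
#'   (possibly zero pairs).
#' @export
suggest_pairs <- function(source, target, coarse, gate) {
  stopifnot(inherits(source, "landmark_set"),
            inherits(target, "landmark_set"),
            inherits(coarse, "spatial_transform"), gate > 0)
  empty_pairs <- data.frame(source_id = character(),
                            target_id = character(),
                            stringsAsFactors = FALSE)
  if (length(source) == 0L || length(target) == 0L) {
    out <- landmark_pairing(source, target, empty_pairs)
    attr(out, "requires_review") <- TRUE
    return(out)
  }
  src <- landmark_coords(source)
  tgt <- landmark_coords(target)
  mapped <- apply_transform(coarse, src)
  D <- cross_dist(mapped, tgt)
  # class mismatch disqualifies a pair
  cls_s <- source$landmarks$feature_class
  cls_t <- target$landmarks$feature_class
  D[outer(cls_s, cls_t, `!=`)] <- Inf
  nn_st <- apply(D, 1, which.min)
  nn_ts <- apply(D, 2, which.min)
  keep <- which(vapply(seq_len(nrow(D)), function(i) {
    j <- nn_st[i]
    is.finite(D[i, j]) && D[i, j] < gate && nn_ts[j] == i
  }, logical(1)))
  pairs <- data.frame(source_id = source$landmarks$id[keep],
                      target_id = target$landmarks$id[nn_st[keep]],
                      stringsAsFactors = FALSE)
  out <- landmark_pairing(source, target, pairs)
  attr(out, "requires_review") <- TRUE
  out
}
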