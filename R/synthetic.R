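#' Parameters for the synthetic skin-tissue generator
#'
#' Defaults emulate the intravital two-photon volumes this workflow is
#' built for: mouse ear skin fields of a few hundred micrometres in xy
#' (270-440 um) imaged 60-200 um deep, containing a branching dermal
#' vessel tree, a collagen-fiber meshwork (the second-harmonic channel),
#' a handful of tumor cells lodged near vessels, and a branded fiducial
#' frame at the skin surface.
#'
#' @param extent numeric length-3, volume size (x, y, z) um; z must lie in
#'   `[60, 200]` and x/y in `[270, 440]` unless `enforce_extent = FALSE`.
#' @param vessel_levels number of binary split levels L of the vessel tree
#'   (`2^L - 1` bifurcations).
#' @param vessel_radius root vessel radius, um (tapers by `2^(-1/3)` per
#'   generation, the Murray's-law calibre ratio).
#' @param n_fibers number of collagen fibers (smoothed random polylines).
#' @param fiber_radius fiber tube radius for rasterization, um.
#' @param n_cells number of cells, placed preferentially near vessels.
#' @param cell_semiaxes typical ellipsoid semi-axes, um.
#' @param nirb_inset fraction of the xy extent by which the surface
#'   branding frame is inset from the volume edge.
#' @param enforce_extent validate the extent ranges above.
#' @return list of class `tissue_params`.
#' @export
tissue_params <- function(extent = c(400, 400, 150),
                          vessel_levels = 3L,
                          vessel_radius = 5,
                          n_fibers = 30L,
                          fiber_radius = 0.8,
                          n_cells = 6L,
                          cell_semiaxes = c(8, 6, 5),
                          nirb_inset = 0.15,
                          enforce_extent = TRUE) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 3L, all(extent > 0))
  if (enforce_extent) {
    if (extent[3] < 60 || extent[3] > 200 ||
        any(extent[1:2] < 270) || any(extent[1:2] > 440)) {
      stop("default extent ranges are 270-440 um in xy and 60-200 um in z; ",
           "set enforce_extent = FALSE to override", call. = FALSE)
    }
  }
  stopifnot(vessel_levels >= 1L, vessel_radius > 0, n_fibers >= 0L,
            n_cells >= 0L, nirb_inset > 0, nirb_inset < 0.5)
  structure(list(extent = extent, vessel_levels = as.integer(vessel_levels),
                 vessel_radius = vessel_radius,
                 n_fibers = as.integer(n_fibers),
                 fiber_radius = fiber_radius,
                 n_cells = as.integer(n_cells),
                 cell_semiaxes = as.numeric(cell_semiaxes),
                 nirb_inset = nirb_inset),
            class = "tissue_params")
}

#' Generate a ground-truth synthetic tissue volume
#'
#' Builds a recursive binary vessel tree (every internal node is a
#' bifurcation), collagen fibers as smoothed random walks, cells biased
#' toward vessels, and a 4-corner branding frame at the surface — all with
#' exact ground-truth coordinates, fully reproducible from `seed`.
#'
#' @param params a [tissue_params()].
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_tissue` with elements
#'   `vessel_nodes` (data.frame id, x, y, z), `vessel_edges` (from, to,
#'   radius), `bifurcations` (n x 3 matrix: the degree-3 tree nodes),
#'   `fibers` ([fiber_set()]), `fiber_crossings` (n x 3 matrix),
#'   `cells` (data.frame centroid + semi-axes), `nirb_frame` (4 x 3
#'   matrix), `extent`, `params`, `seed`.
#' @export
generate_tissue <- function(params = tissue_params(), seed = 1L) {
  stopifnot(inherits(params, "tissue_params"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ext <- params$extent

  tree <- grow_vessel_tree(params)
  fibers <- grow_fibers(params)
  crossings <- fiber_crossing_points(fibers, gate = 2)$points
  cells <- place_cells(params, tree)
  inset <- params$nirb_inset
  nirb <- rbind(c(inset, inset), c(1 - inset, inset),
                c(1 - inset, 1 - inset), c(inset, 1 - inset))
  nirb <- cbind(nirb[, 1] * ext[1], nirb[, 2] * ext[2], z = 0.5)

  structure(list(vessel_nodes = tree$nodes, vessel_edges = tree$edges,
                 bifurcations = tree$bifurcations,
                 fibers = fibers, fiber_crossings = crossings,
                 cells = cells, nirb_frame = as_point_matrix(nirb),
                 extent = ext, params = params, seed = as.integer(seed)),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> %.0f x %.0f x %.0f um: %d vessel bifurcations, %d fibers (%d crossings), %d cells (seed %d)\n",
    x$extent[1], x$extent[2], x$extent[3], nrow(x$bifurcations),
    length(x$fibers$polylines), nrow(x$fiber_crossings), nrow(x$cells),
    x$seed))
  invisible(x)
}

# Recursive binary tree: the root vessel enters near one xy edge at mid
# depth and each branch splits with a moderate opening angle. Directions
# are steered back toward the volume interior so all nodes stay inside.
grow_vessel_tree <- function(params) {
  ext <- params$extent
  margin <- 0.08 * ext
  L <- params$vessel_levels
  root <- c(ext[1] * stats::runif(1, 0.35, 0.65), margin[2],
            ext[3] * stats::runif(1, 0.45, 0.6))
  dir0 <- normalize(c(stats::runif(1, -0.2, 0.2), 1,
                      stats::runif(1, -0.15, 0.15)))
  seg_len <- (ext[2] - 2 * margin[2]) / (L + 1.2)
  nodes <- list(root)
  edges <- list()
  bifs <- list()
  recurse <- function(from_idx, dir, level, radius) {
    p0 <- nodes[[from_idx]]
    p1 <- clamp_inside(p0 + dir * seg_len * stats::runif(1, 0.85, 1.15),
                       ext, margin)
    nodes[[length(nodes) + 1L]] <<- p1
    idx <- length(nodes)
    edges[[length(edges) + 1L]] <<- c(from_idx, idx, radius)
    if (level < L) {
      bifs[[length(bifs) + 1L]] <<- p1
      d_in <- normalize(p1 - p0)
      axis <- normalize(random_perpendicular(d_in))
      ang <- stats::runif(1, 25, 40) * pi / 180
      child_r <- radius * 2^(-1 / 3)
      for (s in c(-1, 1)) {
        d_child <- normalize(rotate_about(d_in, axis, s * ang))
        # steer toward the interior if the child would head out
        tgt <- normalize((ext / 2 - p1) / max(ext))
        d_child <- normalize(0.75 * d_child + 0.25 * tgt)
        recurse(idx, d_child, level + 1L, child_r)
      }
    }
  }
  recurse(1L, dir0, 0L, params$vessel_radius)
  nodes_m <- do.call(rbind, nodes)
  colnames(nodes_m) <- c("x", "y", "z")
  edges_m <- do.call(rbind, edges)
  list(nodes = data.frame(id = sprintf("n%d", seq_len(nrow(nodes_m))),
                          nodes_m, stringsAsFactors = FALSE),
       edges = data.frame(from = as.integer(edges_m[, 1]),
                          to = as.integer(edges_m[, 2]),
                          radius = edges_m[, 3]),
       bifurcations = as_point_matrix(do.call(rbind, bifs)))
}

grow_fibers <- function(params) {
  ext <- params$extent
  n_pts <- 12L
  step <- 0.1 * max(ext[1:2])
  polylines <- lapply(seq_len(params$n_fibers), function(i) {
    # collagen bundles run mostly parallel to the surface, traversing the
    # field with only shallow z drift
    p <- c(stats::runif(1, 0.05, 0.95) * ext[1],
           stats::runif(1, 0.05, 0.95) * ext[2],
           stats::runif(1, 0.15, 0.9) * ext[3])
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- normalize(c(cos(phi), sin(phi), stats::runif(1, -0.08, 0.08)))
    pts <- matrix(NA_real_, n_pts, 3)
    pts[1, ] <- p
    for (k in 2:n_pts) {
      turn <- c(stats::rnorm(2, 0, 0.25), stats::rnorm(1, 0, 0.04))
      dir <- normalize(dir + turn)
      p_new <- clamp_inside(p + dir * step, ext, 0.02 * ext)
      if (sqrt(sum((p_new - p)^2)) < 0.05 * step) {
        # stuck against the boundary: head back toward the interior
        dir <- normalize(ext / 2 - p)
        p_new <- clamp_inside(p + dir * step, ext, 0.02 * ext)
      }
      p <- p_new
      pts[k, ] <- p
    }
    pts
  })
  names(polylines) <- sprintf("F%d", seq_along(polylines))
  fiber_set(polylines)
}

place_cells <- function(params, tree) {
  if (params$n_cells == 0L) {
    return(data.frame(id = character(), x = numeric(), y = numeric(),
                      z = numeric(), a = numeric(), b = numeric(),
                      c = numeric(), stringsAsFactors = FALSE))
  }
  nodes <- as.matrix(tree$nodes[, c("x", "y", "z")])
  out <- t(vapply(seq_len(params$n_cells), function(i) {
    e <- tree$edges[sample.int(nrow(tree$edges), 1L), ]
    tpos <- stats::runif(1)
    on_vessel <- nodes[e$from, ] + tpos * (nodes[e$to, ] - nodes[e$from, ])
    # lodge the cell 8-25 um off the vessel wall
    offset <- normalize(stats::rnorm(3)) *
      (e$radius + stats::runif(1, 8, 25))
    pmax(pmin(on_vessel + offset, params$extent * 0.97),
         params$extent * 0.03)
  }, numeric(3)))
  semi <- t(vapply(seq_len(params$n_cells), function(i) {
    params$cell_semiaxes * stats::runif(3, 0.8, 1.2)
  }, numeric(3)))
  data.frame(id = sprintf("cell%d", seq_len(params$n_cells)),
             x = out[, 1], y = out[, 2], z = out[, 3],
             a = semi[, 1], b = semi[, 2], c = semi[, 3],
             stringsAsFactors = FALSE)
}

#' Ground-truth landmarks of a synthetic tissue
#'
#' Collects the exactly known anatomical reference points of a generated
#' tissue into a [landmark_set()]: vessel bifurcations (`V*`), collagen
#' fiber crossings (`C*`), branding frame corners (`N*`) and cell
#' centroids (`CELL*`).
#'
#' @param tissue a [generate_tissue()] result.
#' @param classes feature classes to include.
#' @param name set name.
#' @return A [landmark_set()].
#' @export
true_landmarks <- function(tissue,
                           classes = c("VESSEL_BIFURCATION",
                                       "FIBER_CROSSING", "NIRB_MARK",
                                       "CELL"),
                           name = "ground-truth") {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  rows <- list()
  if ("VESSEL_BIFURCATION" %in% classes && nrow(tissue$bifurcations)) {
    b <- tissue$bifurcations
    rows$bif <- data.frame(id = sprintf("V%d", seq_len(nrow(b))),
                           x = b[, 1], y = b[, 2], z = b[, 3],
                           feature_class = "VESSEL_BIFURCATION",
                           stringsAsFactors = FALSE)
  }
  if ("FIBER_CROSSING" %in% classes && nrow(tissue$fiber_crossings)) {
    cr <- tissue$fiber_crossings
    rows$cross <- data.frame(id = sprintf("C%d", seq_len(nrow(cr))),
                             x = cr[, 1], y = cr[, 2], z = cr[, 3],
                             feature_class = "FIBER_CROSSING",
                             stringsAsFactors = FALSE)
  }
  if ("NIRB_MARK" %in% classes) {
    nf <- tissue$nirb_frame
    rows$nirb <- data.frame(id = sprintf("N%d", seq_len(nrow(nf))),
                            x = nf[, 1], y = nf[, 2], z = nf[, 3],
                            feature_class = "NIRB_MARK",
                            stringsAsFactors = FALSE)
  }
  if ("CELL" %in% classes && nrow(tissue$cells)) {
    rows$cell <- data.frame(id = toupper(tissue$cells$id),
                            x = tissue$cells$x, y = tissue$cells$y,
                            z = tissue$cells$z, feature_class = "CELL",
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  landmark_set(df, name = name, min_separation = 0)
}

# -- small vector helpers ----------------------------------------------------

normalize <- function(v) v / sqrt(sum(v^2))

random_perpendicular <- function(d) {
  v <- stats::rnorm(3)
  v <- v - sum(v * d) * d
  if (sqrt(sum(v^2)) < 1e-8) v <- c(d[2], -d[1], 0)
  normalize(v)
}

# Rodrigues rotation of vector v about unit axis by angle (radians).
rotate_about <- function(v, axis, angle) {
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp_inside <- function(p, ext, margin) {
  pmax(pmin(p, ext - margin), margin)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
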