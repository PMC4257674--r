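test_that("fiber crossings are found at closest approaches and gated", {
  a <- matrix(c(-10, 0, 5, 10, 0, 5), 2, 3, byrow = TRUE)
  b <- matrix(c(0, -10, 5, 0, 10, 5), 2, 3, byrow = TRUE)
  fs <- fiber_set(list(a, b))
  cr <- detect_fiber_crossings(fs, gate = 2)
  expect_equal(length(cr), 1L)
  expect_equal(as.numeric(landmark_coords(cr)), c(0, 0, 5),
               tolerance = 1e-9)
  expect_equal(cr$landmarks$feature_class, "FIBER_CROSSING")

  par1 <- matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE)
  par2 <- matrix(c(0, 10, 0, 100, 10, 0), 2, 3, byrow = TRUE)
  expect_equal(length(detect_fiber_crossings(fiber_set(list(par1, par2)),
                                             gate = 2)), 0L)
})

test_that("crossing detection matches the brute-force all-segment-pairs oracle", {
  set.seed(40)
  for (rep in 1:3) {
    fs <- fiber_set(lapply(1:20, function(i) {
      start <- c(runif(2, 0, 120), runif(1, 0, 40))
      dir <- rnorm(3)
      dir[3] <- dir[3] * 0.2
      dir <- dir / sqrt(sum(dir^2))
      t(sapply(0:4, function(k) start + k * 15 * dir +
                 c(rnorm(2, 0, 2), rnorm(1, 0, 0.5))))
    }))
    got <- clemdock:::fiber_crossing_points(fs, gate = 2)
    # oracle: plain scan over every segment pair of every fiber pair
    oracle_n <- 0L
    pl <- fs$polylines
    for (i in 1:19) for (j in (i + 1):20) {
      dmin <- Inf
      for (si in seq_len(nrow(pl[[i]]) - 1)) {
        for (sj in seq_len(nrow(pl[[j]]) - 1)) {
          d <- clemdock:::segment_segment_distance(
            pl[[i]][si, ], pl[[i]][si + 1, ], pl[[j]][sj, ],
            pl[[j]][sj + 1, ])$distance
          dmin <- min(dmin, d)
        }
      }
      if (dmin < 2) oracle_n <- oracle_n + 1L
    }
    expect_equal(nrow(got$points), oracle_n)
  }
})

test_that("branch-point candidates come from degree-3 nodes with merging", {
  # a path graph has no degree-3 nodes
  path_nodes <- cbind(seq(0, 50, by = 5), 0, 0)
  path_edges <- cbind(1:10, 2:11)
  expect_equal(length(detect_bifurcations(
    vessel_skeleton(path_nodes, path_edges))), 0L)

  # a single Y junction
  y_nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 5, 0), c(20, -5, 0))
  y_edges <- rbind(c(1, 2), c(2, 3), c(2, 4))
  bi <- detect_bifurcations(vessel_skeleton(y_nodes, y_edges))
  expect_equal(length(bi), 1L)
  expect_equal(as.numeric(landmark_coords(bi)), c(10, 0, 0))

  # two junction voxels 1 um apart merge to their midpoint
  n2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(11, 0, 0), c(21, 0, 0),
              c(10, 5, 0), c(11, -5, 0))
  e2 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(3, 6))
  bi2 <- detect_bifurcations(vessel_skeleton(n2, e2))
  expect_equal(length(bi2), 1L)
  expect_equal(as.numeric(landmark_coords(bi2)), c(10.5, 0, 0))
})

test_that("thinning a straight tube yields a path with no branch points", {
  g <- volume_geometry(c(1, 1, 1), c(40, 15, 15), "LM_2PEM")
  mask <- array(FALSE, dim = c(40, 15, 15))
  for (x in 1:40) for (y in 1:15) for (z in 1:15) {
    if ((y - 8)^2 + (z - 8)^2 <= 16) mask[x, y, z] <- TRUE
  }
  sk <- skeletonize_mask(mask, g)
  expect_equal(sum(skeleton_degree(sk) >= 3), 0L)
  expect_false(sk$has_cycle)
  expect_equal(length(detect_bifurcations(sk)), 0L)
  expect_error(skeletonize_mask(array(FALSE, c(5, 5, 5)),
                                volume_geometry(c(1, 1, 1), c(5, 5, 5))),
               "empty mask")
})

test_that("a rasterized Y-junction yields one bifurcation near the truth", {
  # hand-built two-segment fork around a known branch point
  branch <- c(30, 30, 20)
  tissue <- structure(list(
    vessel_nodes = data.frame(id = c("a", "b", "c", "d"),
                              x = c(5, branch[1], 55, 50),
                              y = c(30, branch[2], 55, 5),
                              z = c(20, branch[3], 25, 15)),
    vessel_edges = data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                              radius = 4),
    bifurcations = matrix(branch, 1, 3),
    fibers = fiber_set(list(matrix(c(0, 0, 0, 1, 1, 1), 2, 3,
                                   byrow = TRUE))),
    fiber_crossings = matrix(numeric(), 0, 3),
    cells = data.frame(id = character(), x = numeric(), y = numeric(),
                       z = numeric(), a = numeric(), b = numeric(),
                       c = numeric()),
    nirb_frame = matrix(c(1, 1, 0, 1, 59, 0, 59, 59, 0, 59, 1, 0), 4, 3,
                        byrow = TRUE),
    extent = c(60, 60, 40),
    params = tissue_params(extent = c(60, 60, 40),
                           enforce_extent = FALSE),
    seed = 0L), class = "synthetic_tissue")
  g <- volume_geometry(c(1, 1, 1), c(61, 61, 41), "LM_2PEM")
  vol <- rasterize(tissue, g, "vessels")
  sk <- suppressWarnings(skeletonize_mask(vol, g))
  bi <- detect_bifurcations(sk)
  expect_equal(length(bi), 1L)
  expect_lt(sqrt(sum((landmark_coords(bi)[1, ] - branch)^2)), 2)
})

test_that("mutual-nearest-neighbor pair suggestion is correct and symmetric", {
  set.seed(41)
  xyz <- random_points(12, extent = c(200, 200, 100))
  ids <- sprintf("P%d", 1:12)
  a <- make_set(xyz, ids, feature_class = "VESSEL_BIFURCATION")
  sugg <- suggest_pairs(a, a, rigid_transform(), gate = 2)
  expect_equal(n_pairs(sugg), 12L)
  expect_identical(sugg$pairs$source_id, sugg$pairs$target_id)
  expect_true(attr(sugg, "requires_review"))

  tr <- c(5, 0, 0)
  b <- make_set(sweep(xyz, 2, tr, `+`), ids,
                feature_class = "VESSEL_BIFURCATION")
  coarse <- rigid_transform(translation = tr)
  full <- suggest_pairs(a, b, coarse, gate = 2)
  expect_equal(n_pairs(full), 12L)

  # symmetry: swap sides and invert the coarse alignment
  rev <- suggest_pairs(b, a, invert_transform(coarse), gate = 2)
  expect_setequal(paste(full$pairs$source_id, full$pairs$target_id),
                  paste(rev$pairs$target_id, rev$pairs$source_id))

  # class mismatch blocks a pair
  c_set <- make_set(sweep(xyz, 2, tr, `+`), ids,
                    feature_class = "FIBER_CROSSING")
  expect_equal(n_pairs(suggest_pairs(a, c_set, coarse, gate = 2)), 0L)
})

test_that("pair suggestion keeps high precision with spurious detections", {
  set.seed(42)
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    true_xyz <- random_points(12, extent = c(300, 300, 120))
    ids <- sprintf("T%d", 1:12)
    spur_a <- random_points(3, extent = c(300, 300, 120))
    spur_b <- random_points(3, extent = c(300, 300, 120))
    a <- make_set(rbind(true_xyz, spur_a),
                  c(ids, sprintf("sa%d", 1:3)),
                  feature_class = "VESSEL_BIFURCATION")
    b <- make_set(rbind(true_xyz + matrix(rnorm(36, 0, 1), 12, 3),
                        spur_b),
                  c(ids, sprintf("sb%d", 1:3)),
                  feature_class = "VESSEL_BIFURCATION")
    sugg <- suggest_pairs(a, b, rigid_transform(), gate = 5)
    good <- sum(sugg$pairs$source_id == sugg$pairs$target_id)
    hits <- hits + good
    total <- total + n_pairs(sugg)
  }
  expect_gte(hits / total, 0.9)
})
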