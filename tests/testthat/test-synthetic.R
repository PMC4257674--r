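test_that("the vessel tree has exactly 2^L - 1 bifurcations, all inside the volume", {
  t1 <- generate_tissue(tissue_params(vessel_levels = 1L), seed = 3)
  expect_equal(nrow(t1$bifurcations), 1L)
  for (s in c(1, 5, 9, 13, 17)) {
    tis <- generate_tissue(tissue_params(vessel_levels = 3L), seed = s)
    expect_equal(nrow(tis$bifurcations), 7L)
    expect_true(all(tis$bifurcations >= 0))
    expect_true(all(sweep(tis$bifurcations, 2, tis$extent) <= 0))
  }
})

test_that("tissue generation is bit-reproducible from its seed", {
  a <- generate_tissue(seed = 11)
  b <- generate_tissue(seed = 11)
  expect_identical(a, b)
  c_ <- generate_tissue(seed = 12)
  expect_false(identical(a$bifurcations, c_$bifurcations))
})

test_that("extent defaults are validated against the imaging envelope", {
  expect_error(tissue_params(extent = c(400, 400, 300)), "60-200")
  expect_error(tissue_params(extent = c(100, 100, 100)), "270-440")
  expect_s3_class(tissue_params(extent = c(100, 100, 300),
                                enforce_extent = FALSE), "tissue_params")
})

test_that("the deformation model obeys its identity and contraction laws", {
  set.seed(50)
  pts <- random_points(30)
  ident <- deformation_model()
  expect_equal(deform_points(ident, pts, c(200, 200, 75)), pts,
               ignore_attr = TRUE)

  shrink <- deformation_model(global_scales = rep(0.95, 3))
  def <- deform_points(shrink, pts, c(200, 200, 75))
  expect_equal(as.numeric(dist(def)) / as.numeric(dist(pts)),
               rep(0.95, choose(30, 2)), tolerance = 1e-12)

  bumps <- deformation_model(
    global_scales = c(1, 1, 1),
    bump_centers = matrix(c(100, 100, 50, 300, 200, 100), 2, 3,
                          byrow = TRUE),
    bump_amplitudes = matrix(c(5, -3, 2, -4, 1, 6), 2, 3, byrow = TRUE),
    bump_widths = c(80, 120))
  disp <- deform_points(bumps, pts, c(200, 200, 75)) - pts
  bound <- sum(sqrt(rowSums(matrix(c(5, -3, 2, -4, 1, 6), 2, 3,
                                   byrow = TRUE)^2)))
  expect_true(all(sqrt(rowSums(disp^2)) <= bound + 1e-12))
})

test_that("landmark observation reproduces the expected noise and dropout statistics", {
  set.seed(51)
  big <- make_set(random_points(1000, extent = c(4000, 4000, 1500)))

  clean <- observe_landmarks(big, detection_noise_sd = 0, dropout_rate = 0)
  expect_identical(clean$landmarks[, 1:4], big$landmarks[, 1:4])

  noisy <- observe_landmarks(big, detection_noise_sd = 2, dropout_rate = 0)
  disp <- sqrt(rowSums((landmark_coords(noisy) - landmark_coords(big))^2))
  # mean of a 3D isotropic Gaussian magnitude: sigma * 2 * sqrt(2/pi)
  closed_form <- 2 * 2 * sqrt(2 / pi)
  expect_lt(abs(mean(disp) - closed_form) / closed_form, 0.05)

  kept <- vapply(1:20, function(s) {
    set.seed(s)
    length(observe_landmarks(big, dropout_rate = 0.2)) / 1000
  }, numeric(1))
  expect_lt(abs(mean(kept) - 0.8), 0.03)
})

test_that("EM processing keeps exact correspondence bookkeeping", {
  tis <- generate_tissue(seed = 4)
  ident <- deformation_model()
  same <- apply_em_processing(tis, ident)
  expect_equal(same$em_tissue$bifurcations, tis$bifurcations)
  expect_equal(
    same$correspondence[, c("lm_x", "lm_y", "lm_z")],
    setNames(same$correspondence[, c("em_x", "em_y", "em_z")],
             c("lm_x", "lm_y", "lm_z")))

  set.seed(52)
  model <- default_deformation(extent = tis$extent)
  proc <- apply_em_processing(tis, model)
  expect_false(anyDuplicated(proc$correspondence$id) > 0)
  # every observed landmark id maps to exactly one truth row
  truth <- true_landmarks(tis)
  set.seed(53)
  obs <- observe_landmarks(truth, model)
  expect_true(all(obs$landmarks$id %in% proc$correspondence$id))
})

test_that("the default scenario reproduces deterministically and yields a usable pairing", {
  a <- simulate_scenario(seed = 6)
  b <- simulate_scenario(seed = 6)
  expect_identical(a$pairing$pairs, b$pairing$pairs)
  expect_identical(landmark_coords(a$lm_observed),
                   landmark_coords(b$lm_observed))
  expect_gte(n_pairs(a$pairing), 6L)
  # observed ids trace back to true landmarks in both frames
  expect_true(all(a$pairing$pairs$source_id %in% a$lm_true$landmarks$id))
})

test_that("rasterization volume agrees with cylinder geometry", {
  # single straight axis-aligned vessel of radius 5
  tissue <- structure(list(
    vessel_nodes = data.frame(id = c("a", "b"), x = c(10, 90),
                              y = c(25, 25), z = c(25, 25)),
    vessel_edges = data.frame(from = 1, to = 2, radius = 5),
    bifurcations = matrix(numeric(), 0, 3),
    fibers = fiber_set(list(matrix(c(0, 0, 0, 1, 1, 1), 2, 3,
                                   byrow = TRUE))),
    fiber_crossings = matrix(numeric(), 0, 3),
    cells = data.frame(id = character(), x = numeric(), y = numeric(),
                       z = numeric(), a = numeric(), b = numeric(),
                       c = numeric()),
    nirb_frame = matrix(c(1, 1, 0, 1, 49, 0, 99, 49, 0, 99, 1, 0), 4, 3,
                        byrow = TRUE),
    extent = c(100, 50, 50),
    params = tissue_params(extent = c(100, 50, 50),
                           enforce_extent = FALSE),
    seed = 0L), class = "synthetic_tissue")
  g <- volume_geometry(c(1, 1, 1), c(101, 51, 51), "LM_2PEM")
  vol <- rasterize(tissue, g, "vessels")
  # segments are painted as capsules: cylinder plus spherical end caps
  analytic <- pi * 5^2 * 80 + 4 / 3 * pi * 5^3
  expect_lt(abs(sum(vol) - analytic) / analytic, 0.1)

  # channels with no structures rasterize to an all-background stack
  expect_equal(sum(rasterize(tissue, g, "cells")), 0)

  coarse <- volume_geometry(c(10, 10, 10), c(11, 6, 6), "LM_2PEM")
  expect_warning(rasterize(tissue, coarse, "vessels"), "spacing")
})

test_that("TIFF stack round-trip preserves the binary volume", {
  set.seed(54)
  vol <- array(runif(20 * 15 * 8) > 0.7, dim = c(20, 15, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(vol, path)
  expect_identical(read_stack(path), vol)
})
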