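test_that("rigid fit recovers a composed rotation + translation exactly", {
  set.seed(1)
  src <- random_points(8)
  p_id <- make_pairing(src, src)
  tf0 <- fit_rigid(p_id)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-12)

  R <- rot_z(90)
  tr <- c(10, -5, 3)
  tgt <- sweep(src %*% t(R), 2, tr, `+`)
  tf <- fit_rigid(make_pairing(src, tgt))
  expect_lt(max(abs(tf$rotation - R)), 1e-9)
  expect_lt(max(abs(tf$translation - tr)), 1e-9)
})

test_that("uniform fixation shrinkage leaves a rigid fit centred with the predicted residual law", {
  set.seed(2)
  src <- random_points(10)
  ctr <- colMeans(src)
  tgt <- sweep(sweep(src, 2, ctr) * 0.95, 2, ctr, `+`)
  p <- make_pairing(src, tgt)
  tf <- fit_rigid(p)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)
  rep <- residual_report(tf, p)
  # residual at each landmark = 5% of its distance from the centroid
  expected <- 0.05 * sqrt(rowSums(sweep(src, 2, ctr)^2))
  expect_equal(rep$offsets$magnitude, expected, tolerance = 1e-9)
})

test_that("similarity fit recovers global shrinkage and swelling scales", {
  set.seed(3)
  src <- random_points(9)
  expect_equal(fit_similarity(make_pairing(src, src))$scale, 1.0,
               tolerance = 1e-12)
  for (s in c(0.95, 1.08)) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 20)
    tgt <- sweep(s * src %*% t(R), 2, tr, `+`)
    tf <- fit_similarity(make_pairing(src, tgt))
    expect_lt(abs(tf$scale - s), 1e-9)
    expect_lt(max(abs(tf$rotation - R)), 1e-9)
    expect_lt(max(abs(tf$translation - tr)), 1e-9)
  }
})

test_that("affine fit recovers anisotropic scaling and reduces to rigid on rigid data", {
  set.seed(4)
  src <- random_points(8)
  A <- diag(c(0.95, 0.95, 0.90))
  tf <- fit_affine(make_pairing(src, src %*% A))
  expect_lt(max(abs(tf$linear - A)), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)

  R <- random_rotation()
  tr <- c(5, 6, -7)
  tgt <- sweep(src %*% t(R), 2, tr, `+`)
  tfr <- fit_affine(make_pairing(src, tgt))
  expect_lt(max(abs(tfr$linear - R)), 1e-8)
  expect_lt(max(abs(tfr$translation - tr)), 1e-8)
})

test_that("TPS at lambda = 0 interpolates and reduces to affine on affine data", {
  set.seed(5)
  src <- random_points(10)
  bumpy <- src + matrix(rnorm(30, 0, 5), 10, 3)
  p <- make_pairing(src, bumpy)
  tf <- fit_tps(p, lambda = 0)
  pred <- apply_transform(tf, src)
  expect_lt(max(abs(pred - bumpy)), 1e-6)
  # side conditions
  expect_lt(max(abs(colSums(tf$warp_coefficients))), 1e-8)
  expect_lt(max(abs(crossprod(src, tf$warp_coefficients))), 1e-6)

  A <- matrix(c(0.9, 0.05, 0, 0, 1.1, 0.02, 0.01, 0, 0.95), 3, 3)
  tgt <- sweep(src %*% t(A), 2, c(3, -2, 1), `+`)
  tfa <- fit_tps(make_pairing(src, tgt), lambda = 0)
  expect_lt(max(sqrt(rowSums(tfa$warp_coefficients^2))), 1e-8)
})

test_that("TPS coefficients equal the dense-system oracle", {
  set.seed(6)
  for (n in c(6, 9, 14, 20)) {
    src <- random_points(n)
    tgt <- src + matrix(rnorm(3 * n, 0, 8), n, 3)
    for (lambda in c(0, 5)) {
      tf <- fit_tps(make_pairing(src, tgt), lambda = lambda)
      oracle <- tps_dense_oracle(src, tgt, lambda = lambda)
      expect_lt(max(abs(tf$warp_coefficients - oracle$W)), 1e-8)
      B_impl <- rbind(tf$affine_part$translation,
                      t(tf$affine_part$linear))
      expect_lt(max(abs(B_impl - oracle$B)), 1e-8)
    }
  }
})

test_that("degenerate and undersized configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid(make_pairing(line, line)), "collinear")
  plane <- cbind(runif(6), runif(6), 0)
  expect_error(fit_affine(make_pairing(plane, plane)), "coplanar")
  expect_error(fit_tps(make_pairing(plane, plane)), "coplanar")
  two <- random_points(2)
  expect_error(fit_rigid(make_pairing(two, two)), "at least 3")
  four <- random_points(4)
  expect_error(fit_tps(make_pairing(four, four)), "at least 5")
  # coincident control points
  src <- random_points(6)
  src[2, ] <- src[1, ]
  tgt <- random_points(6)
  expect_error(fit_tps(make_pairing(src, tgt)), "coincident")
})

test_that("a reflection between modalities is corrected to a proper rotation", {
  set.seed(7)
  src <- random_points(8)
  tgt <- src %*% diag(c(-1, 1, 1))  # mirrored frame
  expect_warning(tf <- fit_rigid(make_pairing(src, tgt)), "reflection")
  expect_gt(det(tf$rotation), 0)
  expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-10)
})

test_that("fitted rotations stay proper orthonormal across random problems", {
  set.seed(8)
  for (i in 1:100) {
    src <- random_points(6)
    tgt <- src + matrix(rnorm(18, 0, 10), 6, 3)
    tf <- suppressWarnings(fit_rigid(make_pairing(src, tgt)))
    expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-10)
    expect_gt(det(tf$rotation), 0)
  }
})

test_that("model nesting gives monotone residuals: rigid >= similarity >= affine >= TPS(0) = 0", {
  set.seed(9)
  for (i in 1:25) {
    src <- random_points(8)
    tgt <- src + matrix(rnorm(24, 0, 6), 8, 3)
    p <- make_pairing(src, tgt)
    r <- vapply(c("rigid", "similarity", "affine", "tps"), function(m) {
      residual_report(suppressWarnings(fit_transform(p, m)), p)$rms
    }, numeric(1))
    expect_true(r["rigid"] >= r["similarity"] - 1e-9)
    expect_true(r["similarity"] >= r["affine"] - 1e-9)
    expect_true(r["affine"] >= r["tps"] - 1e-9)
    expect_lt(r["tps"], 1e-6)
  }
})

test_that("raising lambda trades bending energy for control-point residual monotonically", {
  set.seed(10)
  src <- random_points(12)
  tgt <- src + matrix(rnorm(36, 0, 6), 12, 3)
  p <- make_pairing(src, tgt)
  lambdas <- c(0, 0.1, 1, 10, 100, 1000)
  fits <- lapply(lambdas, function(l) fit_tps(p, lambda = l))
  energy <- vapply(fits, tps_bending_energy, numeric(1))
  rms <- vapply(fits, function(tf) residual_report(tf, p)$rms, numeric(1))
  expect_true(all(diff(energy) <= 1e-8))
  expect_true(all(diff(rms) >= -1e-8))
})

test_that("rigid and similarity optima agree with the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(12)
  src <- random_points(10)
  tgt <- src + matrix(rnorm(30, 0, 5), 10, 3)
  p <- make_pairing(src, tgt)
  tf_sim <- fit_similarity(p)
  ours <- residual_report(tf_sim, p)
  veg <- vegan::procrustes(tgt, src, scale = TRUE, symmetric = FALSE)
  expect_equal(ours$rms, sqrt(mean(stats::residuals(veg)^2)),
               tolerance = 1e-8)
  expect_equal(tf_sim$scale, veg$scale, tolerance = 1e-8)
  expect_equal(ours$offsets$magnitude, unname(stats::residuals(veg)),
               tolerance = 1e-8)
})

test_that("transforms apply, invert and serialize consistently", {
  set.seed(13)
  pts <- random_points(20)
  tf <- rigid_transform(rot_z(35), c(4, -2, 9))
  expect_equal(apply_transform(invert_transform(tf),
                               apply_transform(tf, pts)),
               pts, tolerance = 1e-9, ignore_attr = TRUE)
  tf_s <- similarity_transform(0.95, random_rotation(), c(1, 2, 3))
  expect_equal(apply_transform(invert_transform(tf_s),
                               apply_transform(tf_s, pts)),
               pts, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply_transform(rigid_transform(), pts), pts,
               ignore_attr = TRUE)

  src <- random_points(7)
  tgt <- src + matrix(rnorm(21, 0, 4), 7, 3)
  fits <- list(fit_rigid(make_pairing(src, tgt)),
               fit_similarity(make_pairing(src, tgt)),
               fit_affine(make_pairing(src, tgt)),
               fit_tps(make_pairing(src, tgt), lambda = 0.5))
  for (tf_i in fits) {
    path <- withr::local_tempfile(fileext = ".json")
    write_transform(tf_i, path)
    back <- read_transform(path)
    expect_equal(apply_transform(back, pts), apply_transform(tf_i, pts),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(invert_transform(fits[[4]]), "inverse")
})

test_that("leave-one-out docking errors vanish for exactly realizable correspondences", {
  set.seed(14)
  src <- random_points(8)
  R <- random_rotation()
  tgt <- sweep(src %*% t(R), 2, c(2, 3, 4), `+`)
  loo_r <- loo_docking_error(make_pairing(src, tgt), "rigid")
  expect_lt(max(loo_r$errors$error), 1e-9)

  A <- matrix(c(0.92, 0.03, 0, 0.01, 1.05, 0, 0, 0.02, 0.9), 3, 3)
  tgt_a <- sweep(src %*% t(A), 2, c(-1, 2, 5), `+`)
  loo_t <- loo_docking_error(make_pairing(src, tgt_a), "tps")
  expect_lt(max(loo_t$errors$error), 1e-6)
  expect_true(loo_t$median <= loo_t$max)

  small <- make_pairing(src[1:5, ], tgt[1:5, ])
  expect_error(loo_docking_error(small, "tps"), "at least 6")
})
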