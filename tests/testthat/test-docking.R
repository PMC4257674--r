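test_that("docking maps control points exactly under an interpolating TPS", {
  set.seed(20)
  src <- random_points(8)
  tgt <- src + matrix(rnorm(24, 0, 6), 8, 3)
  p <- make_pairing(src, tgt)
  tf <- fit_tps(p, lambda = 0)
  roi <- region_of_interest("cp", src[3, , drop = FALSE])
  dk <- dock_roi(tf, roi, p)
  expect_equal(as.numeric(dk$predicted_points), tgt[3, ],
               tolerance = 1e-6)
  expect_equal(dk$predicted_z_range, rep(dk$predicted_points[3], 2))
  expect_gte(dk$accuracy_estimate, 0)
  expect_identical(dk$within_claimed_accuracy,
                   dk$accuracy_estimate <= 20)
})

test_that("pure translation docks any ROI by that translation", {
  set.seed(21)
  src <- random_points(8)
  tr <- c(12, -7, 4)
  p <- make_pairing(src, sweep(src, 2, tr, `+`))
  tf <- fit_rigid(p)
  roi_pts <- random_points(5)
  dk <- dock_roi(tf, region_of_interest("blob", roi_pts), p)
  expect_equal(dk$predicted_points, sweep(roi_pts, 2, tr, `+`),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ROIs far outside the landmark hull raise an extrapolation flag", {
  set.seed(22)
  src <- random_points(8, extent = c(100, 100, 50))
  p <- make_pairing(src, src)
  tf <- fit_rigid(p)
  far <- region_of_interest("far", matrix(c(900, 900, 400), 1))
  expect_warning(dk <- dock_roi(tf, far, p), "extrapolation")
  expect_true(dk$extrapolation_flag)
  near <- region_of_interest("near", src[1, , drop = FALSE])
  expect_false(dock_roi(tf, near, p)$extrapolation_flag)
})

test_that("surface-branding alignment recovers in-plane motion and never touches z", {
  frame <- cbind(c(50, 350, 350, 50), c(50, 50, 350, 350), 0)
  marks <- make_set(frame, ids = sprintf("N%d", 1:4),
                    feature_class = "NIRB_MARK")
  tf_id <- coarse_align_nirb(marks, marks)
  expect_equal(tf_id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf_id$translation, c(0, 0, 0), tolerance = 1e-12)

  R <- rot_z(15)
  moved <- sweep(frame %*% t(R), 2, c(30, -10, 0), `+`)
  marks2 <- make_set(moved, ids = sprintf("N%d", 1:4),
                     feature_class = "NIRB_MARK")
  tf <- coarse_align_nirb(marks, marks2)
  expect_lt(max(abs(tf$rotation - R)), 1e-6)
  expect_lt(max(abs(tf$translation - c(30, -10, 0))), 1e-6)

  # a depth offset between the mark sets is reported, not corrected
  shifted_z <- frame
  shifted_z[, 3] <- 8
  marks3 <- landmark_set(
    data.frame(id = sprintf("N%d", 1:4), x = shifted_z[, 1],
               y = shifted_z[, 2], z = shifted_z[, 3],
               feature_class = "NIRB_MARK"),
    min_separation = 0, nirb_surface_band = 10)
  tf_z <- coarse_align_nirb(marks, marks3)
  expect_equal(tf_z$translation[3], 0)
  expect_equal(attr(tf_z, "residual_z_offset"), 8)
  pts <- random_points(10)
  expect_equal(apply_transform(tf_z, pts)[, 3], pts[, 3])

  one <- make_set(matrix(c(1, 1, 0), 1), ids = "N1",
                  feature_class = "NIRB_MARK")
  expect_error(coarse_align_nirb(one, one), "at least 2")
})

test_that("docking depths translate to the correct serial-section window", {
  set.seed(23)
  src <- random_points(8)
  p <- make_pairing(src, src)
  tf <- fit_rigid(p)

  fake_dock <- function(z_lo, z_hi, acc) {
    dk <- dock_roi(tf, region_of_interest("x", src[1, , drop = FALSE]), p)
    dk$predicted_z_range <- c(z_lo, z_hi)
    dk$accuracy_estimate <- acc
    dk
  }
  uniform <- sectioning_scheme(data.frame(count = 400, thickness_nm = 500,
                                          kind = "THICK_LM"))
  # a point prediction on a section boundary goes to the deeper section
  guide <- depth_to_sections(fake_dock(10, 10, 0), uniform)
  expect_equal(guide$first_section, 21L)
  expect_equal(guide$last_section, 21L)
  expect_equal(unname(depth_of(uniform, 21)), c(10.0, 10.5))

  # widening the accuracy margin can only widen the window
  g1 <- depth_to_sections(fake_dock(30, 40, 2), uniform)
  g2 <- depth_to_sections(fake_dock(30, 40, 10), uniform)
  expect_lte(g2$first_section, g1$first_section)
  expect_gte(g2$last_section, g1$last_section)

  shallow <- sectioning_scheme(data.frame(count = 10, thickness_nm = 500,
                                          kind = "THICK_LM"))
  expect_error(depth_to_sections(fake_dock(30, 40, 2), shallow),
               "missing")
})
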