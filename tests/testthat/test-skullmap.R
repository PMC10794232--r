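test_that("slice segmentation thresholds, restricts and despeckles", {
  img <- matrix(0.05, 30, 30)
  img[10:14, 5:25] <- 0.8
  img[25, 28] <- 0.9                       # isolated speck
  m <- segment_slice(img)
  expect_true(all(m[10:14, 5:25]))
  expect_true(m[25, 28])
  m2 <- segment_slice(img, min_component_px = 5)
  expect_false(m2[25, 28])
  expect_true(all(m2[10:14, 5:25]))
  expect_error(segment_slice(img, threshold = 1.01), "\\[0, 1\\]")
  # polygon restriction drops everything outside the polygon
  poly <- rbind(c(8, 3), c(16, 3), c(16, 15), c(8, 15))
  m3 <- segment_slice(img, "polygon+threshold", polygon = poly)
  expect_true(all(which(m3, arr.ind = TRUE)[, 2] <= 15))
  expect_gt(sum(m3), 0)
})

test_that("stacking preserves counts and NIfTI round-trips are lossless", {
  set.seed(33)
  masks <- lapply(1:5, function(i) matrix(runif(20 * 16) > 0.7, 20, 16))
  sm <- stack_masks(masks, c(0.14, 0.14), 0.2)
  expect_equal(dim(sm$mask), c(20L, 16L, 5L))
  expect_equal(sum(sm$mask), sum(vapply(masks, sum, 1L)))
  expect_equal(sm$spacing_mm, c(0.14, 0.14, 0.2))
  path <- tempfile(fileext = ".nii")
  write_nifti(sm, path)
  back <- read_nifti(path)
  expect_identical(array(back$values == 1, dim(sm$mask)), sm$mask)
  expect_equal(back$spacing_mm, sm$spacing_mm, tolerance = 1e-6)
  unlink(path)
})

test_that("binarization uses modality thresholds, idempotent and monotone", {
  hu <- hu_volume(array(0, c(6, 6, 6)), 1)
  expect_equal(binarize(hu, "ct")$n_voxels, 0L)        # all-water CT
  hu$values[] <- 401
  expect_equal(binarize(hu, "ct")$n_voxels, 216L)      # uniform above 400
  set.seed(5)
  v <- array(runif(216), c(6, 6, 6))
  m1 <- binarize(v, "bmode")
  m2 <- binarize(m1$mask * 1, "bmode")                 # idempotent
  expect_true(all(m1$mask == m2$mask))
  lo <- binarize(v, "bmode", threshold = 0.1)
  hi <- binarize(v, "bmode", threshold = 0.5)
  expect_true(all(hi$mask <= lo$mask))                 # monotone
  expect_error(binarize(v, "bmode", threshold = 1.4), "\\[0, 1\\]")
})

test_that("shell mask volume matches the analytic cap-shell volume", {
  # hu_bone 800: the 400 HU threshold is the half-amplitude level, so the
  # binarized volume is geometrically unbiased; cap narrowed to 40 deg so
  # the full cap fits inside the lateral grid extent
  ph <- make_shell_phantom(shell_spec(hu_bone = 800, cap_half_angle_deg = 40))
  m <- binarize(ph$hu, "ct")
  vol <- m$n_voxels * 0.5^3
  v_analytic <- (2 * pi / 3) * (1 - cos(40 * pi / 180)) * (25^3 - 21^3)
  expect_equal(vol, v_analytic, tolerance = 0.05)
})

test_that("rigid registration recovers identity, shifts and rotations", {
  ph <- make_shell_phantom(shell_spec(
    shape = c(48, 56, 56),
    suture_grooves = list(list(position = 12, width_mm = 3, depth_mm = 1.5)),
    orbit_holes = list(list(center = c(20, 10), radius_mm = 4))))
  moving <- skull_mask(ph$truth$mask, 0.5)

  res0 <- rigid_register(moving, moving,
                         search = list(rot_range_deg = 2, rot_step_deg = 2,
                                       maxit = 60))
  expect_gt(res0$dice, 0.99)
  expect_lt(max(abs(res0$transform$translation_mm)), 0.5)
  expect_lt(max(abs(res0$transform$rotation_deg)), 1)

  tr_true <- rigid_transform(c(0, 0, 0), c(3, -2, 1))
  fixed <- apply_rigid(moving, tr_true)
  res <- rigid_register(moving, fixed,
                        search = list(rot_range_deg = 2, rot_step_deg = 2,
                                      maxit = 150))
  expect_lt(max(abs(res$transform$translation_mm - c(3, -2, 1))), 0.5)
  expect_gt(res$dice, 0.9)

  rot_true <- rigid_transform(c(0, 5, 0), c(0, 0, 0))
  fixed_r <- apply_rigid(moving, rot_true)
  res_r <- rigid_register(moving, fixed_r,
                          search = list(rot_range_deg = 6, rot_step_deg = 3,
                                        maxit = 250))
  expect_lt(abs(res_r$transform$rotation_deg[2] - 5), 1)
  expect_gt(res_r$dice, 0.9)
  expect_error(rigid_register(skull_mask(array(FALSE, c(4, 4, 4)), 1),
                              moving), "empty")
})

test_that("line thickness handles oblique probes and disc metrics", {
  spec <- slab_spec(c(0, 0), shape = c(48, 72, 72), spacing = 0.5)
  ph <- make_slab_phantom(spec)
  mask <- skull_mask(ph$truth$mask, 0.5)
  ctr <- c(0, 17.75, 17.75)
  th <- thickness_along_line(mask, ctr, c(1, 0, 0))
  expect_equal(th$thickness_mm, 4, tolerance = 0.25)   # spacing / 2
  # probing 60 degrees off-normal doubles the path length
  th60 <- thickness_along_line(mask, c(0, 3, 17.75),
                               c(cos(60 * pi / 180), sin(60 * pi / 180), 0))
  expect_equal(th60$thickness_mm, 8, tolerance = 0.5)
  expect_error(thickness_along_line(mask, c(0, 17.75, 17.75), c(0, 1, 0)),
               "mask")

  dm <- disc_metrics(mask, center_mm = c(17.75, 17.75), radius_mm = 15)
  expect_equal(dm$mean_thickness_mm, 4, tolerance = 0.25)
  expect_equal(dm$volume_mm3, pi * 15^2 * 4, tolerance = 0.03)
  dm0 <- disc_metrics(mask, center_mm = c(17.75, 17.75), radius_mm = 0)
  expect_equal(dm0$n_columns, 1L)
  expect_error(disc_metrics(mask, center_mm = c(200, 200), radius_mm = 5),
               "misses|intersect")
})

test_that("caliper distances and orbit-hole diameter agree with truth", {
  expect_equal(caliper_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(caliper_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  hole_r <- 5
  ph <- make_shell_phantom(shell_spec(
    orbit_holes = list(list(center = c(17.75, 17.75), radius_mm = hole_r))))
  tm <- ph$truth$true_thickness_map
  # hole edge points along axis 2 through the hole centre row
  k <- 36                                   # z = 17.5 mm row (0.5 mm grid)
  col <- tm[, k]
  idx <- which(is.na(col))
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  lens <- vapply(runs, length, 1L)
  hole_run <- runs[[which.max(lens)]]
  p1 <- c(0, (min(hole_run) - 1) * 0.5, (k - 1) * 0.5)
  p2 <- c(0, (max(hole_run) - 1) * 0.5, (k - 1) * 0.5)
  expect_equal(caliper_distance(p1, p2), 2 * hole_r, tolerance = 0.15)
})
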