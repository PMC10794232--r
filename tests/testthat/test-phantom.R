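test_that("slab tilt produces the analytic incidence angle", {
  ph0 <- make_slab_phantom(slab_spec(c(0, 0)))
  expect_equal(ph0$truth$true_incidence_deg, 90)
  ph20 <- make_slab_phantom(slab_spec(c(20, 0)))
  expect_equal(ph20$truth$true_incidence_deg, 70)
  # composed rotation checked against an independent rotation-matrix oracle
  a <- 10 * pi / 180; b <- 10 * pi / 180
  R2 <- rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  R3 <- rbind(c(cos(b), -sin(b), 0), c(sin(b), cos(b), 0), c(0, 0, 1))
  n_oracle <- R3 %*% R2 %*% c(1, 0, 0)
  inc_oracle <- 90 - acos(abs(n_oracle[1])) * 180 / pi
  ph <- make_slab_phantom(slab_spec(c(10, 10)))
  expect_equal(ph$truth$true_incidence_deg, inc_oracle, tolerance = 1e-12)
  expect_equal(sqrt(sum(ph$truth$true_normal^2)), 1)
})

test_that("slab leaving the grid is rejected with a clear message", {
  expect_error(make_slab_phantom(slab_spec(c(60, 0), shape = c(24, 80, 80))),
               "exits the grid")
})

test_that("slab HU has linear partial volume and consistent masks", {
  ph <- make_slab_phantom(slab_spec(c(7, 0), hu_bone = 800))
  hu <- ph$hu$values
  # interior voxels at full HU, background at zero, and some partial voxels
  expect_equal(max(hu), 800)
  expect_equal(min(hu), 0)
  expect_true(any(hu > 0 & hu < 800))
  # at hu_bone = 800 the 400 HU threshold is the half-amplitude level and
  # must reproduce the voxelized truth mask exactly
  expect_identical(binarize(ph$hu, "ct")$mask, ph$truth$mask)
  # brighter bone: the 400 HU mask may only add partial-volume voxels at
  # the surface (superset within the one-voxel boundary layer)
  ph2 <- make_slab_phantom(slab_spec(c(15, 0), hu_bone = 1500))
  m400 <- binarize(ph2$hu, "ct")$mask
  expect_true(all(ph2$truth$mask <= m400))
})

test_that("truth surface points reproduce the incidence angle to < 0.1 deg", {
  for (tilt in list(c(0, 0), c(12, 0), c(20, 15))) {
    ph <- make_slab_phantom(slab_spec(tilt, shape = c(64, 40, 40)))
    fit <- fit_plane(ph$truth$surface_points, axis = c(1, 0, 0))
    est <- incidence_angle(fit, c(1, 0, 0))
    expect_lt(abs(est$incidence_deg - ph$truth$true_incidence_deg), 0.1)
  }
})

test_that("plain shell has uniform thickness and matching truth map", {
  ph <- make_shell_phantom(shell_spec())
  mask <- skull_mask(ph$truth$mask, 0.5)
  ctr <- (dim(ph$truth$mask)[2:3] / 2) * 0.5
  # probe a few near-apex columns: radial ~ beam axis there
  for (off in list(c(0, 0), c(2, 0), c(0, -2), c(1.5, 1.5))) {
    p <- c(0, ctr[1] + off[1], ctr[2] + off[2])
    th <- thickness_along_line(mask, p, c(1, 0, 0))
    expect_equal(th$thickness_mm, 4, tolerance = 0.5)  # one voxel
    expect_equal(th$n_segments, 1L)
  }
  # truth map equals the nominal thickness where defined
  tm <- ph$truth$true_thickness_map
  expect_true(all(abs(tm[!is.na(tm)] - 4) < 1e-9))
})

test_that("orbit hole removes the analytic volume and groove thins locally", {
  base <- shell_spec()
  ph0 <- make_shell_phantom(base)
  hole_r <- 5
  holed <- shell_spec(orbit_holes = list(list(center = c(17.75, 17.75),
                                              radius_mm = hole_r)))
  ph1 <- make_shell_phantom(holed)
  dv <- (sum(ph0$truth$mask) - sum(ph1$truth$mask)) * 0.5^3
  # independent oracle: cylinder through a 4 mm shell, obliquity from the
  # sphere geometry at the hole centre
  C <- ph0$truth$sphere_center_mm
  d2 <- (17.75 - C[2])^2 + (17.75 - C[3])^2
  cos_theta <- sqrt(25^2 - d2) / 25
  v_analytic <- pi * hole_r^2 * 4 / cos_theta
  expect_equal(dv, v_analytic, tolerance = 0.05)

  grooved <- shell_spec(suture_grooves = list(list(position = 17.75,
                                                   width_mm = 3,
                                                   depth_mm = 1.5)))
  ph2 <- make_shell_phantom(grooved)
  mask <- skull_mask(ph2$truth$mask, 0.5)
  th_groove <- thickness_along_line(mask, c(0, 17.75, 17.75), c(1, 0, 0))
  expect_equal(th_groove$thickness_mm, 4 - 1.5, tolerance = 0.5)
  # away from the groove the full thickness remains
  th_far <- thickness_along_line(mask, c(0, 24, 17.75), c(1, 0, 0))
  expect_equal(th_far$thickness_mm, 4, tolerance = 0.5)
  expect_error(make_shell_phantom(
    shell_spec(suture_grooves = list(list(position = 0, width_mm = 2,
                                          depth_mm = 5)))),
    "deeper")
})

test_that("noiseless B-mode stacks segment to exact truth and are seeded", {
  ph <- make_slab_phantom(slab_spec(c(10, 0), shape = c(40, 32, 16)))
  bm <- render_bmode_stack(ph, slice_spacing_mm = 1,
                           noise = list(snr_db = Inf), seed = 5)
  seg <- bm$stack$slices >= 0.19
  expect_identical(array(seg, dim(seg)), bm$gt_masks)
  # determinism: same seed, bit-identical; noise actually varies otherwise
  n1 <- render_bmode_stack(ph, slice_spacing_mm = 1,
                           noise = list(speckle_scale = 0.5, snr_db = 20),
                           seed = 9)
  n2 <- render_bmode_stack(ph, slice_spacing_mm = 1,
                           noise = list(speckle_scale = 0.5, snr_db = 20),
                           seed = 9)
  n3 <- render_bmode_stack(ph, slice_spacing_mm = 1,
                           noise = list(speckle_scale = 0.5, snr_db = 20),
                           seed = 10)
  expect_identical(n1$stack$slices, n2$stack$slices)
  expect_false(identical(n1$stack$slices, n3$stack$slices))
})

test_that("20 dB SNR stacks still segment with Dice >= 0.9", {
  ph <- make_slab_phantom(slab_spec(c(10, 0), shape = c(48, 40, 12)))
  bm <- render_bmode_stack(ph, slice_spacing_mm = 1,
                           noise = list(speckle_scale = 0.5, snr_db = 20),
                           seed = 3)
  for (k in seq_len(dim(bm$stack$slices)[3])) {
    seg <- segment_slice(bm$stack$slices[, , k])
    expect_gte(dice_of(seg, bm$gt_masks[, , k]), 0.9)
  }
})

test_that("channel data obeys time-of-flight arithmetic and cancellation", {
  arr <- array_geometry()
  c0 <- water_constants()$c_m_s
  # single on-axis scatterer at 50 mm: first arrival on the centre elements
  # at 2*50 mm / c within one sample
  cd <- synth_channel_data(cbind(50, 0), 1, arr, tilts_deg = 0,
                           polarities = 1)
  fs <- cd$fs_hz
  ctr_el <- 32L
  tr <- cd$rf[, ctr_el, 1]
  t_first <- (which(abs(tr) > 1e-9 * max(abs(tr)))[1] - 1) / fs
  t_expected <- 2 * 50e-3 / c0
  expect_lt(abs(t_first - t_expected), 1.5 / fs)
  # fundamental-only echoes cancel exactly under pulse inversion
  cd2 <- synth_channel_data(cbind(50, 0), 1, arr, tilts_deg = c(-5, 5),
                            polarities = c(1, -1), harmonic_fraction = 0)
  pi_rf <- pulse_inversion_events(cd2)
  expect_equal(max(abs(pi_rf$rf)), 0)
  # empty scatterer list gives all-zero traces
  cd0 <- synth_channel_data(matrix(numeric(0), 0, 2), 1, arr, tilts_deg = 0)
  expect_true(all(cd0$rf == 0))
  expect_error(synth_channel_data(cbind(150, 0), 1, arr), "imaging depth")
})

test_that("pulse-inversion sum of harmonic-bearing echoes peaks at 2 f_tx", {
  arr <- array_geometry()
  cd <- synth_channel_data(cbind(50, 0), 1, arr, tilts_deg = 0,
                           polarities = c(1, -1), harmonic_fraction = 0.1)
  hr <- pulse_inversion_events(cd)
  sp <- amp_spectrum(hr$rf[, 32, 1], cd$fs_hz)
  pk_freq <- sp$freq[which.max(sp$amp)]
  expect_equal(pk_freq, 2 * cd$f_tx_hz, tolerance = 0.15)
})

test_that("channel data round-trips through the binary container", {
  arr <- array_geometry(n_elements = 8)
  cd <- synth_channel_data(cbind(40, 2), 1, arr, tilts_deg = c(-4, 4),
                           polarities = c(1, -1), harmonic_fraction = 0.05)
  path <- tempfile("chan_")
  write_channel_data(cd, arr, path)
  back <- read_channel_data(path)
  expect_equal(back$rf, cd$rf, tolerance = 1e-6)     # float32 storage
  expect_equal(back$tilt_deg, cd$tilt_deg)
  expect_equal(back$polarity, cd$polarity)
  expect_equal(back$fs_hz, cd$fs_hz)
  expect_equal(back$virtual_source_mm, cd$virtual_source_mm,
               tolerance = 1e-9)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$element_positions_mm, arr$element_positions_mm)
  unlink(paste0(path, c(".bin", ".json")))
})
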