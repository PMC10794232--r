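test_that("grid design helpers match the published settings", {
  # 0.4 mm, water, CFL 0.2 -> 54 ns; the skull-case 26.7 ns implies a
  # reference speed of ~2996 m/s
  expect_equal(cfl_dt(0.4, 1482, 0.2) * 1e9, 54.0, tolerance = 1e-3)
  expect_equal(cfl_dt(0.8, 1482, 0.2), 2 * cfl_dt(0.4, 1482, 0.2))
  expect_equal(cfl_dt(0.4, 2996, 0.2) * 1e9, 26.7, tolerance = 1e-3)
  expect_error(cfl_dt(-1, 1482, 0.2), "positive")

  expect_equal(ppw_of(1482, 250e3, 0.4), 14.82)
  expect_equal(round(ppw_of(1482, 250e3, 0.4)), 15)
  expect_equal(ppw_of(1482, 250e3, 0.5928), 10, tolerance = 1e-4)
  expect_equal(ppw_of(2.66 * 1482, 250e3, 0.4), 39.4, tolerance = 1e-3)
})

test_that("transducer geometry validates its invariants", {
  g <- transducer_geometry()
  expect_equal(g$outer_diameter_mm, 110)
  expect_equal(g$inner_diameter_mm, 44)
  expect_equal(sqrt(sum(g$axis^2)), 1)
  expect_error(transducer_geometry(inner_diameter_mm = 120), "inner")
  expect_error(transducer_geometry(focal_distance_mm = 40), "focal")
  g2 <- scale_geometry(g, 0.5)
  expect_equal(g2$focal_distance_mm / g2$outer_diameter_mm,
               g$focal_distance_mm / g$outer_diameter_mm)
})

test_that("bowl discretization selects an equidistant annular arc", {
  # 2D arc at the published scale on a 0.4 mm grid
  geom <- transducer_geometry(apex_mm = c(4, 60), axis = c(1, 0))
  grid <- sim_grid(c(330, 300), 0.4, 1482, pml_cells = 8)
  src <- discretize_bowl(geom, grid)
  focus <- geom$apex_mm + 110 * geom$axis
  d <- sqrt(rowSums(sweep(src$positions_mm, 2, focus)^2))
  expect_true(all(abs(d - 110) <= 0.4))
  # aperture annulus: no source voxels inside the central hole
  lat <- abs(src$positions_mm[, 2] - 60)
  expect_true(all(lat <= 55 + 0.4))
  expect_true(all(lat >= 22 - 0.4))
  # a full cap has more sources than the annulus
  geom_full <- transducer_geometry(inner_diameter_mm = 0,
                                   apex_mm = c(4, 60), axis = c(1, 0))
  expect_gt(discretize_bowl(geom_full, grid)$n, src$n)
  expect_error(transducer_geometry(inner_diameter_mm = 110,
                                   outer_diameter_mm = 110), "inner")
  # bowl clipped by the PML is rejected with the overhang named
  expect_error(discretize_bowl(geom, sim_grid(c(330, 150), 0.4, 1482)),
               "clipped")
})

test_that("Rayleigh oracle matches the closed on-axis form and symmetry", {
  geom <- transducer_geometry(inner_diameter_mm = 0)
  z <- c(60, 90, 105, 120)
  num <- Mod(oneil_reference(geom, cbind(z, 0, 0), n_theta = 400,
                             n_phi = 16))
  cf <- Mod(oneil_onaxis(geom, z))
  expect_equal(num / cf, rep(1, length(z)), tolerance = 1e-3)
  # annular bowl: lateral symmetry to machine precision
  geom2 <- transducer_geometry()
  r <- c(1.5, 4, 8)
  pp <- Mod(oneil_reference(geom2, cbind(104, r, 0)))
  pm <- Mod(oneil_reference(geom2, cbind(104, -r, 0)))
  expect_equal(pp, pm, tolerance = 1e-12)
  # focal peak sits on-axis slightly proximal to the geometric focus
  zs <- seq(70, 130, by = 0.5)
  prof <- Mod(oneil_onaxis(geom2, zs))
  zpk <- zs[which.max(prof)]
  expect_lt(zpk, 110)
  expect_gt(zpk, 0.95 * 110 - 5)
})

test_that("solver is linear in the drive amplitude", {
  med <- homogeneous_medium(c(72, 64), 1)
  grid <- sim_grid(c(72, 64), 1, 1482, n_steps = 400)
  geom <- transducer_geometry(f0_hz = 250e3, outer_diameter_mm = 30,
                              inner_diameter_mm = 10,
                              focal_distance_mm = 30,
                              apex_mm = c(10, 32), axis = c(1, 0))
  src <- discretize_bowl(geom, grid)
  f1 <- run_pstd(med, grid, src, drive_signal(1, 5, 250e3))
  f2 <- run_pstd(med, grid, src, drive_signal(2, 5, 250e3))
  expect_equal(f2$max_pressure, 2 * f1$max_pressure, tolerance = 1e-12)
})

test_that("1D plane wave decays at the configured absorption rate", {
  n <- 600; dx <- 0.5
  med <- homogeneous_medium(n, dx, alpha0 = 10.8, y = 2)
  grid <- sim_grid(n, dx, 1482, cfl = 0.2, pml_cells = 12)
  fld <- run_pstd(med, grid, 20L,
                  drive_signal(n_cycles = 70, f_hz = 250e3,
                               ramp_cycles = 10))
  x <- (seq_len(n) - 1) * dx
  sel <- x > 50 & x < 200
  slope_db_cm <- -coef(lm(20 * log10(fld$max_pressure[sel]) ~ x[sel]))[2] * 10
  expect_equal(unname(slope_db_cm), 0.675, tolerance = 0.02)
})

test_that("homogeneous-medium reciprocity holds within 1 percent", {
  med <- homogeneous_medium(c(96, 80), 1)
  grid <- sim_grid(c(96, 80), 1, 1482, n_steps = 500)
  drv <- drive_signal(n_cycles = 4, f_hz = 250e3)
  A <- c(25L, 30L); B <- c(70L, 55L)
  ia <- A[1] + (A[2] - 1) * 96
  ib <- B[1] + (B[2] - 1) * 96
  fab <- run_pstd(med, grid, ia, drv)
  fba <- run_pstd(med, grid, ib, drv)
  pa <- fab$max_pressure[B[1], B[2]]
  pb <- fba$max_pressure[A[1], A[2]]
  expect_equal(pa / pb, 1, tolerance = 0.01)
})

test_that("PML keeps boundary reflections below 1 percent at the focus", {
  geom <- transducer_geometry(f0_hz = 250e3, outer_diameter_mm = 40,
                              inner_diameter_mm = 16,
                              focal_distance_mm = 40,
                              apex_mm = c(12, 60), axis = c(1, 0))
  drv <- drive_signal(n_cycles = 8, f_hz = 250e3)
  run_at <- function(shape) {
    med <- homogeneous_medium(shape, 1)
    grid <- sim_grid(shape, 1, 1482, pml_cells = 10,
                     n_steps = 900)
    src <- discretize_bowl(geom, grid)
    fld <- run_pstd(med, grid, src, drv)
    focal_peak_in_roi(fld, list(center_mm = c(52, 60),
                                half_width_mm = 8))$p_peak
  }
  p_small <- run_at(c(90, 120))
  p_big <- run_at(c(150, 180))
  expect_equal(p_small / p_big, 1, tolerance = 0.01)
})

test_that("free-field convergence stabilizes with grid refinement", {
  geom <- scale_geometry(transducer_geometry(), 40 / 110)
  drv <- drive_signal(n_cycles = 8, f_hz = 250e3)
  tab <- convergence_study(c(3, 6, 10, 14), geom, drv, mode = "2d")
  expect_equal(nrow(tab), 4L)
  expect_true(all(is.finite(tab$lateral_fwhm_mm)))
  d_last <- abs(tab$lateral_fwhm_mm[4] - tab$lateral_fwhm_mm[3]) /
    tab$lateral_fwhm_mm[4]
  expect_lt(d_last, 0.05)
  # successive differences shrink as the grid refines
  d_first <- abs(tab$lateral_fwhm_mm[2] - tab$lateral_fwhm_mm[1]) /
    tab$lateral_fwhm_mm[2]
  expect_lt(d_last, d_first)
  one <- convergence_study(6, geom, drv, mode = "2d")
  expect_equal(nrow(one), 1L)
  expect_equal(one$lateral_fwhm_mm, tab$lateral_fwhm_mm[2])
})
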