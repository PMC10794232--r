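test_that("focal peak search handles delta, ties and Gaussian blobs", {
  v <- array(0, c(11, 11, 11))
  v[4, 7, 6] <- 1
  f <- pressure_field(v, 1)
  pk <- focal_peak_in_roi(f, list(center_mm = c(5, 5, 5), half_width_mm = 5))
  expect_equal(pk$index, c(4L, 7L, 6L))
  expect_equal(pk$p_voxel, 1)
  # uniform field: ties break to the lowest linear index = ROI corner
  fu <- pressure_field(array(1, c(7, 7, 7)), 1)
  pku <- focal_peak_in_roi(fu, list(center_mm = c(3, 3, 3), half_width_mm = 1.2))
  expect_equal(pku$index, c(3L, 3L, 3L))
  expect_error(focal_peak_in_roi(f, list(center_mm = c(50, 5, 5),
                                         half_width_mm = 2)), "outside")
  # subvoxel recovery of an analytic Gaussian within 0.1 voxel
  ctr <- c(5.3, 6.7, 4.1)
  co <- seq_len(11) - 1
  g <- exp(-outer(outer((co - ctr[1])^2, (co - ctr[2])^2, "+"),
                  (co - ctr[3])^2, "+") / (2 * 2^2))
  pkg_ <- focal_peak_in_roi(pressure_field(g, 1),
                            list(center_mm = c(5, 5, 5), half_width_mm = 5))
  expect_lt(max(abs(pkg_$location_mm - ctr)), 0.1)
})

test_that("attenuation percentage is exact and scale invariant", {
  expect_equal(attenuation_pct(1, 1), 0)
  expect_equal(attenuation_pct(1, 0), 100)
  expect_equal(attenuation_pct(1.0, 0.53), 47)
  set.seed(2)
  for (i in 1:20) {
    pf <- runif(1, 0.1, 10); ps <- runif(1, 0, pf); k <- runif(1, 0.1, 100)
    expect_equal(attenuation_pct(k * pf, k * ps), attenuation_pct(pf, ps))
  }
  expect_error(attenuation_pct(0, 0), "positive")
})

test_that("FWHM measurement matches closed forms", {
  x <- seq(0, 60, by = 0.25)
  tri <- pmax(1 - abs(x - 30) / 10, 0)          # half-width at half max = 5
  f1 <- list(max_pressure = array(tri, length(tri)), spacing_mm = 0.25,
             origin_mm = 0)
  expect_equal(fwhm_along(f1, 30, 1), 10, tolerance = 1e-3)
  sigma <- 4
  gs <- exp(-(x - 30)^2 / (2 * sigma^2))
  f2 <- list(max_pressure = array(gs, length(gs)), spacing_mm = 0.25,
             origin_mm = 0)
  expect_equal(fwhm_along(f2, 30, 1), 2.3548 * sigma, tolerance = 0.01)
  # scale invariance
  f3 <- f2; f3$max_pressure <- 7.3 * f3$max_pressure
  expect_equal(fwhm_along(f3, 30, 1), fwhm_along(f2, 30, 1))
  # truncated profile is flagged, not silently measured
  f4 <- list(max_pressure = array(0.5 * gs + 0.6, length(gs)),
             spacing_mm = 0.25, origin_mm = 0)
  expect_error(fwhm_along(f4, 30, 1), "truncated")
})

test_that("focal shift decomposes displacement by Pythagoras", {
  ref <- list(peak_location_mm = c(10, 5, 5))
  expect_equal(focal_shift(ref, ref, c(1, 0, 0)),
               list(axial_mm = 0, lateral_mm = 0))
  m <- list(peak_location_mm = c(13, 5, 5))
  sh <- focal_shift(m, ref, c(1, 0, 0))
  expect_equal(sh$axial_mm, 3)          # positive = beyond the focus
  expect_equal(sh$lateral_mm, 0)
  set.seed(4)
  for (i in 1:20) {
    d <- rnorm(3)
    sh <- focal_shift(list(peak_location_mm = ref$peak_location_mm + d),
                      ref, c(1, 0, 0))
    expect_equal(sh$axial_mm^2 + sh$lateral_mm^2, sum(d^2))
    expect_gte(sh$lateral_mm, 0)
  }
})

test_that("angle-attenuation regression recovers linear relationships", {
  ang <- seq(50, 85, by = 5)
  rec <- do.call(rbind, lapply(seq_along(ang), function(i)
    attenuation_record(ang[i], 1, 1 - (90 - ang[i]) / 100, config_id = i)))
  fit <- fit_angle_attenuation(rec)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$n, 8L)
  # attenuation column satisfies its defining identity
  expect_equal(rec$attenuation_pct,
               100 * (rec$p_ff_pa - rec$p_skull_pa) / rec$p_ff_pa,
               tolerance = 1e-9)
  # zero-mean noise: slope estimate within its own 95% CI of the truth
  set.seed(8)
  noisy <- rec
  noisy$attenuation_pct <- rec$attenuation_pct + rnorm(8, sd = 1.5)
  lmfit <- lm(attenuation_pct ~ incidence_deg, noisy)
  ci <- confint(lmfit)["incidence_deg", ]
  expect_true(ci[1] <= -1 && -1 <= ci[2])
  expect_error(fit_angle_attenuation(rec[1:2, ]), "at least 3")
  const <- rec; const$incidence_deg <- 70
  expect_error(fit_angle_attenuation(const), "constant")
})
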