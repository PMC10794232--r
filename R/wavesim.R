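#' Time step from the Courant-Friedrichs-Lewy number
#'
#' @param dx_mm isotropic spatial step, mm.
#' @param c_max_m_s maximum sound speed in the medium, m/s.
#' @param cfl CFL number (0.2 by default throughout the package).
#' @return time step in seconds, `cfl * dx / c_max`.
#' @examples
#' cfl_dt(0.4, 1482, 0.2)  # 5.40e-8 s = 54 ns
#' @export
cfl_dt <- function(dx_mm, c_max_m_s, cfl = 0.2) {
  if (any(c(dx_mm, c_max_m_s, cfl) <= 0)) stop("all arguments must be positive")
  cfl * (dx_mm * 1e-3) / c_max_m_s
}

#' Grid points per acoustic wavelength
#'
#' @param c_m_s sound speed, m/s.
#' @param f_hz frequency, Hz.
#' @param dx_mm spatial step, mm.
#' @return (c/f)/dx, dimensionless.
#' @examples
#' ppw_of(1482, 250e3, 0.4)  # 14.82, i.e. ~15 ppw in water
#' @export
ppw_of <- function(c_m_s, f_hz, dx_mm) {
  if (any(c(c_m_s, f_hz, dx_mm) <= 0)) stop("all arguments must be positive")
  (c_m_s / f_hz) / (dx_mm * 1e-3)
}

#' Simulation grid definition
#'
#' First array index is the axial (beam) direction by convention. World
#' coordinate of voxel i (1-based) along axis d is
#' `origin_mm[d] + (i - 1) * dx_mm`.
#'
#' @param shape integer vector (length 1, 2 or 3).
#' @param dx_mm isotropic spatial step, mm.
#' @param c_max_m_s maximum sound speed the grid must be stable for.
#' @param cfl CFL number; `dt = cfl * dx / c_max`.
#' @param n_steps number of time steps; if `NULL`, [run_pstd()] chooses one
#'   covering a full domain traversal plus the drive burst.
#' @param pml_cells perfectly-matched-layer thickness in cells (>= 8).
#' @param pml_alpha PML absorption strength (nepers per grid-crossing scale).
#' @param origin_mm world coordinate of the first voxel centre.
#' @return object of class `sim_grid`.
#' @export
sim_grid <- function(shape, dx_mm, c_max_m_s, cfl = 0.2, n_steps = NULL,
                     pml_cells = 10L, pml_alpha = 2,
                     origin_mm = rep(0, length(shape))) {
  shape <- as.integer(shape)
  stopifnot(length(shape) >= 1L, length(shape) <= 3L, all(shape >= 4L))
  if (pml_cells < 8L) stop("pml_cells must be >= 8")
  if (any(2L * pml_cells >= shape)) stop("grid too small for the PML")
  dt <- cfl_dt(dx_mm, c_max_m_s, cfl)
  structure(list(shape = shape, dx_mm = dx_mm, dt_s = dt, cfl = cfl,
                 c_max_m_s = c_max_m_s, n_steps = n_steps,
                 pml_cells = as.integer(pml_cells), pml_alpha = pml_alpha,
                 origin_mm = as.numeric(origin_mm)),
            class = "sim_grid")
}

#' Focused bowl transducer geometry
#'
#' Defaults mirror a 250 kHz single-element therapeutic bowl: outer
#' diameter 110 mm, inner (hole) diameter 44 mm, radius of curvature /
#' focal distance 110 mm. The geometric focus sits at
#' `apex_mm + focal_distance_mm * axis`.
#'
#' @param f0_hz centre frequency, Hz.
#' @param outer_diameter_mm aperture outer diameter, mm.
#' @param inner_diameter_mm central hole diameter, mm (0 for a full cap).
#' @param focal_distance_mm radius of curvature, mm.
#' @param apex_mm position of the bowl apex (deepest point), mm.
#' @param axis unit propagation direction.
#' @return object of class `transducer_geometry`.
#' @export
transducer_geometry <- function(f0_hz = 250e3, outer_diameter_mm = 110,
                                inner_diameter_mm = 44,
                                focal_distance_mm = 110,
                                apex_mm = c(0, 0, 0),
                                axis = c(1, 0, 0)) {
  if (inner_diameter_mm < 0 || inner_diameter_mm >= outer_diameter_mm)
    stop("need 0 <= inner diameter < outer diameter")
  if (focal_distance_mm < outer_diameter_mm / 2)
    stop("focal distance must be >= outer radius")
  axis <- as.numeric(axis)
  stopifnot(length(axis) == length(apex_mm))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be a nonzero vector")
  structure(list(f0_hz = f0_hz, outer_diameter_mm = outer_diameter_mm,
                 inner_diameter_mm = inner_diameter_mm,
                 focal_distance_mm = focal_distance_mm,
                 apex_mm = as.numeric(apex_mm), axis = axis / n),
            class = "transducer_geometry")
}

#' Scale a transducer geometry
#'
#' Multiplies all lengths by `s`, preserving the f-number and the
#' inner/outer diameter ratio. Used for reduced-domain (desk-scale) runs.
#' @param geom a [transducer_geometry()].
#' @param s positive scale factor.
#' @export
scale_geometry <- function(geom, s) {
  stopifnot(inherits(geom, "transducer_geometry"), s > 0)
  transducer_geometry(geom$f0_hz, geom$outer_diameter_mm * s,
                      geom$inner_diameter_mm * s,
                      geom$focal_distance_mm * s, geom$apex_mm, geom$axis)
}

#' Drive signal for the therapeutic transducer
#'
#' A sine burst with a half-Hann amplitude ramp over the first
#' `ramp_cycles` cycles (and symmetric ramp-down at the end of the burst).
#'
#' @param amplitude_pa drive amplitude (relative units are fine; the solver
#'   is linear).
#' @param n_cycles number of cycles (>= 1).
#' @param f_hz frequency, Hz.
#' @param ramp_cycles ramp length in cycles.
#' @return object of class `drive_signal`.
#' @export
drive_signal <- function(amplitude_pa = 1, n_cycles = 15L, f_hz = 250e3,
                         ramp_cycles = 2) {
  stopifnot(amplitude_pa > 0, n_cycles >= 1, f_hz > 0, ramp_cycles >= 0)
  structure(list(amplitude_pa = amplitude_pa, n_cycles = n_cycles,
                 f_hz = f_hz, ramp_cycles = ramp_cycles),
            class = "drive_signal")
}

# sampled drive waveform at times t (s)
drive_waveform <- function(drive, t) {
  f <- drive$f_hz
  dur <- drive$n_cycles / f
  s <- drive$amplitude_pa * sin(2 * pi * f * t)
  w <- rep(1, length(t))
  if (drive$ramp_cycles > 0) {
    tr <- drive$ramp_cycles / f
    up <- t < tr
    w[up] <- 0.5 * (1 - cos(pi * t[up] / tr))
    dn <- t > dur - tr & t <= dur
    w[dn] <- 0.5 * (1 - cos(pi * (dur - t[dn]) / tr))
  }
  w[t < 0 | t > dur] <- 0
  s * w
}

#' Per-voxel maximum pressure field
#' @param max_pressure nonnegative array.
#' @param spacing_mm voxel spacing.
#' @param origin_mm world coordinate of first voxel centre.
#' @param axis transducer axis recorded with the field.
#' @return object of class `pressure_field`.
#' @export
pressure_field <- function(max_pressure, spacing_mm,
                           origin_mm = rep(0, length(spacing_mm)),
                           axis = NULL) {
  max_pressure <- as.array(max_pressure)
  if (any(!is.finite(max_pressure)) || any(max_pressure < 0))
    stop("max_pressure must be finite and nonnegative")
  nd <- length(dim(max_pressure))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  structure(list(max_pressure = max_pressure, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), axis = axis),
            class = "pressure_field")
}

# --- internal broadcasting helpers -----------------------------------------

# expand a per-axis vector v (length shape[d]) to a full array along dim d
expand_vec <- function(v, shape, d) {
  nd <- length(shape)
  if (nd == 1L) return(v)
  src <- c(d, seq_len(nd)[-d])
  a <- array(v, dim = shape[src])
  aperm(a, match(seq_len(nd), src))
}

# angular wavenumbers (rad/m) for an n-point axis with step dx_m
k_axis <- function(n, dx_m) {
  m <- seq_len(n) - 1
  m[m > n / 2] <- m[m > n / 2] - n
  2 * pi * m / (n * dx_m)
}

# PML attenuation profile exp(-sigma*dt/2) at regular / staggered positions
pml_profile <- function(n, pml_cells, pml_alpha, dx_m, c_ref, dt,
                        staggered = FALSE) {
  pos <- seq_len(n) + (if (staggered) 0.5 else 0)
  sigma <- numeric(n)
  left <- pml_cells + 1 - pos            # >0 inside left PML
  right <- pos - (n - pml_cells)         # >0 inside right PML
  depth <- pmax(pmax(left, 0), pmax(right, 0)) / pml_cells
  sigma <- pml_alpha * (c_ref / dx_m) * depth^4
  exp(-sigma * dt / 2)
}

# midpoint average along dim d (edge replicated) for staggered density
stagger_avg <- function(a, d) {
  nd <- length(dim(a)); if (nd == 0) nd <- 1
  n <- if (nd == 1) length(a) else dim(a)[d]
  idx <- c(seq(2, n), n)
  if (nd == 1) return((a + a[idx]) / 2)
  args <- rep(list(quote(expr = )), nd)
  args[[d]] <- idx
  shifted <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  (a + array(shifted, dim(a))) / 2
}

#' Discretize a focused bowl (3D) or arc (2D) source onto a grid
#'
#' Selects the voxels lying on the spherical cap of radius
#' `focal_distance_mm` about the geometric focus, restricted to the annular
#' aperture between the inner and outer diameters. All selected voxels are
#' equidistant from the focus to within half a grid step, so driving them in
#' phase reproduces the geometric focusing of a single-element bowl.
#'
#' @param geom a [transducer_geometry()] (2- or 3-component apex/axis
#'   matching the grid dimensionality).
#' @param grid a [sim_grid()].
#' @return list with `indices` (linear voxel indices), `positions_mm`
#'   (matrix) and `n`.
#' @export
discretize_bowl <- function(geom, grid) {
  shape <- grid$shape
  nd <- length(shape)
  if (nd < 2L) stop("bowl sources need a 2D or 3D grid")
  dx <- grid$dx_mm
  axis <- geom$axis[seq_len(nd)]
  apex <- geom$apex_mm[seq_len(nd)]
  f <- geom$focal_distance_mm
  focus <- apex + f * axis
  coords <- lapply(seq_len(nd), function(d)
    grid$origin_mm[d] + (seq_len(shape[d]) - 1) * dx)
  # squared distance to focus, accumulated per axis
  d2 <- array(0, shape)
  for (d in seq_len(nd)) {
    d2 <- d2 + expand_vec((coords[[d]] - focus[d])^2, shape, d)
  }
  r <- sqrt(d2)
  # angle from the -axis direction seen from the focus
  proj <- array(0, shape)
  for (d in seq_len(nd)) {
    proj <- proj + expand_vec((coords[[d]] - focus[d]) * (-axis[d]), shape, d)
  }
  cosang <- proj / pmax(r, .Machine$double.eps)
  th_max <- asin(pmin(1, (geom$outer_diameter_mm / 2) / f))
  th_min <- asin(pmin(1, (geom$inner_diameter_mm / 2) / f))
  # analytic cap bounding box (apex + aperture rim) must clear the PML
  rim_center <- focus - f * cos(th_max) * axis
  rim_half <- f * sin(th_max) * sqrt(pmax(1 - axis^2, 0))
  b_lo <- pmin(apex, rim_center - rim_half)
  b_hi <- pmax(apex, rim_center + rim_half)
  pml <- grid$pml_cells
  g_lo <- grid$origin_mm + pml * dx
  g_hi <- grid$origin_mm + (shape - 1 - pml) * dx
  bad <- b_lo < g_lo - dx / 2 | b_hi > g_hi + dx / 2
  if (any(bad)) {
    stop(sprintf(
      "bowl clipped by grid/PML along axis %s: bowl spans %s..%s mm, usable grid %s..%s mm",
      paste(which(bad), collapse = ","),
      paste(round(b_lo, 1), collapse = ","),
      paste(round(b_hi, 1), collapse = ","),
      paste(round(g_lo, 1), collapse = ","),
      paste(round(g_hi, 1), collapse = ",")))
  }
  sel <- abs(r - f) <= dx / 2 & cosang >= cos(th_max) & cosang <= cos(th_min) + 1e-12
  idx <- which(sel)
  if (length(idx) == 0L) stop("empty source set: bowl does not intersect the grid")
  sub <- arrayInd(idx, shape)
  pos <- sapply(seq_len(nd), function(d)
    grid$origin_mm[d] + (sub[, d] - 1) * dx)
  list(indices = idx, positions_mm = matrix(pos, ncol = nd), n = length(idx))
}

#' Linear acoustic propagation: k-space pseudospectral time domain
#'
#' Solves the first-order linear acoustic equations (momentum, mass
#' conservation, pressure closure) in a heterogeneous medium with spectral
#' spatial derivatives on staggered grids, exact-in-homogeneous k-space
#' dispersion correction (reference speed = medium maximum), split-field
#' PML boundaries, and a local frequency-squared (y = 2) absorption term.
#' Works in 1D, 2D and 3D; the per-voxel maximum absolute pressure is
#' recorded after a start-up window of two drive cycles.
#'
#' @param medium an [acoustic_medium()] with the same shape as the grid.
#' @param grid a [sim_grid()]; `grid$c_max_m_s` must be >= the medium's
#'   maximum sound speed.
#' @param source list with `indices` (linear voxel indices driven in phase),
#'   e.g. from [discretize_bowl()], or a single linear index for a point
#'   source.
#' @param drive a [drive_signal()].
#' @return a [pressure_field()].
#' @export
run_pstd <- function(medium, grid, source, drive) {
  stopifnot(inherits(medium, "acoustic_medium"), inherits(grid, "sim_grid"),
            inherits(drive, "drive_signal"))
  shape <- grid$shape
  nd <- length(shape)
  if (!identical(as.integer(dim(medium$density)), shape))
    stop("medium and grid shapes disagree")
  if (is.numeric(source)) source <- list(indices = as.integer(source))
  c0 <- medium$sound_speed
  rho0 <- medium$density
  c_max <- max(c0)
  dx_m <- grid$dx_mm * 1e-3
  dt <- grid$dt_s
  if (c_max * dt / dx_m > 0.35)
    stop(sprintf("CFL violation: c_max*dt/dx = %.3f > 0.35", c_max * dt / dx_m))

  n_steps <- grid$n_steps
  if (is.null(n_steps)) {
    diag_m <- sqrt(sum((shape * dx_m)^2))
    t_end <- 1.15 * (diag_m / min(c0) + (drive$n_cycles + 2) / drive$f_hz)
    n_steps <- ceiling(t_end / dt)
  }

  # spectral operators: kappa * i k * (half-cell shift) per axis
  kvecs <- lapply(shape, k_axis, dx_m = dx_m)
  k2 <- array(0, shape)
  for (d in seq_len(nd)) k2 <- k2 + expand_vec(kvecs[[d]]^2, shape, d)
  kap_arg <- c_max * sqrt(k2) * dt / 2
  kappa <- ifelse(kap_arg == 0, 1, sin(kap_arg) / pmax(kap_arg, .Machine$double.eps))
  Af <- Ab <- vector("list", nd)
  for (d in seq_len(nd)) {
    kd <- expand_vec(kvecs[[d]], shape, d)
    Af[[d]] <- kappa * (1i * kd) * exp( 1i * kd * dx_m / 2)
    Ab[[d]] <- kappa * (1i * kd) * exp(-1i * kd * dx_m / 2)
  }

  # PML exponentials (full arrays), regular and staggered
  pml_r <- pml_s <- vector("list", nd)
  for (d in seq_len(nd)) {
    pr <- pml_profile(shape[d], grid$pml_cells, grid$pml_alpha, dx_m,
                      c_max, dt, staggered = FALSE)
    ps <- pml_profile(shape[d], grid$pml_cells, grid$pml_alpha, dx_m,
                      c_max, dt, staggered = TRUE)
    pml_r[[d]] <- expand_vec(pr, shape, d)
    pml_s[[d]] <- expand_vec(ps, shape, d)
  }

  rho_sg <- lapply(seq_len(nd), function(d) stagger_avg(rho0, d))

  # absorption: alpha0 map in dB/cm/MHz^y -> Np/((rad/s)^y m); for y = 2 the
  # loss enters the pressure closure as tau * drho/dt with tau = -2 a c0.
  y <- medium$y
  if (any(medium$alpha0_map > 0) && y != 2)
    stop("the solver implements absorption for y = 2 only; refit alpha0 first")
  alpha_np <- medium$alpha0_map * (100 / 8.685889638065035) / (2 * pi * 1e6)^y
  tau_term <- -2 * alpha_np * c0 * rho0     # multiplies div(u); thermoviscous
  c0sq <- c0^2

  u <- lapply(seq_len(nd), function(d) array(0, shape))
  rho <- lapply(seq_len(nd), function(d) array(0, shape))
  p <- array(0, shape)
  pmax_field <- array(0, shape)
  ts <- (seq_len(n_steps) - 1) * dt
  src_amp <- drive_waveform(drive, ts)
  # additive mass-source scaling; relative pressures only (linear solver)
  src_scale <- dt / (mean(c0sq) * nd)
  record_from <- ceiling((2 / drive$f_hz) / dt)
  inv_n <- 1 / prod(shape)

  for (it in seq_len(n_steps)) {
    P <- stats::fft(p)
    for (d in seq_len(nd)) {
      dpdx <- Re(stats::fft(P * Af[[d]], inverse = TRUE)) * inv_n
      u[[d]] <- pml_s[[d]] * (pml_s[[d]] * u[[d]] - (dt / rho_sg[[d]]) * dpdx)
    }
    divu <- array(0, shape)
    for (d in seq_len(nd)) {
      dudx <- Re(stats::fft(stats::fft(u[[d]]) * Ab[[d]], inverse = TRUE)) * inv_n
      divu <- divu + dudx
      rho[[d]] <- pml_r[[d]] * (pml_r[[d]] * rho[[d]] - dt * rho0 * dudx)
    }
    if (src_amp[it] != 0) {
      add <- src_amp[it] * src_scale
      for (d in seq_len(nd)) rho[[d]][source$indices] <-
          rho[[d]][source$indices] + add
    }
    rho_sum <- rho[[1L]]
    if (nd > 1L) for (d in 2:nd) rho_sum <- rho_sum + rho[[d]]
    p <- c0sq * (rho_sum + tau_term * divu)
    if (it > record_from) {
      ap <- abs(p)
      upd <- ap > pmax_field
      pmax_field[upd] <- ap[upd]
    }
    if (it %% 100L == 0L && anyNA(p))
      stop(sprintf("solver diverged (NaN) at step %d", it))
  }
  if (anyNA(pmax_field)) stop("solver diverged (NaN) during the run")
  pressure_field(pmax_field, spacing_mm = grid$dx_mm,
                 origin_mm = grid$origin_mm,
                 axis = if (nd >= 2) geom_axis_or_default(nd) else 1)
}

geom_axis_or_default <- function(nd) c(1, rep(0, nd - 1))

# --- analytic free-field oracle --------------------------------------------

#' Rayleigh-integral reference field of the focused bowl (3D)
#'
#' Numerically integrates exp(ikR)/R over the spherical-cap annulus of the
#' bowl; a lossless homogeneous medium is assumed. Used as an independent
#' oracle for the focal position and beam widths of [run_pstd()]. Returned
#' pressures are relative (unit surface velocity, constant factors dropped).
#'
#' @param geom a [transducer_geometry()] with 3D apex/axis.
#' @param points_mm n x 3 matrix of field points, mm (world coordinates).
#' @param c_m_s sound speed, m/s.
#' @param f_hz frequency (defaults to the transducer's).
#' @param n_theta,n_phi quadrature resolution over the cap.
#' @return complex vector of relative pressures at `points_mm`.
#' @export
oneil_reference <- function(geom, points_mm, c_m_s = water_constants()$c_m_s,
                            f_hz = geom$f0_hz, n_theta = 220L, n_phi = 440L) {
  stopifnot(inherits(geom, "transducer_geometry"))
  points_mm <- matrix(points_mm, ncol = 3)
  k <- 2 * pi * f_hz / c_m_s            # rad/m
  f <- geom$focal_distance_mm
  a <- geom$axis
  # orthonormal frame
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * a) * a; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(a[2] * e2[3] - a[3] * e2[2],
          a[3] * e2[1] - a[1] * e2[3],
          a[1] * e2[2] - a[2] * e2[1])
  focus <- geom$apex_mm + f * a
  th_max <- asin((geom$outer_diameter_mm / 2) / f)
  th_min <- asin((geom$inner_diameter_mm / 2) / f)
  th <- th_min + (seq_len(n_theta) - 0.5) * (th_max - th_min) / n_theta
  ph <- (seq_len(n_phi) - 0.5) * (2 * pi) / n_phi
  dS <- (f * 1e-3)^2 * sin(th) * ((th_max - th_min) / n_theta) * (2 * pi / n_phi)
  # source points (mm): focus - f * (cos(th) a + sin(th)(cos(ph) e2 + sin(ph) e3))
  ct <- cos(th); st <- sin(th)
  cp <- cos(ph); sp <- sin(ph)
  # build (n_theta*n_phi) x 3 source matrix
  dir1 <- outer(ct, rep(1, n_phi))                 # component along a
  dir2 <- outer(st, cp)
  dir3 <- outer(st, sp)
  sx <- focus[1] - f * (dir1 * a[1] + dir2 * e2[1] + dir3 * e3[1])
  sy <- focus[2] - f * (dir1 * a[2] + dir2 * e2[2] + dir3 * e3[2])
  sz <- focus[3] - f * (dir1 * a[3] + dir2 * e2[3] + dir3 * e3[3])
  w <- outer(dS, rep(1, n_phi))
  sxv <- as.vector(sx); syv <- as.vector(sy); szv <- as.vector(sz)
  wv <- as.vector(w)
  out <- complex(length.out = nrow(points_mm))
  chunk <- max(1L, floor(2e6 / length(sxv)))
  for (i0 in seq(1, nrow(points_mm), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(points_mm))
    for (i in i0:i1) {
      Rm <- sqrt((points_mm[i, 1] - sxv)^2 + (points_mm[i, 2] - syv)^2 +
                 (points_mm[i, 3] - szv)^2) * 1e-3
      out[i] <- sum(wv * exp(1i * k * Rm) / Rm)
    }
  }
  out
}

#' Closed-form on-axis pressure of a full spherical-cap bowl
#'
#' Exact on-axis reduction of the Rayleigh integral for an aperture with no
#' central hole (inner diameter 0); an annular bowl is the difference of two
#' caps. Relative units matching [oneil_reference()].
#'
#' @param geom a [transducer_geometry()]; `inner_diameter_mm` is honoured
#'   (annulus handled by cap subtraction).
#' @param z_mm axial distances from the apex along the axis, mm.
#' @inheritParams oneil_reference
#' @return complex vector.
#' @export
oneil_onaxis <- function(geom, z_mm, c_m_s = water_constants()$c_m_s,
                         f_hz = geom$f0_hz) {
  k <- 2 * pi * f_hz / c_m_s
  f <- geom$focal_distance_mm
  cap <- function(theta_max, z) {
    # R at cap edge and at apex for on-axis point z (mm -> m inside)
    Redge <- sqrt(f^2 + (z - f)^2 + 2 * f * (z - f) * cos(theta_max)) * 1e-3
    Rapex <- abs(z) * 1e-3
    fz <- (f - z) * 1e-3
    out <- 2 * pi * (f * 1e-3) / (1i * k * fz) * (exp(1i * k * Redge) - exp(1i * k * Rapex))
    # z == f: integrand constant, integral = 2*pi*f^2(1-cos(th))/f * e^{ikf}
    deg <- abs(fz) < 1e-9
    out[deg] <- 2 * pi * (f * 1e-3) * (1 - cos(theta_max)) * exp(1i * k * f * 1e-3)
    out
  }
  th_max <- asin((geom$outer_diameter_mm / 2) / f)
  th_min <- asin((geom$inner_diameter_mm / 2) / f)
  res <- cap(th_max, z_mm)
  if (th_min > 0) res <- res - cap(th_min, z_mm)
  res
}

#' 2D (focused arc) analogue of the Rayleigh oracle
#'
#' Line-source integral over the focused arc with the 2D free-space Green's
#' function H0(kR); the matched reference for the solver's 2D mode.
#'
#' @param geom a [transducer_geometry()] (only diameters/focal used).
#' @param points_mm n x 2 matrix (axial, lateral) from the apex, mm.
#' @inheritParams oneil_reference
#' @param n_theta quadrature points per arc side.
#' @return complex vector of relative pressures.
#' @export
oneil_reference_2d <- function(geom, points_mm,
                               c_m_s = water_constants()$c_m_s,
                               f_hz = geom$f0_hz, n_theta = 600L) {
  points_mm <- matrix(points_mm, ncol = 2)
  k <- 2 * pi * f_hz / c_m_s
  f <- geom$focal_distance_mm
  th_max <- asin((geom$outer_diameter_mm / 2) / f)
  th_min <- asin((geom$inner_diameter_mm / 2) / f)
  th_half <- th_min + (seq_len(n_theta) - 0.5) * (th_max - th_min) / n_theta
  th <- c(-rev(th_half), th_half)
  dl <- (f * 1e-3) * (th_max - th_min) / n_theta
  # arc points (axial from apex, lateral); focus at (f, 0)
  sx <- f - f * cos(th)
  sy <- f * sin(th)
  vapply(seq_len(nrow(points_mm)), function(i) {
    Rm <- sqrt((points_mm[i, 1] - sx)^2 + (points_mm[i, 2] - sy)^2) * 1e-3
    h0 <- besselJ(k * Rm, 0) + 1i * besselY(k * Rm, 0)
    sum(h0) * dl
  }, complex(1))
}

#' Free-field focal convergence study
#'
#' Runs the pseudospectral solver in homogeneous water at each grid
#' resolution in `ppw_list` and tabulates the focal properties. Successive
#' rows stabilize as the resolution increases; desk-scale sweeps use the 2D
#' mode and a reduced geometry.
#'
#' @param ppw_list grid resolutions, points per wavelength in water.
#' @param geom a [transducer_geometry()].
#' @param drive a [drive_signal()].
#' @param mode "2d" (default, fast) or "3d".
#' @param c_m_s water sound speed.
#' @param cfl CFL number.
#' @param pml_cells PML thickness.
#' @return data.frame with columns ppw, dx_mm, axial_fwhm_mm,
#'   lateral_fwhm_mm, peak_pressure.
#' @export
convergence_study <- function(ppw_list, geom, drive = drive_signal(f_hz = geom$f0_hz),
                              mode = c("2d", "3d"),
                              c_m_s = water_constants()$c_m_s, cfl = 0.2,
                              pml_cells = 10L) {
  mode <- match.arg(mode)
  rows <- lapply(ppw_list, function(ppw) {
    ff <- free_field_run(geom, ppw, drive, mode = mode, c_m_s = c_m_s,
                         cfl = cfl, pml_cells = pml_cells)
    m <- free_field_focal_metrics(ff$field, geom)
    data.frame(ppw = ppw, dx_mm = ff$dx_mm, axial_fwhm_mm = m$axial_fwhm_mm,
               lateral_fwhm_mm = m$lateral_fwhm_mm,
               peak_pressure = m$p_peak)
  })
  do.call(rbind, rows)
}

#' Run a free-field simulation of the bowl at a given resolution
#'
#' Builds a grid just large enough for the bowl, its focus and a margin,
#' places the apex behind the PML and runs [run_pstd()] in water.
#'
#' @inheritParams convergence_study
#' @param ppw grid resolution in points per wavelength (water).
#' @return list with `field` (a [pressure_field()]), `geom` (apex-shifted
#'   geometry in grid coordinates), `dx_mm`.
#' @export
free_field_run <- function(geom, ppw, drive = drive_signal(f_hz = geom$f0_hz),
                           mode = c("2d", "3d"),
                           c_m_s = water_constants()$c_m_s, cfl = 0.2,
                           pml_cells = 10L) {
  mode <- match.arg(mode)
  nd <- if (mode == "2d") 2L else 3L
  dx <- (c_m_s / geom$f0_hz) * 1000 / ppw
  f <- geom$focal_distance_mm
  od <- geom$outer_diameter_mm
  bowl_depth <- f - sqrt(f^2 - (od / 2)^2)
  ax_extent <- bowl_depth + f * 1.35
  lat_extent <- od * 1.15
  n_ax <- ceiling(ax_extent / dx) + 2L * pml_cells
  n_lat <- ceiling(lat_extent / dx) + 2L * pml_cells
  shape <- c(n_ax, rep(n_lat, nd - 1L))
  apex <- c((pml_cells + 2L) * dx, rep((n_lat - 1) * dx / 2, nd - 1L))
  g <- transducer_geometry(geom$f0_hz, od, geom$inner_diameter_mm, f,
                           apex_mm = apex, axis = c(1, rep(0, nd - 1L)))
  grid <- sim_grid(shape, dx, c_max_m_s = c_m_s, cfl = cfl,
                   pml_cells = pml_cells)
  med <- homogeneous_medium(shape, dx, c_m_s = c_m_s)
  src <- discretize_bowl(g, grid)
  field <- run_pstd(med, grid, src, drive)
  field$axis <- g$axis
  list(field = field, geom = g, dx_mm = dx)
}

# focal peak + FWHMs of a free-field run (peak searched near the nominal focus)
free_field_focal_metrics <- function(field, geom) {
  nd <- length(dim(field$max_pressure))
  focus <- (geom$apex_mm + geom$focal_distance_mm * geom$axis)[seq_len(nd)]
  half <- 0.45 * geom$focal_distance_mm
  pk <- focal_peak_in_roi(field, roi = list(center_mm = focus,
                                            half_width_mm = half))
  ax <- fwhm_along(field, point_mm = pk$location_mm,
                   direction = c(1, rep(0, nd - 1L)))
  lat <- fwhm_along(field, point_mm = pk$location_mm,
                    direction = c(0, 1, rep(0, nd - 2L)))
  list(p_peak = pk$p_peak, peak_location_mm = pk$location_mm,
       axial_fwhm_mm = ax, lateral_fwhm_mm = lat)
}
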