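#' Specification of a synthetic skull phantom
#'
#' Describes either a flat bone slab (tilted to create a known incidence
#' angle) or a spherical-cap shell with sutures and orbit holes, standing in
#' for an ex-vivo primate skull fragment imaged by CT. Voxels strictly
#' inside bone get `hu_bone`; voxels straddling a surface get linearly
#' interpolated HU (partial volume), which makes subvoxel surface and
#' thickness checks meaningful.
#'
#' @param grid_shape integer triple of voxel counts (axial, lateral,
#'   elevation); first index is the beam direction.
#' @param spacing_mm voxel spacing, mm (scalar or triple).
#' @param skull_kind "slab" or "spherical_shell".
#' @param outer_radius_mm outer radius of curvature (shell only).
#' @param thickness_mm nominal bone thickness, mm; must be at least two
#'   voxels.
#' @param thickness_ripple_mm amplitude of the sinusoidal thickness ripple
#'   (shell only).
#' @param tilt_deg length-2 rotations (degrees) about the two lateral axes.
#' @param hu_bone HU assigned to solid bone (default 1500).
#' @param hu_background HU of the water/soft-tissue background (default 0).
#' @param suture_grooves list of `list(position, width_mm, depth_mm)`
#'   grooves carved into the inner shell surface; `position` is the lateral
#'   (second-axis) world coordinate of the groove line, mm.
#' @param orbit_holes list of `list(center, radius_mm)` circular holes;
#'   `center` is the lateral (axis 2, axis 3) world position, mm.
#' @param cap_half_angle_deg angular half-extent of the shell cap.
#' @param apex_depth_frac axial position of the shell apex / slab centre as
#'   a fraction of the axial extent.
#' @param center_mm optional explicit slab/shell-apex centre (3-vector).
#' @param noise_seed integer seed recorded with the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm,
                         skull_kind = c("slab", "spherical_shell"),
                         outer_radius_mm = NULL, thickness_mm = 4,
                         thickness_ripple_mm = 0, tilt_deg = c(0, 0),
                         hu_bone = 1500, hu_background = 0,
                         suture_grooves = list(), orbit_holes = list(),
                         cap_half_angle_deg = 60, apex_depth_frac = 0.35,
                         center_mm = NULL, noise_seed = 1L) {
  skull_kind <- match.arg(skull_kind)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (thickness_mm < 2 * min(spacing_mm))
    stop("thickness_mm must be >= 2 * min(spacing_mm)")
  if (skull_kind == "spherical_shell") {
    if (is.null(outer_radius_mm) || outer_radius_mm <= thickness_mm)
      stop("shell phantoms need outer_radius_mm > thickness_mm")
    for (h in orbit_holes) {
      if (h$radius_mm >= outer_radius_mm)
        stop("orbit hole radius must be smaller than the shell radius")
    }
    for (g in suture_grooves) {
      if (g$depth_mm >= thickness_mm - thickness_ripple_mm)
        stop("suture groove deeper than the shell thickness")
    }
  }
  stopifnot(length(tilt_deg) == 2L)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 skull_kind = skull_kind, outer_radius_mm = outer_radius_mm,
                 thickness_mm = thickness_mm,
                 thickness_ripple_mm = thickness_ripple_mm,
                 tilt_deg = as.numeric(tilt_deg), hu_bone = hu_bone,
                 hu_background = hu_background,
                 suture_grooves = suture_grooves, orbit_holes = orbit_holes,
                 cap_half_angle_deg = cap_half_angle_deg,
                 apex_depth_frac = apex_depth_frac, center_mm = center_mm,
                 noise_seed = as.integer(noise_seed)),
            class = "phantom_spec")
}

# rotation taking the beam axis e1 to the slab/cap normal for tilt (a, b):
# R = R3(b) %*% R2(a), rotations about the two lateral axes (degrees)
tilt_rotation <- function(tilt_deg) {
  a <- tilt_deg[1] * pi / 180; b <- tilt_deg[2] * pi / 180
  R2 <- rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  R3 <- rbind(c(cos(b), -sin(b), 0), c(sin(b), cos(b), 0), c(0, 0, 1))
  R3 %*% R2
}

phantom_coords <- function(spec) {
  lapply(1:3, function(d)
    (seq_len(spec$grid_shape[d]) - 1) * spec$spacing_mm[d])
}

phantom_center <- function(spec) {
  if (!is.null(spec$center_mm)) return(as.numeric(spec$center_mm))
  ext <- (spec$grid_shape - 1) * spec$spacing_mm
  # slabs are centred axially (room to rotate); shells anchor the cap apex
  frac <- if (spec$skull_kind == "slab") 0.5 else spec$apex_depth_frac
  c(frac * ext[1], ext[2] / 2, ext[3] / 2)
}

slice_masks_from_array <- function(mask3d) {
  lapply(seq_len(dim(mask3d)[3]), function(k) mask3d[, , k])
}

#' Generate a tilted flat-slab skull phantom
#'
#' A bone slab of the stated thickness, rotated by `tilt_deg` about the two
#' lateral axes, with exact analytic ground truth: the outer-surface points,
#' the surface normal at the beam-axis intersection, and the incidence angle
#' 90 deg minus the angle between that normal and the beam axis.
#'
#' @param spec a [phantom_spec()] with `skull_kind = "slab"`.
#' @return list with `hu` (an [hu_volume()]) and `truth` (list:
#'   `surface_points`, `true_normal`, `true_incidence_deg`,
#'   `true_thickness_map`, `mask`, `slice_masks`).
#' @export
make_slab_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$skull_kind != "slab") stop("spec$skull_kind must be 'slab'")
  n <- unit_vec(as.vector(tilt_rotation(spec$tilt_deg) %*% c(1, 0, 0)))
  if (n[1] <= 0.05) stop("tilt too steep: slab nearly parallel to the beam")
  ctr <- phantom_center(spec)
  co <- phantom_coords(spec)
  shape <- spec$grid_shape
  t2 <- spec$thickness_mm / 2
  s <- expand_vec((co[[1]] - ctr[1]) * n[1], shape, 1) +
       expand_vec((co[[2]] - ctr[2]) * n[2], shape, 2) +
       expand_vec((co[[3]] - ctr[3]) * n[3], shape, 3)
  # projected voxel extent along the slab normal
  h <- sum(abs(n) * spec$spacing_mm)
  frac <- pmin(pmax(0.5 + (t2 - abs(s)) / h, 0), 1)
  hu <- spec$hu_background + (spec$hu_bone - spec$hu_background) * frac
  # outer/inner face axial coordinates across the lateral footprint
  face_x <- function(sgn) {
    dy <- range(co[[2]] - ctr[2]); dz <- range(co[[3]] - ctr[3])
    corners <- expand.grid(dy = dy, dz = dz)
    ctr[1] + (sgn * t2 - n[2] * corners$dy - n[3] * corners$dz) / n[1]
  }
  xr <- range(c(face_x(-1), face_x(1)))
  ext1 <- (shape[1] - 1) * spec$spacing_mm[1]
  if (xr[1] < spec$spacing_mm[1] || xr[2] > ext1 - spec$spacing_mm[1]) {
    stop(sprintf(
      "slab exits the grid after rotation: faces span %.1f..%.1f mm axially, grid holds %.1f..%.1f mm",
      xr[1], xr[2], spec$spacing_mm[1], ext1 - spec$spacing_mm[1]))
  }
  mask <- frac >= 0.5
  # analytic outer-surface points, one per lateral column
  yz <- expand.grid(y = co[[2]], z = co[[3]])
  sx <- ctr[1] + (-t2 - n[2] * (yz$y - ctr[2]) - n[3] * (yz$z - ctr[3])) / n[1]
  keep <- sx >= 0 & sx <= ext1
  surface_points <- cbind(sx, yz$y, yz$z)[keep, , drop = FALSE]
  colnames(surface_points) <- c("x", "y", "z")
  alpha_aux <- acos(min(abs(n[1]), 1)) * 180 / pi
  truth <- list(
    surface_points = surface_points,
    true_normal = n,
    true_incidence_deg = 90 - alpha_aux,
    true_thickness_map = matrix(spec$thickness_mm, shape[2], shape[3]),
    mask = mask,
    slice_masks = slice_masks_from_array(mask))
  list(hu = hu_volume(hu, spec$spacing_mm), truth = truth)
}

#' Generate a spherical-cap shell skull phantom
#'
#' A shell of outer radius `outer_radius_mm` and nominal thickness
#' `thickness_mm`, optionally with a sinusoidal thickness ripple, straight
#' suture grooves carved into the inner surface, and circular orbit holes
#' drilled along the beam axis. The constructed thickness field is recorded
#' analytically per beam-axis column together with the local surface
#' obliquity (cosine between the radial direction and the beam axis).
#'
#' @param spec a [phantom_spec()] with `skull_kind = "spherical_shell"`.
#' @return list with `hu` and `truth` (adds `true_obliquity_map` and
#'   `sphere_center_mm` to the slab truth fields).
#' @export
make_shell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$skull_kind != "spherical_shell")
    stop("spec$skull_kind must be 'spherical_shell'")
  R0 <- spec$outer_radius_mm
  t0 <- spec$thickness_mm
  u <- unit_vec(as.vector(tilt_rotation(spec$tilt_deg) %*% c(1, 0, 0)))
  apex <- phantom_center(spec)
  C <- apex + R0 * u                    # sphere centre (deeper than apex)
  co <- phantom_coords(spec)
  shape <- spec$grid_shape
  dx1 <- expand_vec(co[[1]] - C[1], shape, 1)
  dx2 <- expand_vec(co[[2]] - C[2], shape, 2)
  dx3 <- expand_vec(co[[3]] - C[3], shape, 3)
  rho <- sqrt(dx1^2 + dx2^2 + dx3^2)
  rho <- pmax(rho, .Machine$double.eps)
  # angular position on the cap: theta from the apex direction (-u)
  cth <- (dx1 * (-u[1]) + dx2 * (-u[2]) + dx3 * (-u[3])) / rho
  theta <- acos(pmin(pmax(cth, -1), 1))
  # azimuth in a frame orthogonal to u (only drives the ripple pattern)
  ref <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  e2 <- unit_vec(ref - sum(ref * u) * u)
  e3 <- c(u[2] * e2[3] - u[3] * e2[2], u[3] * e2[1] - u[1] * e2[3],
          u[1] * e2[2] - u[2] * e2[1])
  phi <- atan2(dx1 * e3[1] + dx2 * e3[2] + dx3 * e3[3],
               dx1 * e2[1] + dx2 * e2[2] + dx3 * e2[3])
  t_loc <- t0 + if (spec$thickness_ripple_mm > 0) {
    spec$thickness_ripple_mm * sin(6 * theta) * cos(4 * phi)
  } else 0
  # grooves raise the inner radius locally (carved from the inner table)
  groove_cut <- array(0, shape)
  for (g in spec$suture_grooves) {
    inside <- abs(expand_vec(co[[2]], shape, 2) - g$position) < g$width_mm / 2
    groove_cut[inside] <- pmax(groove_cut[inside], g$depth_mm)
  }
  Rin <- R0 - t_loc + groove_cut
  h <- min(spec$spacing_mm)
  f_out <- pmin(pmax(0.5 + (R0 - rho) / h, 0), 1)
  f_in <- pmin(pmax(0.5 + (rho - Rin) / h, 0), 1)
  frac <- pmin(f_out, f_in)
  frac[theta > spec$cap_half_angle_deg * pi / 180] <- 0
  for (hole in spec$orbit_holes) {
    lat2 <- (expand_vec(co[[2]], shape, 2) - hole$center[1])^2 +
            (expand_vec(co[[3]], shape, 3) - hole$center[2])^2
    frac[lat2 < hole$radius_mm^2] <- 0
  }
  hu <- spec$hu_background + (spec$hu_bone - spec$hu_background) * frac
  mask <- frac >= 0.5
  # analytic per-column truth along the beam axis
  yz <- expand.grid(y = co[[2]], z = co[[3]])
  d2 <- (yz$y - C[2])^2 + (yz$z - C[3])^2
  hit <- d2 < R0^2
  sx <- rep(NA_real_, nrow(yz))
  sx[hit] <- C[1] - sqrt(R0^2 - d2[hit])
  tmap <- omap <- matrix(NA_real_, shape[2], shape[3])
  spx <- spy <- spz <- numeric(0)
  for (i in which(hit)) {
    P <- c(sx[i], yz$y[i], yz$z[i])
    v <- (P - C) / R0
    th <- acos(pmin(pmax(sum(v * (-u)), -1), 1))
    if (th > spec$cap_half_angle_deg * pi / 180) next
    in_hole <- FALSE
    for (hole in spec$orbit_holes) {
      if ((P[2] - hole$center[1])^2 + (P[3] - hole$center[2])^2 <
          hole$radius_mm^2) in_hole <- TRUE
    }
    if (in_hole) next
    ph <- atan2(sum((P - C) * e3), sum((P - C) * e2))
    tl <- t0 + if (spec$thickness_ripple_mm > 0)
      spec$thickness_ripple_mm * sin(6 * th) * cos(4 * ph) else 0
    for (g in spec$suture_grooves) {
      if (abs(P[2] - g$position) < g$width_mm / 2) tl <- tl - g$depth_mm
    }
    jk <- c(which.min(abs(co[[2]] - P[2])), which.min(abs(co[[3]] - P[3])))
    tmap[jk[1], jk[2]] <- tl
    omap[jk[1], jk[2]] <- abs(v[1])     # cos(angle between radial and beam)
    spx <- c(spx, P[1]); spy <- c(spy, P[2]); spz <- c(spz, P[3])
  }
  # normal at the beam-axis intersection (through the lateral grid centre)
  gy <- phantom_center(spec)[2]; gz <- phantom_center(spec)[3]
  d0 <- (gy - C[2])^2 + (gz - C[3])^2
  if (d0 >= R0^2) stop("beam axis misses the shell; reduce the tilt")
  Pax <- c(C[1] - sqrt(R0^2 - d0), gy, gz)
  n_ax <- unit_vec(C - Pax)
  alpha_aux <- acos(min(abs(n_ax[1]), 1)) * 180 / pi
  truth <- list(
    surface_points = cbind(x = spx, y = spy, z = spz),
    true_normal = n_ax,
    true_incidence_deg = 90 - alpha_aux,
    true_thickness_map = tmap,
    true_obliquity_map = omap,
    sphere_center_mm = C,
    mask = mask,
    slice_masks = slice_masks_from_array(mask))
  list(hu = hu_volume(hu, spec$spacing_mm), truth = truth)
}

# run fn with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Render a harmonic B-mode slice stack from a phantom
#'
#' Each slice shows the skull cross-section as a bright band (amplitude 1)
#' over a weak soft-tissue background (amplitude 0.05), degraded by
#' multiplicative Rayleigh speckle and additive Gaussian noise, then
#' linearly normalized to [0, 1] per slice so the standard 0.19
#' normalized-amplitude binarization threshold applies. With `snr_db =
#' Inf` the noise model is disabled entirely and thresholding recovers the
#' ground-truth masks exactly.
#'
#' @param phantom output of [make_slab_phantom()] / [make_shell_phantom()].
#' @param slice_axis axis along which slices are taken (3 = elevation).
#' @param slice_spacing_mm spacing between kept slices; must be a multiple
#'   of (and at least) the in-plane voxel spacing.
#' @param noise list with `speckle_scale` in [0, 1] (fraction of fully
#'   developed speckle, default 0.5) and `snr_db` (additive noise level
#'   relative to the bone amplitude, default Inf).
#' @param seed RNG seed; identical spec + seed gives bit-identical stacks.
#' @return list with `stack` (class `bmode_stack`: `slices` array
#'   axial x lateral x n_slice, spacings, axis) and `gt_masks` (logical
#'   array of the matching ground-truth masks).
#' @export
render_bmode_stack <- function(phantom, slice_axis = 3L,
                               slice_spacing_mm = NULL,
                               noise = list(speckle_scale = 0.5, snr_db = Inf),
                               seed = 1L) {
  stopifnot(slice_axis == 3L)           # elevation-stacked slices only
  hu <- phantom$hu; truth <- phantom$truth
  sp <- hu$spacing_mm
  if (is.null(slice_spacing_mm)) slice_spacing_mm <- sp[3]
  if (slice_spacing_mm < max(sp[1:2]) - 1e-9)
    stop("slice spacing must be >= the in-plane spacing")
  step <- round(slice_spacing_mm / sp[3])
  if (abs(step * sp[3] - slice_spacing_mm) > 1e-6)
    stop("slice spacing must be an integer multiple of the grid spacing")
  keep <- seq(1, dim(hu$values)[3], by = step)
  speckle_scale <- if (is.null(noise$speckle_scale)) 0.5 else noise$speckle_scale
  snr_db <- if (is.null(noise$snr_db)) Inf else noise$snr_db
  n1 <- dim(hu$values)[1]; n2 <- dim(hu$values)[2]
  slices <- array(0, c(n1, n2, length(keep)))
  gt <- array(FALSE, c(n1, n2, length(keep)))
  render <- function() {
    for (s in seq_along(keep)) {
      m <- truth$slice_masks[[keep[s]]]
      img <- ifelse(m, 1, 0.05)
      if (is.finite(snr_db)) {
        sigma_r <- sqrt(2 / pi)         # unit-mean Rayleigh
        ray <- sigma_r * sqrt(-2 * log(stats::runif(length(img))))
        img <- img * ((1 - speckle_scale) + speckle_scale * ray)
        img <- img + stats::rnorm(length(img), sd = 10^(-snr_db / 20))
        img[img < 0] <- 0
      }
      img <- img / max(img)
      slices[, , s] <<- img
      gt[, , s] <<- m
    }
  }
  with_seed(seed, render)
  stack <- structure(list(slices = slices, in_plane_spacing_mm = sp[1:2],
                          slice_spacing_mm = slice_spacing_mm,
                          slice_axis = slice_axis,
                          origin_mm = c(0, 0, 0)),
                     class = "bmode_stack")
  list(stack = stack, gt_masks = gt)
}

#' Synthesize diverging-wave channel data from point scatterers
#'
#' Straight-ray time-of-flight echo model for a phased array transmitting
#' tilted diverging waves: the virtual source sits behind the sub-aperture
#' centre, the echo from each scatterer arrives at each element after the
#' transmit delay (relative to the wave crossing the array centre) plus the
#' return path, with 1/r amplitude decay on both legs. Each echo is
#' `polarity * fundamental + polarity^2 * harmonic_fraction * second
#' harmonic`, so summing opposite-polarity events cancels the fundamental
#' (pulse inversion). Events are every tilt at every polarity.
#'
#' @param scatterers n x 2 matrix of (depth, lateral) positions, mm; depths
#'   must be within `depth_mm`.
#' @param amplitudes scatterer amplitudes (recycled).
#' @param array an [array_geometry()].
#' @param pulse list with `f_tx_hz` (default 2 MHz) and `n_cycles`
#'   (default 2).
#' @param tilts_deg transmit tilt angles, degrees, within [-30, 30].
#' @param polarities polarity set per tilt (default `c(1, -1)`).
#' @param harmonic_fraction second-harmonic amplitude relative to the
#'   fundamental (models harmonic generation at the scatterer).
#' @param fs_hz sampling rate (default 8 x transmit frequency).
#' @param c_m_s sound speed.
#' @param depth_mm imaging depth (default 110 mm).
#' @param noise_db additive Gaussian noise level re the strongest echo
#'   (Inf = none).
#' @param seed RNG seed for the noise.
#' @return object of class `channel_data`: `rf` array (samples x elements
#'   x events), `fs_hz`, `tilt_deg`/`polarity`/`virtual_source_mm` per
#'   event, pulse and medium metadata.
#' @export
synth_channel_data <- function(scatterers, amplitudes = 1, array,
                               pulse = list(f_tx_hz = 2e6, n_cycles = 2),
                               tilts_deg = 0, polarities = c(1, -1),
                               harmonic_fraction = 0, fs_hz = NULL,
                               c_m_s = water_constants()$c_m_s,
                               depth_mm = 110, noise_db = Inf, seed = 1L) {
  scatterers <- matrix(scatterers, ncol = 2)
  if (nrow(scatterers) > 0 && any(scatterers[, 1] > depth_mm))
    stop("scatterers must lie within the imaging depth")
  if (any(abs(tilts_deg) > 30)) stop("tilts must be within [-30, 30] degrees")
  stopifnot(all(polarities %in% c(-1, 1)))
  f <- pulse$f_tx_hz
  if (is.null(fs_hz)) fs_hz <- 8 * f
  amplitudes <- rep_len(amplitudes, max(nrow(scatterers), 1L))
  ev <- expand.grid(polarity = polarities, tilt = tilts_deg)
  L <- array$sub_aperture_mm / 2
  Tburst <- pulse$n_cycles / f
  n_t <- ceiling((2 * depth_mm * 1e-3 / c_m_s + Tburst) * fs_hz) + 16L
  ne <- array$n_elements
  rf <- array(0, c(n_t, ne, nrow(ev)))
  vs_all <- matrix(0, nrow(ev), 2)
  tt <- (seq_len(n_t) - 1) / fs_hz
  burst <- function(tau, freq) {
    out <- numeric(length(tau))
    w <- tau >= 0 & tau <= Tburst
    out[w] <- sin(2 * pi * freq * tau[w]) * sin(pi * tau[w] / Tburst)^2
    out
  }
  fill <- function() {
    for (e in seq_len(nrow(ev))) {
      th <- ev$tilt[e] * pi / 180
      dvec <- c(cos(th), sin(th))
      vs <- -L * dvec                   # (depth, lateral) mm
      vs_all[e, ] <<- vs
      pol <- ev$polarity[e]
      if (nrow(scatterers) > 0) {
        for (s in seq_len(nrow(scatterers))) {
          sc <- scatterers[s, ]
          r_tx <- sqrt(sum((sc - vs)^2))
          t_tx <- (r_tx - L) * 1e-3 / c_m_s
          for (el in seq_len(ne)) {
            epos <- c(0, array$element_positions_mm[el])
            r_rx <- sqrt(sum((sc - epos)^2))
            t_arr <- t_tx + r_rx * 1e-3 / c_m_s
            amp <- amplitudes[s] / ((max(r_tx, 1) / 50) * (max(r_rx, 1) / 50))
            tau <- tt - t_arr
            sig <- pol * burst(tau, f) +
              harmonic_fraction * burst(tau, 2 * f)
            rf[, el, e] <<- rf[, el, e] + amp * sig
          }
        }
      }
      if (is.finite(noise_db)) {
        ref <- max(abs(rf[, , e]), 1e-12)
        rf[, , e] <<- rf[, , e] +
          stats::rnorm(n_t * ne, sd = ref * 10^(-noise_db / 20))
      }
    }
  }
  with_seed(seed, fill)
  structure(list(rf = rf, fs_hz = fs_hz, tilt_deg = ev$tilt,
                 polarity = ev$polarity, virtual_source_mm = vs_all,
                 f_tx_hz = f, n_cycles = pulse$n_cycles, c_m_s = c_m_s,
                 depth_mm = depth_mm,
                 sub_aperture_mm = array$sub_aperture_mm),
            class = "channel_data")
}

#' Write channel data as a binary container with a JSON sidecar
#'
#' The RF samples go to `<path>.bin` (little-endian float32, column-major
#' samples x elements x events); acquisition metadata (element positions,
#' sample rate, tilt list, polarities, virtual sources, pulse and medium
#' parameters, array shape) goes to `<path>.json`.
#'
#' @param data a `channel_data` object.
#' @param array the [array_geometry()] used to synthesize it.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_channel_data <- function(data, array, path) {
  stopifnot(inherits(data, "channel_data"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(data$rf), con, size = 4, endian = "little")
  close(con)
  meta <- list(shape = dim(data$rf), sample_rate_hz = data$fs_hz,
               element_positions_mm = array$element_positions_mm,
               tilt_deg = data$tilt_deg, polarity = data$polarity,
               virtual_source_mm = data$virtual_source_mm,
               f_tx_hz = data$f_tx_hz, n_cycles = data$n_cycles,
               c_m_s = data$c_m_s, depth_mm = data$depth_mm,
               sub_aperture_mm = data$sub_aperture_mm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read channel data written by [write_channel_data()]
#'
#' @param path path without extension.
#' @return a `channel_data` object (float32 precision).
#' @export
read_channel_data <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  rf <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  structure(list(rf = array(rf, meta$shape), fs_hz = meta$sample_rate_hz,
                 tilt_deg = meta$tilt_deg, polarity = meta$polarity,
                 virtual_source_mm = matrix(meta$virtual_source_mm,
                                            ncol = 2),
                 f_tx_hz = meta$f_tx_hz, n_cycles = meta$n_cycles,
                 c_m_s = meta$c_m_s, depth_mm = meta$depth_mm,
                 sub_aperture_mm = meta$sub_aperture_mm),
            class = "channel_data")
}
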