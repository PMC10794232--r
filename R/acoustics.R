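#' Power-law absorption description
#'
#' Acoustic absorption in soft tissue and bone is conventionally written as
#' \eqn{\alpha = \alpha_0 f^y} with \eqn{\alpha} in dB/cm, \eqn{\alpha_0} in
#' dB/cm/MHz^y and \eqn{f} in MHz. The solver in this package uses a fixed
#' exponent \eqn{y = 2} across the whole grid (a k-space scheme cannot vary
#' the exponent spatially and the simulations are single-frequency), so a
#' literature value quoted at a different exponent is re-expressed at
#' \eqn{y' = 2} with [refit_alpha0()].
#'
#' @param alpha0 absorption coefficient, dB/cm/MHz^y; must be >= 0.
#' @param y power-law exponent (dimensionless).
#' @return an object of class `absorption_law`.
#' @examples
#' law <- absorption_law(2.7, 1)
#' absorption_at(law, 0.25)  # 0.675 dB/cm
#' @export
absorption_law <- function(alpha0, y) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1L, is.finite(alpha0),
            is.numeric(y), length(y) == 1L, is.finite(y))
  if (alpha0 < 0) stop("alpha0 must be non-negative")
  structure(list(alpha0 = alpha0, y = y), class = "absorption_law")
}

#' @export
print.absorption_law <- function(x, ...) {
  cat(sprintf("<absorption_law> alpha = %g * f^%g dB/cm (f in MHz)\n",
              x$alpha0, x$y))
  invisible(x)
}

#' Evaluate a power-law absorption at a frequency
#'
#' @param law an [absorption_law()].
#' @param f_mhz frequency in MHz, > 0.
#' @return absorption in dB/cm.
#' @export
absorption_at <- function(law, f_mhz) {
  stopifnot(inherits(law, "absorption_law"), is.numeric(f_mhz))
  if (any(f_mhz <= 0)) stop("frequency must be positive")
  law$alpha0 * f_mhz^law$y
}

#' Re-express an absorption value at a new power-law exponent
#'
#' Given a target absorption (dB/cm) at a working frequency, returns the law
#' with exponent `y_new` that reproduces that absorption exactly at that
#' frequency: \eqn{\alpha_{0,new} = \alpha / f^{y'}}.
#'
#' @param alpha_target_db_cm absorption to match, dB/cm.
#' @param f_mhz working frequency, MHz, > 0.
#' @param y_new new exponent (the solver requires 2).
#' @return an [absorption_law()] with `absorption_at(law, f_mhz) ==
#'   alpha_target_db_cm` to machine precision.
#' @examples
#' refit_alpha0(0.675, 0.25, 2)  # alpha0 = 10.8 dB/cm/MHz^2
#' @export
refit_alpha0 <- function(alpha_target_db_cm, f_mhz, y_new) {
  stopifnot(is.numeric(alpha_target_db_cm), is.numeric(f_mhz),
            is.numeric(y_new))
  if (f_mhz <= 0) stop("frequency must be positive")
  if (alpha_target_db_cm < 0) stop("target absorption must be non-negative")
  absorption_law(alpha_target_db_cm / f_mhz^y_new, y_new)
}

#' Hounsfield-unit volume container
#'
#' @param values 1D/2D/3D numeric array of Hounsfield units.
#' @param spacing_mm voxel spacing per axis, mm, strictly positive.
#' @param origin_mm world coordinate of the first voxel centre, mm.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(values, spacing_mm, origin_mm = rep(0, length(spacing_mm))) {
  values <- as.array(values)
  nd <- length(dim(values))
  stopifnot(nd >= 1L, nd <= 3L, length(values) > 0L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  stopifnot(length(spacing_mm) == nd, all(spacing_mm > 0))
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == nd, all(is.finite(origin_mm)))
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("<hu_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# Water reference constants used across the package. The source experiments
# never print them; these are standard degassed-water values near 20 C.
#' Default water acoustic constants
#' @return list with `c_m_s` (1482 m/s) and `rho_kg_m3` (1000 kg/m^3).
#' @export
water_constants <- function() list(c_m_s = 1482, rho_kg_m3 = 1000)

#' Default Hounsfield-to-acoustic-property node table
#'
#' Piecewise-linear nodes mapping HU to density (kg/m^3) and sound speed
#' (m/s). The top node is chosen so the maximum sound speed is 2.66 times
#' that of water (1482 m/s), the ratio that governs the skull-side grid
#' resolution. The table ships as plain text in `inst/extdata/hu_nodes.tsv`
#' and can be replaced wholesale by the user.
#'
#' @param path optional path to an alternative whitespace-separated node
#'   file with columns `hu`, `density_kg_m3`, `sound_speed_m_s`.
#' @return data.frame of nodes, strictly increasing in HU.
#' @export
hu_node_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hu_nodes.tsv", package = "fusmap",
                        mustWork = TRUE)
  }
  nodes <- utils::read.table(path, header = TRUE)
  need <- c("hu", "density_kg_m3", "sound_speed_m_s")
  if (!all(need %in% names(nodes))) {
    stop("node table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.unsorted(nodes$hu, strictly = TRUE)) {
    stop("node table HU values must be strictly increasing")
  }
  nodes
}

#' Heterogeneous acoustic medium container
#'
#' Co-registered density, sound-speed and absorption-coefficient maps plus a
#' single power-law exponent shared by the whole grid.
#'
#' @param density kg/m^3 array.
#' @param sound_speed m/s array, same shape.
#' @param alpha0_map dB/cm/MHz^y array, same shape (default all zero).
#' @param y shared power-law exponent (default 2).
#' @param spacing_mm voxel spacing, mm.
#' @param origin_mm world coordinate of first voxel centre.
#' @return object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(density, sound_speed, alpha0_map = NULL, y = 2,
                            spacing_mm, origin_mm = rep(0, length(spacing_mm))) {
  density <- as.array(density); sound_speed <- as.array(sound_speed)
  stopifnot(identical(dim(density), dim(sound_speed)))
  if (is.null(alpha0_map)) alpha0_map <- array(0, dim(density))
  alpha0_map <- as.array(alpha0_map)
  stopifnot(identical(dim(density), dim(alpha0_map)))
  if (any(!is.finite(density)) || any(!is.finite(sound_speed)))
    stop("medium maps must be finite")
  if (any(density < 900)) stop("density below physical water floor (900 kg/m^3)")
  if (any(sound_speed < 1400)) stop("sound speed below water floor (1400 m/s)")
  nd <- length(dim(density))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  stopifnot(length(spacing_mm) == nd, all(spacing_mm > 0))
  structure(list(density = density, sound_speed = sound_speed,
                 alpha0_map = alpha0_map, y = y, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf(
    "<acoustic_medium> %s voxels | c: %.0f-%.0f m/s | rho: %.0f-%.0f kg/m^3 | alpha0 max %.2f (y = %g)\n",
    paste(dim(x$density), collapse = "x"),
    min(x$sound_speed), max(x$sound_speed),
    min(x$density), max(x$density), max(x$alpha0_map), x$y))
  invisible(x)
}

#' Convert a Hounsfield-unit volume to an acoustic medium
#'
#' Per-voxel piecewise-linear interpolation between the nodes of
#' [hu_node_table()]; values outside the node range are clamped to the end
#' nodes, so any sub-water HU maps to water and any HU above the top node to
#' the densest bone in the table. The map is monotone non-decreasing in HU.
#'
#' @param hu an [hu_volume()].
#' @param nodes node table as from [hu_node_table()].
#' @param water water constants, see [water_constants()].
#' @param y power-law exponent recorded on the medium (default 2).
#' @return an [acoustic_medium()] with a zero absorption map (fill it with
#'   [heterogeneous_alpha_map()]).
#' @export
hu_to_medium <- function(hu, nodes = hu_node_table(),
                         water = water_constants(), y = 2) {
  stopifnot(inherits(hu, "hu_volume"))
  if (is.unsorted(nodes$hu, strictly = TRUE))
    stop("node table HU values must be strictly increasing")
  v <- hu$values
  dens <- stats::approx(nodes$hu, nodes$density_kg_m3, xout = as.vector(v),
                        rule = 2)$y
  spd <- stats::approx(nodes$hu, nodes$sound_speed_m_s, xout = as.vector(v),
                       rule = 2)$y
  acoustic_medium(array(dens, dim(v)), array(spd, dim(v)), y = y,
                  spacing_mm = hu$spacing_mm, origin_mm = hu$origin_mm)
}

#' Fill the absorption-coefficient map of a medium
#'
#' The skull absorption map is heterogeneous: each voxel's alpha0 is
#' interpolated between the water value and the maximum bone value in
#' proportion to its normalized bone fraction, taken as
#' (rho - rho_water)/(rho_max - rho_water) clipped to [0, 1]. A voxel at the
#' maximum density of the map therefore carries exactly `alpha0_bone_max`.
#' A degenerate all-water volume gets a uniform water map.
#'
#' @param medium an [acoustic_medium()].
#' @param alpha0_water water alpha0, dB/cm/MHz^y.
#' @param alpha0_bone_max maximum bone alpha0, dB/cm/MHz^y; must be >=
#'   `alpha0_water`.
#' @param rho_water water density used as the bone-fraction floor.
#' @return the medium with `alpha0_map` replaced.
#' @export
heterogeneous_alpha_map <- function(medium, alpha0_water, alpha0_bone_max,
                                    rho_water = water_constants()$rho_kg_m3) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (alpha0_bone_max < alpha0_water)
    stop("alpha0_bone_max must be >= alpha0_water")
  rho <- medium$density
  rho_max <- max(rho)
  if (rho_max <= rho_water) {
    frac <- array(0, dim(rho))
  } else {
    frac <- (rho - rho_water) / (rho_max - rho_water)
    frac[frac < 0] <- 0
    frac[frac > 1] <- 1
  }
  medium$alpha0_map <- alpha0_water + (alpha0_bone_max - alpha0_water) * frac
  medium
}

#' Construct a homogeneous medium
#'
#' Convenience wrapper for free-field (water) or single-material runs.
#'
#' @param shape integer vector of grid dimensions (length 1, 2 or 3).
#' @param spacing_mm voxel spacing.
#' @param c_m_s sound speed, m/s.
#' @param rho_kg_m3 density, kg/m^3.
#' @param alpha0 uniform absorption coefficient, dB/cm/MHz^y.
#' @param y exponent.
#' @param origin_mm origin.
#' @return an [acoustic_medium()].
#' @export
homogeneous_medium <- function(shape, spacing_mm,
                               c_m_s = water_constants()$c_m_s,
                               rho_kg_m3 = water_constants()$rho_kg_m3,
                               alpha0 = 0, y = 2,
                               origin_mm = rep(0, length(shape))) {
  shape <- as.integer(shape)
  acoustic_medium(array(rho_kg_m3, shape), array(c_m_s, shape),
                  array(alpha0, shape), y = y, spacing_mm = spacing_mm,
                  origin_mm = origin_mm)
}
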