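#' Focal peak inside a cube-shaped region of interest
#'
#' Finds the maximum of a peak-pressure field within an axis-aligned cube
#' and refines its location to subvoxel precision with a separable
#' three-point quadratic interpolation around the argmax. Ties break to the
#' lowest linear index (column-major order).
#'
#' @param field a [pressure_field()].
#' @param roi list with `center_mm` and `half_width_mm` (scalar or per-axis).
#' @return list with `p_peak` (interpolated), `p_voxel` (raw voxel max),
#'   `location_mm` (subvoxel), `index` (voxel subscripts).
#' @export
focal_peak_in_roi <- function(field, roi) {
  stopifnot(inherits(field, "pressure_field"))
  v <- field$max_pressure
  dims <- dim(v); if (is.null(dims)) dims <- length(v)
  d <- length(dims)
  ctr <- roi$center_mm
  hw <- roi$half_width_mm
  if (length(hw) == 1L) hw <- rep(hw, d)
  lo <- hi <- integer(d)
  for (j in seq_len(d)) {
    cj <- axis_coords(dims[j], field$spacing_mm[j], field$origin_mm[j])
    sel <- which(cj >= ctr[j] - hw[j] & cj <= ctr[j] + hw[j])
    if (length(sel) == 0L) stop("ROI lies outside the field along axis ", j)
    lo[j] <- min(sel); hi[j] <- max(sel)
  }
  idx_list <- lapply(seq_len(d), function(j) lo[j]:hi[j])
  sub <- do.call(`[`, c(list(v), idx_list, list(drop = FALSE)))
  imax <- which.max(sub)                      # first max in column-major order
  subs <- arrayInd(imax, dim(sub))[1, ] + lo - 1L
  loc <- numeric(d)
  pk <- v[matrix(subs, 1)]
  p_interp <- pk
  for (j in seq_len(d)) {
    i <- subs[j]
    delta <- 0
    if (i > 1L && i < dims[j]) {
      gj <- function(ii) { s <- subs; s[j] <- ii; v[matrix(s, 1)] }
      fm <- gj(i - 1L); f0 <- pk; fp <- gj(i + 1L)
      denom <- fm - 2 * f0 + fp
      if (denom < 0) {
        delta <- 0.5 * (fm - fp) / denom
        delta <- max(min(delta, 0.5), -0.5)
        p_interp <- max(p_interp, f0 - 0.25 * (fm - fp) * delta)
      }
    }
    loc[j] <- field$origin_mm[j] + (i - 1 + delta) * field$spacing_mm[j]
  }
  list(p_peak = p_interp, p_voxel = pk, location_mm = loc, index = subs)
}

#' Transcranial attenuation in percent of the free-field focal pressure
#'
#' @param p_ff free-field focal peak pressure (> 0).
#' @param p_skull transcranial focal peak pressure (>= 0).
#' @return 100 * (p_ff - p_skull) / p_ff.
#' @examples
#' attenuation_pct(1.0, 0.53)  # 47
#' @export
attenuation_pct <- function(p_ff, p_skull) {
  if (any(p_ff <= 0)) stop("free-field pressure must be positive")
  if (any(p_skull < 0)) stop("transcranial pressure must be nonnegative")
  100 * (p_ff - p_skull) / p_ff
}

#' Full width at half maximum along a line through a field
#'
#' Samples the field along the given line (multi-linear interpolation, step
#' = spacing/4), locates the profile maximum, and measures the width of the
#' contiguous above-half-maximum region containing that peak, with linear
#' interpolation at the two half-maximum crossings. If the profile never
#' falls below half maximum on either side before leaving the field, the
#' profile is truncated and an error is raised.
#'
#' @param field a [pressure_field()] (or list with `max_pressure`,
#'   `spacing_mm`, `origin_mm`).
#' @param point_mm a point on the line (the peak must lie on the line).
#' @param direction line direction (normalized internally).
#' @return width in mm.
#' @export
fwhm_along <- function(field, point_mm, direction) {
  v <- field$max_pressure
  dims <- dim(v); if (is.null(dims)) dims <- length(v)
  d <- length(dims)
  u <- unit_vec(as.numeric(direction)[seq_len(d)])
  step <- min(field$spacing_mm) / 4
  # parametric extent of the line inside the bounding box
  tmin <- -Inf; tmax <- Inf
  for (j in seq_len(d)) {
    lo <- field$origin_mm[j]
    hi <- field$origin_mm[j] + (dims[j] - 1) * field$spacing_mm[j]
    if (abs(u[j]) < 1e-12) {
      if (point_mm[j] < lo || point_mm[j] > hi)
        stop("line does not pass through the field")
    } else {
      t1 <- (lo - point_mm[j]) / u[j]; t2 <- (hi - point_mm[j]) / u[j]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) stop("line does not intersect the field")
  ts <- seq(tmin, tmax, by = step)
  pts <- outer(ts, u) + matrix(point_mm[seq_len(d)], length(ts), d, byrow = TRUE)
  prof <- interp_nd(v, field$spacing_mm, field$origin_mm, pts, outside = NA)
  ok <- !is.na(prof)
  prof <- prof[ok]; ts <- ts[ok]
  if (length(prof) < 3L) stop("profile too short")
  ipk <- which.max(prof)
  half <- prof[ipk] / 2
  above <- prof >= half
  # contiguous run containing the peak
  i0 <- ipk; while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
  i1 <- ipk; while (i1 < length(prof) && above[i1 + 1L]) i1 <- i1 + 1L
  if (i0 == 1L || i1 == length(prof))
    stop("profile truncated: field never falls below half maximum")
  # linear interpolation at the crossings
  tL <- ts[i0 - 1L] + (half - prof[i0 - 1L]) / (prof[i0] - prof[i0 - 1L]) *
    (ts[i0] - ts[i0 - 1L])
  tR <- ts[i1] + (half - prof[i1]) / (prof[i1 + 1L] - prof[i1]) *
    (ts[i1 + 1L] - ts[i1])
  tR - tL
}

#' Axial and lateral focal shift relative to a reference field
#'
#' Decomposes the displacement of the focal peak into the signed component
#' along the transducer axis (positive = beyond the nominal focus, away
#' from the transducer) and the nonnegative orthogonal (lateral) magnitude.
#'
#' @param metrics list with `peak_location_mm` (e.g. [focal_peak_in_roi()]).
#' @param reference same, for the free-field reference.
#' @param axis transducer axis (unit vector).
#' @return list with `axial_mm` (signed) and `lateral_mm` (>= 0).
#' @export
focal_shift <- function(metrics, reference, axis) {
  a <- unit_vec(as.numeric(axis))
  loc <- function(m) {
    out <- m$peak_location_mm %||% m$location_mm
    if (is.null(out)) stop("no peak location in metrics")
    out
  }
  delta <- loc(metrics) - loc(reference)
  axial <- sum(delta * a)
  lat2 <- max(sum(delta^2) - axial^2, 0)
  list(axial_mm = axial, lateral_mm = sqrt(lat2))
}

#' One incidence-angle / attenuation observation
#'
#' @param incidence_deg estimated incidence angle, degrees.
#' @param p_ff free-field focal pressure.
#' @param p_skull transcranial focal pressure.
#' @param config_id label for the configuration (tilt id etc.).
#' @return one-row data.frame.
#' @export
attenuation_record <- function(incidence_deg, p_ff, p_skull, config_id = "") {
  data.frame(config_id = config_id, incidence_deg = incidence_deg,
             p_ff_pa = p_ff, p_skull_pa = p_skull,
             attenuation_pct = attenuation_pct(p_ff, p_skull),
             stringsAsFactors = FALSE)
}

#' Linear fit of attenuation on incidence angle
#'
#' Ordinary least squares of attenuation (percent) on incidence angle
#' (degrees). As the incidence angle approaches 90 degrees (normal
#' incidence) the attenuation decreases, so the expected slope is negative.
#'
#' @param records data.frame with columns `incidence_deg` and
#'   `attenuation_pct` (e.g. rows from [attenuation_record()]).
#' @return list with `slope` (percent/degree), `intercept`, `r_squared`,
#'   `n`.
#' @export
fit_angle_attenuation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("incidence_deg", "attenuation_pct") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 records")
  if (length(unique(records$incidence_deg)) < 2L)
    stop("incidence angles are constant; no fit possible")
  fit <- stats::lm(attenuation_pct ~ incidence_deg, data = records)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((records$attenuation_pct - mean(records$attenuation_pct))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       n = nrow(records))
}
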