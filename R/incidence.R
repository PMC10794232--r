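#' Outer skull surface seen from the transducer side
#'
#' For every voxel column parallel to the view direction (the beam axis,
#' grid axis 1), the first mask-entry crossing is located with subvoxel
#' (half-voxel midpoint) interpolation; columns containing no bone are
#' skipped. Only the entry surface matters: it is the surface the focused
#' beam sonicates.
#'
#' @param mask a [skull_mask()] (nonempty).
#' @param view_axis grid axis of the view direction (default 1).
#' @return `surface_points`: an n x 3 matrix of mm coordinates.
#' @export
outer_surface <- function(mask, view_axis = 1L) {
  stopifnot(inherits(mask, "skull_mask"))
  if (mask$n_voxels == 0L) stop("empty mask has no surface")
  d <- dim(mask$mask)
  lat <- setdiff(1:3, view_axis)
  pts <- matrix(NA_real_, 0, 3)
  rows <- list()
  for (k in seq_len(d[lat[2]])) {
    sl <- switch(view_axis,
                 mask$mask[, , k],
                 stop("view_axis must be 1 in this release"))
    # first TRUE per column of the axial x lateral slice
    first <- apply(sl, 2, function(col) {
      w <- which(col); if (length(w)) w[1] else NA_integer_
    })
    j <- which(!is.na(first))
    if (!length(j)) next
    i <- first[j]
    # boundary midway between the last empty and first filled voxel
    x <- mask$origin_mm[1] + (i - 1 - 0.5) * mask$spacing_mm[1]
    x[i == 1L] <- mask$origin_mm[1]     # surface at the grid face
    rows[[length(rows) + 1L]] <- cbind(
      x,
      mask$origin_mm[2] + (j - 1) * mask$spacing_mm[2],
      mask$origin_mm[3] + (k - 1) * mask$spacing_mm[3])
  }
  if (!length(rows)) stop("empty mask has no surface")
  out <- do.call(rbind, rows)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Restrict surface points to the focusing-cone footprint
#'
#' The focused beam converges from the outer-diameter aperture rim to the
#' geometric focus; at axial depth z from the aperture plane the cone
#' radius is r(z) = (OD/2) (F - z)/F. Surface points outside that radius
#' (or beyond the focus) are dropped. The central-hole shadow is not
#' excluded: the footprint is the full cone cross-section.
#'
#' @param geom a [transducer_geometry()] (apex and axis in the same world
#'   frame as the points).
#' @param surface_points n x 3 matrix from [outer_surface()].
#' @return the retained points (>= 3 required).
#' @export
cone_footprint <- function(geom, surface_points) {
  stopifnot(inherits(geom, "transducer_geometry"))
  pts <- matrix(surface_points, ncol = 3)
  a <- geom$axis
  rel <- sweep(pts, 2, geom$apex_mm)
  z <- as.vector(rel %*% a)
  lat <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  f <- geom$focal_distance_mm
  rmax <- (geom$outer_diameter_mm / 2) * (f - z) / f
  keep <- z >= 0 & z < f & lat <= rmax
  out <- pts[keep, , drop = FALSE]
  if (nrow(out) < 3L)
    stop(sprintf(
      "only %d surface points fall inside the focusing cone; scan a larger region or move the transducer back",
      nrow(out)))
  out
}

#' Total-least-squares plane fit of surface points
#'
#' The plane normal is the direction of least variance of the centred
#' points (smallest principal component); its sign is flipped to point
#' toward the transducer (against the propagation axis). The RMS
#' point-to-plane residual is reported.
#'
#' @param points n x 3 matrix of mm coordinates, n >= 3, non-collinear.
#' @param axis propagation axis used for the orientation convention.
#' @return list (class `plane_fit`) with `centroid_mm`, `normal`,
#'   `rms_residual_mm`.
#' @export
fit_plane <- function(points, axis = c(1, 0, 0)) {
  pts <- matrix(points, ncol = 3)
  if (nrow(pts) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-10)
    stop("points are collinear or coincident; the plane is degenerate")
  n <- sv$v[, 3]
  if (sum(n * axis) > 0) n <- -n        # orient toward the transducer
  rms <- sqrt(mean((X %*% n)^2))
  structure(list(centroid_mm = ctr, normal = n, rms_residual_mm = rms),
            class = "plane_fit")
}

#' Incidence angle from a fitted skull plane
#'
#' The auxiliary angle alpha is the angle between the fitted plane normal
#' and the propagation direction (absolute dot product, so the result does
#' not depend on normal orientation); the incidence angle is 90 deg -
#' alpha. 90 deg means normal incidence.
#'
#' @param fit a `plane_fit` (or any list with a `normal` field, or a bare
#'   3-vector).
#' @param axis unit propagation direction.
#' @return list (class `incidence_result`) with `alpha_aux_deg`,
#'   `incidence_deg`, `footprint_size` (when known).
#' @export
incidence_angle <- function(fit, axis = c(1, 0, 0)) {
  n <- if (is.numeric(fit)) fit else fit$normal
  n <- unit_vec(as.numeric(n))
  a <- unit_vec(as.numeric(axis))
  alpha <- acos(min(abs(sum(n * a)), 1)) * 180 / pi
  structure(list(alpha_aux_deg = alpha, incidence_deg = 90 - alpha,
                 footprint_size = NA_integer_),
            class = "incidence_result")
}

#' Full incidence-angle pipeline on a skull mask
#'
#' Outer surface extraction, cone-footprint restriction, plane fit and
#' angle computation in one call.
#'
#' @param mask a [skull_mask()].
#' @param geom a [transducer_geometry()].
#' @return an `incidence_result` with the `plane_fit` attached as `fit`.
#' @export
estimate_incidence <- function(mask, geom) {
  surf <- outer_surface(mask)
  fp <- cone_footprint(geom, surf)
  fit <- fit_plane(fp, axis = geom$axis)
  res <- incidence_angle(fit, axis = geom$axis)
  res$footprint_size <- nrow(fp)
  res$fit <- fit
  res
}
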