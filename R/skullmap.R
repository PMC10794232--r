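#' Binary skull-occupancy volume
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing (possibly anisotropic).
#' @param origin_mm world coordinate of the first voxel centre.
#' @return object of class `skull_mask`.
#' @export
skull_mask <- function(mask, spacing_mm, origin_mm = rep(0, 3)) {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  stopifnot(length(dim(mask)) == 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(all(spacing_mm > 0))
  structure(list(mask = mask, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), n_voxels = sum(mask)),
            class = "skull_mask")
}

#' @export
print.skull_mask <- function(x, ...) {
  cat(sprintf("<skull_mask> %s voxels, %d in mask (%.0f mm^3)\n",
              paste(dim(x$mask), collapse = "x"), x$n_voxels,
              x$n_voxels * prod(x$spacing_mm)))
  invisible(x)
}

# 4-connected component labelling of a logical matrix (iterative flood fill)
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  cur <- 0L
  todo <- which(m & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      q <- queue
      queue <- integer(0)
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (dd in 1:4) {
        rn <- r + c(-1L, 1L, 0L, 0L)[dd]
        cn <- cc + c(0L, 0L, -1L, 1L)[dd]
        ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
        idx <- (cn[ok] - 1L) * nr + rn[ok]
        idx <- idx[m[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

# even-odd ray-casting point-in-polygon test, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Segment the skull band from one normalized B-mode slice
#'
#' Deterministic surrogate for the manual slice-by-slice segmentation:
#' thresholding at 0.19 normalized amplitude, optionally restricted to a
#' polygonal region of interest, with small connected components removed.
#'
#' @param image a `bmode_image` or a numeric matrix in [0, 1].
#' @param method "threshold" or "polygon+threshold".
#' @param threshold binarization threshold on normalized amplitude, in
#'   [0, 1] (default 0.19).
#' @param polygon for the polygon method, an n x 2 matrix of (row, col)
#'   pixel vertices.
#' @param min_component_px connected components smaller than this are
#'   dropped (0 keeps everything).
#' @return logical matrix.
#' @export
segment_slice <- function(image, method = c("threshold", "polygon+threshold"),
                          threshold = 0.19, polygon = NULL,
                          min_component_px = 0L) {
  method <- match.arg(method)
  img <- if (inherits(image, "bmode_image")) image$envelope else image
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1] (normalized amplitude)")
  m <- img >= threshold
  if (method == "polygon+threshold") {
    if (is.null(polygon)) stop("polygon method requires a polygon")
    rc <- expand.grid(r = seq_len(nrow(img)), c = seq_len(ncol(img)))
    inside <- points_in_polygon(rc$r, rc$c, polygon)
    m <- m & matrix(inside, nrow(img), ncol(img))
  }
  if (min_component_px > 0L && any(m)) {
    lab <- label_components(m)
    keep <- which(tabulate(lab) >= min_component_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' Assemble segmented slices into a 3D skull mask
#'
#' @param masks list of logical matrices sharing one shape, ordered along
#'   the slice axis.
#' @param in_plane_spacing_mm length-2 in-plane spacing, mm.
#' @param slice_spacing_mm spacing between slices, mm.
#' @param origin_mm world origin.
#' @return a [skull_mask()] with anisotropic spacing (in-plane, in-plane,
#'   slice).
#' @export
stack_masks <- function(masks, in_plane_spacing_mm = c(0.14, 0.14),
                        slice_spacing_mm = 0.2, origin_mm = rep(0, 3)) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("slice shapes differ")
  vol <- array(FALSE, c(d, length(masks)))
  for (i in seq_along(masks)) vol[, , i] <- masks[[i]]
  skull_mask(vol, c(in_plane_spacing_mm, slice_spacing_mm), origin_mm)
}

#' Binarize a CT or B-mode volume into a skull mask
#'
#' CT volumes threshold at 400 HU (everything below is soft tissue or
#' water); normalized B-mode volumes threshold at 0.19. Idempotent and
#' monotone in the threshold.
#'
#' @param volume an [hu_volume()], a `bmode_stack`, or a 3D array.
#' @param modality "ct" or "bmode"; inferred from the object class when
#'   possible.
#' @param threshold override of the default (400 HU / 0.19).
#' @return a [skull_mask()].
#' @export
binarize <- function(volume, modality = c("ct", "bmode"), threshold = NULL) {
  if (inherits(volume, "hu_volume")) {
    modality <- "ct"
    vals <- volume$values; sp <- volume$spacing_mm; or <- volume$origin_mm
  } else if (inherits(volume, "bmode_stack")) {
    modality <- "bmode"
    vals <- volume$slices
    sp <- c(volume$in_plane_spacing_mm, volume$slice_spacing_mm)
    or <- volume$origin_mm
  } else {
    modality <- match.arg(modality)
    vals <- as.array(volume); sp <- attr(volume, "spacing_mm")
    if (is.null(sp)) sp <- c(1, 1, 1)
    or <- rep(0, 3)
  }
  if (is.null(threshold)) threshold <- if (modality == "ct") 400 else 0.19
  if (modality == "bmode" && (threshold < 0 || threshold > 1))
    stop("B-mode threshold must lie in [0, 1]")
  skull_mask(vals >= threshold, sp, or)
}

#' Rigid transform (rotation + translation)
#'
#' Euler angles are applied about the world axes in the fixed order
#' axis-1, then axis-2, then axis-3 (extrinsic X-Y-Z), rotating about the
#' moving mask's centroid.
#'
#' @param rotation_deg length-3 Euler angles, degrees.
#' @param translation_mm length-3 translation, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3L, length(translation_mm) == 3L)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

rotation_matrix_xyz <- function(deg) {
  r <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

mask_centroid_mm <- function(m) {
  idx <- which(m$mask)
  if (length(idx) == 0L) stop("empty mask")
  sub <- arrayInd(idx, dim(m$mask))
  colMeans(sweep(sweep(sub - 1, 2, m$spacing_mm, "*"), 2, m$origin_mm, "+"))
}

#' Apply a rigid transform to a skull mask
#'
#' Resamples the transformed moving mask onto the grid of `target`
#' (trilinear interpolation, 0.5 threshold). Rotation is about the moving
#' mask's centroid.
#'
#' @param moving a [skull_mask()].
#' @param transform a [rigid_transform()].
#' @param target grid-defining [skull_mask()] (defaults to `moving`).
#' @param soft if TRUE return the continuous interpolated values instead of
#'   a thresholded mask.
#' @return a [skull_mask()] (or numeric array when `soft`).
#' @export
apply_rigid <- function(moving, transform, target = moving, soft = FALSE) {
  R <- rotation_matrix_xyz(transform$rotation_deg)
  ctr <- mask_centroid_mm(moving)
  tr <- transform$translation_mm
  d <- dim(target$mask)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  pts <- cbind(target$origin_mm[1] + (g$i - 1) * target$spacing_mm[1],
               target$origin_mm[2] + (g$j - 1) * target$spacing_mm[2],
               target$origin_mm[3] + (g$k - 1) * target$spacing_mm[3])
  # inverse map: fixed-space point -> moving-space point
  back <- t(t(pts) - (ctr + tr)) %*% R + matrix(ctr, nrow(pts), 3, byrow = TRUE)
  vals <- interp_nd(moving$mask * 1, moving$spacing_mm, moving$origin_mm,
                    back, outside = 0)
  arr <- array(vals, d)
  if (soft) return(arr)
  skull_mask(arr >= 0.5, target$spacing_mm, target$origin_mm)
}

dice_score <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(0)
  2 * sum(a & b) / (sa + sb)
}

#' Rigid registration of two binary skull masks
#'
#' Deterministic surrogate for external rigid-registration tools: the
#' translation is initialized from the centroid offset, a coarse grid over
#' Euler angles is scanned, and the six parameters are refined by
#' derivative-free (Nelder-Mead) maximization of a soft Dice overlap.
#'
#' @param moving,fixed [skull_mask()] objects (nonempty).
#' @param init optional [rigid_transform()] initial guess (overrides the
#'   centroid initialization).
#' @param search list: `rot_range_deg` (coarse scan half-range, default 6),
#'   `rot_step_deg` (default 3), `maxit` for the refinement (default 200).
#' @return list with `transform` (a [rigid_transform()]) and `dice` (final
#'   hard-threshold Dice overlap).
#' @export
rigid_register <- function(moving, fixed, init = NULL,
                           search = list(rot_range_deg = 6, rot_step_deg = 3,
                                         maxit = 200)) {
  stopifnot(inherits(moving, "skull_mask"), inherits(fixed, "skull_mask"))
  if (moving$n_voxels == 0L || fixed$n_voxels == 0L)
    stop("cannot register an empty mask")
  fx <- fixed$mask * 1
  objective <- function(par) {
    tf <- rigid_transform(par[1:3], par[4:6])
    soft <- apply_rigid(moving, tf, target = fixed, soft = TRUE)
    -2 * sum(soft * fx) / (sum(soft) + sum(fx))
  }
  if (is.null(init)) {
    t0 <- mask_centroid_mm(fixed) - mask_centroid_mm(moving)
    rr <- search$rot_range_deg %||% 6
    rs <- search$rot_step_deg %||% 3
    angles <- seq(-rr, rr, by = rs)
    best <- c(0, 0, 0); bestv <- Inf
    for (a1 in angles) for (a2 in angles) for (a3 in angles) {
      v <- objective(c(a1, a2, a3, t0))
      if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
    }
    par0 <- c(best, t0)
  } else {
    par0 <- c(init$rotation_deg, init$translation_mm)
  }
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = search$maxit %||% 200,
                                     reltol = 1e-9))
  # restart from the optimum: a fresh simplex escapes premature collapse
  opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                      control = list(maxit = search$maxit %||% 200,
                                     reltol = 1e-9))
  tf <- rigid_transform(opt$par[1:3], opt$par[4:6])
  hard <- apply_rigid(moving, tf, target = fixed)
  list(transform = tf, dice = dice_score(hard$mask, fixed$mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bone thickness along a probe line
#'
#' Samples the mask along the line (trilinear interpolation at a quarter
#' voxel step) and measures the total in-bone path between the 0.5-level
#' entry and exit crossings, with linear interpolation at each boundary.
#' Disjoint crossings (e.g. two skull tables with a gap) are summed and
#' counted.
#'
#' @param mask a [skull_mask()].
#' @param point_mm a point on the line, mm.
#' @param direction probe direction.
#' @return list with `thickness_mm` (sum of in-bone segment lengths) and
#'   `n_segments`.
#' @export
thickness_along_line <- function(mask, point_mm, direction) {
  stopifnot(inherits(mask, "skull_mask"))
  u <- unit_vec(as.numeric(direction))
  d <- dim(mask$mask)
  step <- min(mask$spacing_mm) / 4
  tmin <- -Inf; tmax <- Inf
  for (j in 1:3) {
    lo <- mask$origin_mm[j]
    hi <- mask$origin_mm[j] + (d[j] - 1) * mask$spacing_mm[j]
    if (abs(u[j]) < 1e-12) {
      if (point_mm[j] < lo || point_mm[j] > hi)
        stop("probe line does not pass through the volume")
    } else {
      t1 <- (lo - point_mm[j]) / u[j]; t2 <- (hi - point_mm[j]) / u[j]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) stop("probe line does not intersect the volume")
  ts <- seq(tmin, tmax, by = step)
  pts <- outer(ts, u) + matrix(point_mm, length(ts), 3, byrow = TRUE)
  prof <- interp_nd(mask$mask * 1, mask$spacing_mm, mask$origin_mm, pts,
                    outside = 0)
  above <- prof >= 0.5
  if (!any(above)) stop("probe line does not intersect the mask")
  # 0.5-level crossings with linear interpolation
  cross_t <- function(i) {
    ts[i] + (0.5 - prof[i]) / (prof[i + 1L] - prof[i]) * step
  }
  total <- 0; nseg <- 0L
  i <- 1L
  n <- length(ts)
  while (i <= n) {
    if (above[i]) {
      t_in <- if (i == 1L) ts[1] else cross_t(i - 1L)
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      t_out <- if (j == n) ts[n] else cross_t(j)
      total <- total + (t_out - t_in)
      nseg <- nseg + 1L
      i <- j + 1L
    }
    i <- i + 1L
  }
  list(thickness_mm = total, n_segments = nseg)
}

#' Mean thickness and bone volume over a circular skull region
#'
#' Probes every voxel column (along one grid axis) whose lateral position
#' lies within `radius_mm` of the centre, averages the per-column
#' thicknesses, and integrates the in-mask voxel volume inside the
#' cylindrical footprint.
#'
#' @param mask a [skull_mask()].
#' @param center_mm centre of the disc in the plane orthogonal to the probe
#'   axis (length-2, in the order of the remaining axes).
#' @param radius_mm disc radius, mm (default 15; 0 probes a single column).
#' @param probe_axis grid axis along which columns run (default 1, the
#'   beam axis).
#' @return list with `mean_thickness_mm`, `volume_mm3`, `n_columns`.
#' @export
disc_metrics <- function(mask, center_mm, radius_mm = 15, probe_axis = 1L) {
  stopifnot(inherits(mask, "skull_mask"))
  d <- dim(mask$mask)
  lat_axes <- setdiff(1:3, probe_axis)
  c1 <- axis_coords(d[lat_axes[1]], mask$spacing_mm[lat_axes[1]],
                    mask$origin_mm[lat_axes[1]])
  c2 <- axis_coords(d[lat_axes[2]], mask$spacing_mm[lat_axes[2]],
                    mask$origin_mm[lat_axes[2]])
  g <- expand.grid(a = seq_along(c1), b = seq_along(c2))
  r2 <- (c1[g$a] - center_mm[1])^2 + (c2[g$b] - center_mm[2])^2
  inside <- r2 <= radius_mm^2
  # radius 0 (or smaller than the voxel) degrades to the nearest column
  if (!any(inside) && min(r2) <= sum(mask$spacing_mm[lat_axes]^2))
    inside[which.min(r2)] <- TRUE
  if (!any(inside)) stop("disc footprint misses the grid")
  dirv <- numeric(3); dirv[probe_axis] <- 1
  th <- c(); vol_count <- 0
  for (idx in which(inside)) {
    pt <- numeric(3)
    pt[lat_axes[1]] <- c1[g$a[idx]]
    pt[lat_axes[2]] <- c2[g$b[idx]]
    pt[probe_axis] <- mask$origin_mm[probe_axis]
    col <- switch(probe_axis,
                  mask$mask[, g$a[idx], g$b[idx]],
                  mask$mask[g$a[idx], , g$b[idx]],
                  mask$mask[g$a[idx], g$b[idx], ])
    vol_count <- vol_count + sum(col)
    if (!any(col)) next
    th <- c(th, thickness_along_line(mask, pt, dirv)$thickness_mm)
  }
  if (length(th) == 0L) stop("disc footprint does not intersect the mask")
  list(mean_thickness_mm = mean(th),
       volume_mm3 = vol_count * prod(mask$spacing_mm),
       n_columns = length(th))
}

#' Euclidean caliper distance between two landmarks
#'
#' @param p1_mm,p2_mm 3D points, mm.
#' @return distance in mm.
#' @export
caliper_distance <- function(p1_mm, p2_mm) {
  sqrt(sum((as.numeric(p1_mm) - as.numeric(p2_mm))^2))
}
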