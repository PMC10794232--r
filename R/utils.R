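# shared low-level helpers (not exported)

# multi-linear interpolation of a 1/2/3D array at world-coordinate points.
# points outside the grid return `outside`.
interp_nd <- function(values, spacing_mm, origin_mm, pts_mm,
                      outside = NA_real_) {
  dims <- dim(values)
  if (is.null(dims)) dims <- length(values)
  d <- length(dims)
  pts <- matrix(pts_mm, ncol = d)
  ci <- sweep(sweep(pts, 2, origin_mm, "-"), 2, spacing_mm, "/") + 1
  valid <- rep(TRUE, nrow(pts))
  for (j in seq_len(d)) valid <- valid & ci[, j] >= 1 & ci[, j] <= dims[j]
  lo <- floor(ci)
  for (j in seq_len(d)) lo[, j] <- pmin(pmax(lo[, j], 1), max(dims[j] - 1, 1))
  fr <- ci - lo
  for (j in seq_len(d)) if (dims[j] == 1L) fr[, j] <- 0
  strides <- cumprod(c(1, dims[-d]))
  base0 <- as.vector((lo - 1) %*% strides) + 1
  nmax <- prod(dims)
  out <- numeric(nrow(pts))
  for (corner in 0:(2^d - 1)) {
    w <- rep(1, nrow(pts)); off <- 0
    for (j in seq_len(d)) {
      bit <- bitwAnd(corner, bitwShiftL(1L, j - 1L)) > 0
      w <- w * if (bit) fr[, j] else (1 - fr[, j])
      if (bit) off <- off + strides[j]
    }
    idx <- pmin(base0 + off, nmax)
    out <- out + w * values[idx]
  }
  out[!valid] <- outside
  out
}

# world coordinates of voxel centres along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector where a direction is required")
  v / n
}
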