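#' Phased-array geometry
#'
#' Defaults describe a 64-element sub-aperture of 20.48 mm (0.32 mm pitch),
#' the excitation aperture used for diverging-wave cranial imaging. The
#' element count, pitch and sampling details of the original acquisitions
#' are not published; these are documented assumptions.
#'
#' @param n_elements number of elements (>= 2).
#' @param pitch_mm element pitch, mm.
#' @param sub_aperture_mm transmit sub-aperture width, mm (sets the virtual
#'   source stand-off distance).
#' @return object of class `array_geometry` with centred
#'   `element_positions_mm`.
#' @export
array_geometry <- function(n_elements = 64L, pitch_mm = 0.32,
                           sub_aperture_mm = 20.48) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 2L, pitch_mm > 0, sub_aperture_mm > 0)
  pos <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch_mm
  structure(list(n_elements = n_elements, pitch_mm = pitch_mm,
                 element_positions_mm = pos,
                 sub_aperture_mm = sub_aperture_mm),
            class = "array_geometry")
}

#' Pulse-inversion harmonic combination
#'
#' Elementwise sum of the echoes from two opposite-polarity transmits: odd
#' (fundamental) components cancel, even harmonics reinforce. Linear and
#' commutative in its arguments.
#'
#' @param rf_pos,rf_neg RF arrays of identical shape (samples x elements,
#'   or any matching shape).
#' @return the summed harmonic RF array.
#' @export
pulse_inversion <- function(rf_pos, rf_neg) {
  if (!identical(dim(rf_pos), dim(rf_neg)) ||
      length(rf_pos) != length(rf_neg))
    stop("RF shapes must match for pulse inversion")
  rf_pos + rf_neg
}

#' Pulse-inversion combination of a full channel-data set
#'
#' Pairs the +1 and -1 polarity events of each tilt and sums them,
#' returning harmonic-only channel data (one event per tilt).
#'
#' @param data a `channel_data` object from [synth_channel_data()].
#' @return a `channel_data` object with `polarity = 0` events.
#' @export
pulse_inversion_events <- function(data) {
  stopifnot(inherits(data, "channel_data"))
  tilts <- unique(data$tilt_deg)
  n_t <- dim(data$rf)[1]; ne <- dim(data$rf)[2]
  rf <- array(0, c(n_t, ne, length(tilts)))
  vs <- matrix(0, length(tilts), 2)
  for (i in seq_along(tilts)) {
    ip <- which(data$tilt_deg == tilts[i] & data$polarity == 1)
    im <- which(data$tilt_deg == tilts[i] & data$polarity == -1)
    if (length(ip) != 1L || length(im) != 1L)
      stop("each tilt needs exactly one +1 and one -1 polarity event")
    rf[, , i] <- pulse_inversion(data$rf[, , ip], data$rf[, , im])
    vs[i, ] <- data$virtual_source_mm[ip, ]
  }
  out <- data
  out$rf <- rf
  out$tilt_deg <- tilts
  out$polarity <- rep(0, length(tilts))
  out$virtual_source_mm <- vs
  out
}

# analytic-signal envelope along the first (axial) dimension of a matrix
hilbert_envelope <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(X * h, inverse = TRUE) / n)
}

#' Delay-and-sum beamforming of tilted diverging waves
#'
#' For each event the per-pixel delay is the diverging-wave transmit time
#' (distance from the virtual source to the pixel, minus the virtual-source
#' stand-off) plus the return time to each element; RF samples are linearly
#' interpolated, coherently summed across elements and events, envelope-
#' detected along depth (analytic-signal magnitude) and normalized to a
#' maximum of 1. Delays falling beyond the recorded traces contribute zero.
#'
#' @param data a `channel_data` object (typically after
#'   [pulse_inversion_events()]).
#' @param array an [array_geometry()].
#' @param image_grid list with `depth_mm` and `lateral_mm` sample vectors.
#' @param c_m_s beamforming sound speed.
#' @return object of class `bmode_image`: `envelope` (depth x lateral, in
#'   [0, 1]), `depth_mm`, `lateral_mm`, `spacing_mm`.
#' @export
das_diverging <- function(data, array, image_grid,
                          c_m_s = data$c_m_s) {
  stopifnot(inherits(data, "channel_data"), inherits(array, "array_geometry"))
  zd <- image_grid$depth_mm; xl <- image_grid$lateral_mm
  if (max(zd) > data$depth_mm)
    stop("image grid exceeds the recorded depth")
  nz <- length(zd); nx <- length(xl)
  fs <- data$fs_hz
  n_t <- dim(data$rf)[1]
  L <- data$sub_aperture_mm / 2
  acc <- matrix(0, nz, nx)
  pz <- matrix(zd, nz, nx)
  px <- matrix(xl, nz, nx, byrow = TRUE)
  for (e in seq_len(dim(data$rf)[3])) {
    vs <- data$virtual_source_mm[e, ]
    t_tx <- (sqrt((pz - vs[1])^2 + (px - vs[2])^2) - L) * 1e-3 / c_m_s
    for (el in seq_len(array$n_elements)) {
      ex <- array$element_positions_mm[el]
      t_rx <- sqrt(pz^2 + (px - ex)^2) * 1e-3 / c_m_s
      si <- (t_tx + t_rx) * fs + 1      # fractional sample index
      i0 <- floor(si)
      w <- si - i0
      ok <- i0 >= 1 & i0 < n_t
      tr <- data$rf[, el, e]
      val <- numeric(length(si))
      val[ok] <- (1 - w[ok]) * tr[i0[ok]] + w[ok] * tr[i0[ok] + 1L]
      acc <- acc + matrix(val, nz, nx)
    }
  }
  env <- hilbert_envelope(acc)
  mx <- max(env)
  if (mx > 0) env <- env / mx
  structure(list(envelope = env, depth_mm = zd, lateral_mm = xl,
                 spacing_mm = c(if (nz > 1) diff(zd[1:2]) else 1,
                                if (nx > 1) diff(xl[1:2]) else 1)),
            class = "bmode_image")
}

#' Log-compress an envelope image for display
#'
#' 20*log10 compression clipped to `dynamic_range_db`, affinely mapped to
#' [0, 1]; monotone in the input. The maximum pixel maps to 1 and a pixel
#' at -`dynamic_range_db` (or below) maps to 0.
#'
#' @param image a `bmode_image` or a nonnegative matrix.
#' @param dynamic_range_db display dynamic range, dB (> 0).
#' @return matrix (or `bmode_image`) in [0, 1].
#' @export
envelope_lognorm <- function(image, dynamic_range_db = 40) {
  if (dynamic_range_db <= 0) stop("dynamic range must be positive")
  env <- if (inherits(image, "bmode_image")) image$envelope else image
  mx <- max(env)
  if (mx <= 0) stop("image is identically zero")
  db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 2)))
  out <- (pmax(db, -dynamic_range_db) + dynamic_range_db) / dynamic_range_db
  if (inherits(image, "bmode_image")) {
    image$envelope <- out
    image
  } else out
}
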