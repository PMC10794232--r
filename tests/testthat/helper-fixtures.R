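# shared fixture builders; everything is generated in code at test time

slab_spec <- function(tilt = c(0, 0), shape = c(48, 40, 40), spacing = 0.5,
                      thickness = 4, hu_bone = 1500, ...) {
  phantom_spec(shape, spacing, "slab", thickness_mm = thickness,
               tilt_deg = tilt, hu_bone = hu_bone, ...)
}

shell_spec <- function(shape = c(64, 72, 72), spacing = 0.5, radius = 25,
                       thickness = 4, hu_bone = 800, ...) {
  phantom_spec(shape, spacing, "spherical_shell", outer_radius_mm = radius,
               thickness_mm = thickness, hu_bone = hu_bone, ...)
}

# transducer geometry scaled to a 70 mm focus, apex placed so the slab's
# outer surface sits `surface_depth` mm down the axis (slab at grid centre)
scaled_geom_for <- function(spec, surface_depth = 40) {
  ctr <- ((spec$grid_shape - 1) * spec$spacing_mm) / 2
  ctr[1] <- spec$apex_depth_frac * (spec$grid_shape[1] - 1) * spec$spacing_mm[1]
  apex <- c(ctr[1] - spec$thickness_mm / 2 - surface_depth, ctr[2], ctr[3])
  scale_geometry(
    transducer_geometry(apex_mm = apex, axis = c(1, 0, 0)), 70 / 110)
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# single-sided amplitude spectrum of a vector
amp_spectrum <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  list(freq = freq, amp = sp)
}
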