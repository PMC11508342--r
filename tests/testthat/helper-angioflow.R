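# small, fast phantom used across tests: 48 px field, short vessel, quick
# transit so the full bolus passes in a few seconds
tiny_spec <- function(frame_rate = 4, noise = FALSE, seed = 1L, ...) {
  stenosis_phantom_spec(
    frame_rate = frame_rate,
    image_size = 48,
    base_velocity = 18,
    sinuosity_amplitude = 5,
    roi_offset_proximal = 8,
    roi_offset_distal = 8,
    roi_radius = 2,
    photon_noise_scale = if (noise) 0.2 else 0,
    readout_noise_sd = if (noise) 5 else 0,
    random_seed = seed,
    ...
  )
}

# constant-value series helper
constant_series <- function(value = 100, n = 6, h = 5, w = 4, fr = 4) {
  frame_series(array(value, c(n, h, w)), fr)
}

# independent windowed-sd oracle: explicit loop, population convention
brute_window_sd <- function(x, L, alignment = "trailing", edge = "truncate") {
  T <- length(x)
  vapply(seq_len(T), function(t) {
    if (alignment == "trailing") {
      lo <- t - L + 1; hi <- t
      if (edge == "shift") { lo <- max(1, lo); hi <- max(hi, L) }
    } else {
      h <- L %/% 2
      lo <- t - h; hi <- t + h
      if (edge == "shift") {
        sh <- max(0, 1 - lo) - max(0, hi - T)
        lo <- lo + sh; hi <- hi + sh
      }
    }
    v <- x[max(1, lo):min(T, hi)]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
}
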