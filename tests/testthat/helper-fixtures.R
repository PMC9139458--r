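# shared fixtures: small acquisition configs and deterministic shapes

small_acq <- function(n_frames = 75, field = c(64L, 64L)) {
  acq_config(n_frames = n_frames, field_size_px = field)
}

# a clean preset without blinking or localization noise
clean_preset <- function(D = 0.02, alpha = 1, v = 0, ...) {
  motion_preset("clean", D_alpha = D, alpha = alpha, v = v,
                blink_off_prob = 0, blink_on_prob = 1, loc_noise_sd_um = 0, ...)
}

# binary disc mask of given radius (px) centred in a square image
disc_mask <- function(size_px, radius_px, center = (size_px + 1) / 2) {
  idx <- seq_len(size_px)
  d2 <- outer((idx - center)^2, (idx - center)^2, "+")
  d2 <= radius_px^2
}

# disc with nr radial rods (protrusions) of given length/width in px
disc_with_rods <- function(size_px, radius_px, nr, rod_len_px, rod_w_px,
                           offset_deg = 10) {
  m <- disc_mask(size_px, radius_px)
  c0 <- (size_px + 1) / 2
  idx <- seq_len(size_px)
  X <- matrix(idx - c0, size_px, size_px, byrow = TRUE)
  Y <- t(X)
  ang <- offset_deg * pi / 180 + 2 * pi * (seq_len(nr) - 1) / nr
  for (a in ang) {
    s <- X * cos(a) + Y * sin(a)
    q <- abs(-X * sin(a) + Y * cos(a))
    m <- m | (s >= radius_px - 1 & s <= radius_px + rod_len_px & q <= rod_w_px / 2)
  }
  m
}
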