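# shared fixtures, built in code at test time

default_layout <- screen_layout()

# a small all-visible grid for fast alignment/metrics tests
tiny_grid <- function(seed = 1L, layout = default_layout) {
  generate_grid(seed, layout,
                occlusion = matrix(TRUE, 5, 2),
                n_cols = 5L, n_rows = 2L, spacing_px = 200)
}

# hand-built gaze data frame in global pixel coordinates
make_gaze <- function(gx, gy, rate_hz = 60, layout = default_layout,
                      valid = TRUE) {
  n <- length(gx)
  sc <- global_to_screen(layout, gx, gy)
  data.frame(t_s = (seq_len(n) - 1) / rate_hz,
             screen_id = sc$screen, x_px = sc$x, y_px = sc$y,
             gx = gx, gy = gy, valid = rep_len(valid, n))
}

# brute-force nearest visible feature on the unrolled pixel canvas
nearest_feature <- function(gx, gy, grid) {
  feats <- grid[grid$visible, , drop = FALSE]
  d <- sqrt((feats$gx - gx)^2 + (feats$gy - gy)^2)
  feats$feature_id[which.min(d)]
}
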