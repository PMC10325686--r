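# Shared fixtures: analytic masks and small phantom configurations.

# Binary annulus (r_in, r_out] about (cy, cx); ang_keep optionally restricts
# to pixels whose angle (visual counterclockwise from image up) falls in the
# half-open interval [a0, a1) (radians, not wrapped).
make_annulus <- function(size = 64, r_in = 10, r_out = 20,
                         cy = (size + 1) / 2, cx = (size + 1) / 2,
                         ang_drop = NULL) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  rad <- sqrt((rows - cy)^2 + (cols - cx)^2)
  m <- (rad > r_in & rad <= r_out) * 1L
  if (!is.null(ang_drop)) {
    ang <- (atan2(-(cols - cx), cy - rows) + 2 * pi) %% (2 * pi)
    rel <- (ang - ang_drop[1]) %% (2 * pi)
    m[rel < (ang_drop[2] - ang_drop[1])] <- 0L
  }
  m
}

# Independent per-pixel angle map (same convention as the package documents:
# 0 = image up, increasing visual-counterclockwise).
angle_map_oracle <- function(size, cy, cx) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  (atan2(-(cols - cx), cy - rows) + 2 * pi) %% (2 * pi)
}

# Small fast phantom for unit tests.
test_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(n_slices = 6L, image_size = 96L, noise_sd = 5, seed = 11L), list(...))
  do.call(phantom_config, args)
}

# 85x85 toy patches: bright centered blob vs flat noise, z-scored.
toy_patch <- function(blob, sd = 0.3) {
  x <- matrix(stats::rnorm(85 * 85, 0, sd), 85, 85)
  if (blob) x[30:50, 30:50] <- x[30:50, 30:50] + 1.5
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

small_arch <- function() {
  arch_config(conv_filters = c(3L, 4L, 5L, 4L), fc_sizes = c(10L, 6L, 1L),
              dropout_rate = 0, input_size = 20L)
}
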