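# Fixture builders shared across test files. Everything is generated in
# code; seeds are fixed per call site.

deg <- pi / 180

# Random smooth tail: small random bends accumulated over segments.
random_tail_theta <- function(seed, n = 9, max_step = 6) {
  set.seed(seed)
  dir0 <- runif(1, -pi / 6, pi / 6)
  dir0 + c(0, cumsum(runif(n - 1, -max_step, max_step) * deg))
}

# Standard tail fixture: renders `theta` and returns frame + params.
tail_fixture <- function(theta, method = "com", start = c(35, 110),
                         seg_len = 14, width = 3, shape = c(220, 220),
                         noise_sigma = 0, seed = NULL) {
  tru <- tail_truth(theta, start_xy = start, seg_len = seg_len,
                    width = width, shape = shape, noise_sigma = noise_sigma)
  fr <- render_tail_frame(tru, seed = seed)
  tp <- tail_params(start_xy = start, tail_length = seg_len * length(theta),
                    tail_dir0 = theta[1], n_segments = length(theta),
                    method = method)
  list(frame = fr, params = tp, truth = tru)
}

# Integer pixel set of a filled rotated ellipse (exact ground truth for the
# moment-based fit).
filled_ellipse_pixels <- function(cx, cy, a, b, phi) {
  r <- ceiling(max(a, b)) + 1
  g <- expand.grid(x = (floor(cx) - r):(ceiling(cx) + r),
                   y = (floor(cy) - r):(ceiling(cy) + r))
  u <- (g$x - cx) * cos(phi) + (g$y - cy) * sin(phi)
  v <- -(g$x - cx) * sin(phi) + (g$y - cy) * cos(phi)
  as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, ])
}

# Background model pre-initialized with a uniform empty-arena frame.
empty_bg <- function(shape, value = 200, time_constant = 20) {
  bg <- background_model(time_constant = time_constant, n_init_frames = 1)
  update_background(bg, new_frame(matrix(value, shape[1], shape[2]),
                                  t = -1 / 300))
}

# Default detection parameters matched to fish_template().
scene_fish_params <- function() {
  fish_params(area_range = c(40, 1000), fg_threshold = 25,
              eye_bladder_threshold = 100, tail_radius = 14)
}

# Brute-force trailing-window population standard deviation.
vigor_oracle <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i >= w) {
      win <- x[(i - w + 1):i]
      out[i] <- sqrt(mean(win^2) - mean(win)^2)
    }
  }
  out
}

# Wrapped absolute angular error in degrees (axial, mod pi).
axial_err_deg <- function(a, b) {
  abs(((a - b + pi / 2) %% pi) - pi / 2) / deg
}

# Wrapped absolute angular error in degrees (full circle).
circ_err_deg <- function(a, b) {
  abs(atan2(sin(a - b), cos(a - b))) / deg
}
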