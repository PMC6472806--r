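# Ground-truth fixture generator. Renders tail, eye and whole-arena scenes
# with exactly known kinematics so every tracker can be validated against
# truth defined by construction. Rendering is anti-aliased with sub-pixel
# positioning (a 1 px linear edge ramp), so recovery tolerances reflect
# algorithm error rather than raster error. All randomness is seeded and the
# caller's RNG state is restored.

#' Tail-scene ground truth
#'
#' @param theta absolute segment angles, radians (must respect the tracker's
#'   `max_bend` constraint between neighbors).
#' @param start_xy tail base (x, y), pixels.
#' @param seg_len segment length, pixels.
#' @param width tail stroke width, pixels.
#' @param intensity peak tail intensity.
#' @param noise_sigma additive Gaussian pixel noise SD.
#' @param shape frame (height, width) in pixels.
#' @param background background intensity.
#' @return an object of class `tail_truth`.
#' @export
tail_truth <- function(theta, start_xy, seg_len, width = 3, intensity = 255,
                       noise_sigma = 0, shape = c(120, 220), background = 0) {
  if (any(abs(wrap_angle(diff(theta))) > pi / 2 + 1e-9)) {
    stopf("ground-truth bend exceeds the tracker's max_bend of pi/2")
  }
  pts <- matrix(NA_real_, length(theta) + 1, 2)
  pts[1, ] <- start_xy
  for (i in seq_along(theta)) {
    pts[i + 1, ] <- pts[i, ] + seg_len * c(cos(theta[i]), sin(theta[i]))
  }
  structure(
    list(theta = theta, start_xy = as.numeric(start_xy), seg_len = seg_len,
         width = width, intensity = intensity, noise_sigma = noise_sigma,
         shape = as.integer(shape), background = background, points = pts),
    class = "tail_truth"
  )
}

#' Render one tail frame
#'
#' Draws the tail polyline as an anti-aliased bright curve on a dark
#' background and adds seeded Gaussian noise. Errors if the curve (plus its
#' width) leaves the frame: fixtures must be fully visible.
#'
#' @param truth a [tail_truth()].
#' @param t,frame_id frame timestamp and id.
#' @param seed noise seed (ignored when `noise_sigma` is 0).
#' @return a `fish_frame`; the exact polyline vertices are attached as
#'   attribute `"polyline"`.
#' @export
render_tail_frame <- function(truth, t = 0, frame_id = 0L, seed = NULL) {
  h <- truth$shape[1]; w <- truth$shape[2]
  m <- truth$width / 2 + 1
  if (any(truth$points[, 1] < m) || any(truth$points[, 1] > w - 1 - m) ||
      any(truth$points[, 2] < m) || any(truth$points[, 2] > h - 1 - m)) {
    stopf("rendered tail leaves the frame")
  }
  px <- matrix(truth$background, h, w)
  px <- draw_polyline(px, truth$points, truth$width, truth$intensity,
                      brighten = TRUE)
  if (truth$noise_sigma > 0) {
    px <- px + with_seed(seed, matrix(stats::rnorm(h * w,
                                                   sd = truth$noise_sigma),
                                      h, w))
    px <- pmin(pmax(px, 0), 255)
  }
  fr <- new_frame(px, t = t, frame_id = frame_id)
  attr(fr, "polyline") <- truth$points
  fr
}

# Blend a polyline of the given width into the image. `brighten = TRUE`
# raises pixels toward `intensity`, FALSE darkens them (for dark fish).
draw_polyline <- function(px, pts, width, intensity, brighten = TRUE) {
  h <- nrow(px); w <- ncol(px)
  x0 <- max(0L, floor(min(pts[, 1]) - width - 2))
  x1 <- min(w - 1L, ceiling(max(pts[, 1]) + width + 2))
  y0 <- max(0L, floor(min(pts[, 2]) - width - 2))
  y1 <- min(h - 1L, ceiling(max(pts[, 2]) + width + 2))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  d <- dist_to_polyline_cpp(gx, gy, pts[, 1], pts[, 2])
  alpha <- pmin(pmax(width / 2 + 0.5 - d, 0), 1)
  idx <- cbind(gy + 1, gx + 1)
  old <- px[idx]
  px[idx] <- if (brighten) pmax(old, old * (1 - alpha) + intensity * alpha)
             else pmin(old, old * (1 - alpha) + intensity * alpha)
  px
}

# Blend a filled disc into the image (darkening toward `intensity`).
draw_disc <- function(px, cx, cy, r, intensity, brighten = FALSE) {
  h <- nrow(px); w <- ncol(px)
  x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
  y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
  if (x1 < x0 || y1 < y0) return(px)
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)
  alpha <- pmin(pmax(r + 0.5 - d, 0), 1)
  idx <- cbind(gy + 1, gx + 1)
  old <- px[idx]
  px[idx] <- if (brighten) pmax(old, old * (1 - alpha) + intensity * alpha)
             else pmin(old, old * (1 - alpha) + intensity * alpha)
  px
}

#' Render a frame with filled ellipses (eye fixture)
#'
#' Dark filled ellipses on a bright background, the geometry eye tracking
#' assumes. Anti-aliased edges; exact parameters are the ground truth.
#'
#' @param centers n x 2 matrix of ellipse centers (x, y).
#' @param semi_axes n x 2 matrix (major, minor) semi-axes, pixels.
#' @param angles major-axis orientations, radians.
#' @param shape frame (height, width).
#' @param background background intensity.
#' @param intensity ellipse intensity (darker than background).
#' @param t,frame_id frame metadata.
#' @return a `fish_frame`.
#' @export
render_ellipse_frame <- function(centers, semi_axes, angles,
                                 shape = c(100, 100), background = 200,
                                 intensity = 30, t = 0, frame_id = 0L) {
  h <- shape[1]; w <- shape[2]
  px <- matrix(background, h, w)
  centers <- matrix(as.numeric(centers), ncol = 2)
  semi_axes <- matrix(as.numeric(semi_axes), ncol = 2)
  for (i in seq_len(nrow(centers))) {
    a <- semi_axes[i, 1]; b <- semi_axes[i, 2]; phi <- angles[i]
    cx <- centers[i, 1]; cy <- centers[i, 2]
    r <- max(a, b)
    x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
    y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
    gx <- rep(x0:x1, each = y1 - y0 + 1)
    gy <- rep(y0:y1, times = x1 - x0 + 1)
    u <- (gx - cx) * cos(phi) + (gy - cy) * sin(phi)
    v <- -(gx - cx) * sin(phi) + (gy - cy) * cos(phi)
    # signed distance to the ellipse boundary (first-order: level-set value
    # over its gradient) for a 1 px AA ramp
    rho <- sqrt((u / a)^2 + (v / b)^2)
    grad <- sqrt((u / a^2)^2 + (v / b^2)^2) / pmax(rho, 1e-9)
    dd <- (rho - 1) / pmax(grad, 1e-9)
    alpha <- pmin(pmax(0.5 - dd, 0), 1)
    idx <- cbind(gy + 1, gx + 1)
    old <- px[idx]
    px[idx] <- pmin(old, old * (1 - alpha) + intensity * alpha)
  }
  new_frame(px, t = t, frame_id = frame_id)
}

#' Total-curvature trace of one swim bout
#'
#' `curvature(t) = amplitude * env(t) * sin(2 pi f_beat t)` inside the bout,
#' 0 outside. Physiologic tail-beat frequencies reach ~50 Hz, so sampling
#' must satisfy the Nyquist guard `fs > 2 f_beat` (300 Hz is the
#' recommended acquisition rate).
#'
#' @param f_beat tail-beat frequency, Hz.
#' @param amplitude curvature amplitude, radians.
#' @param duration bout duration, seconds.
#' @param fs sampling rate, Hz.
#' @param envelope `"rect"` or `"raised_cosine"`.
#' @param t_start bout onset within the trace, seconds.
#' @param t_total total trace duration, seconds (default: bout only).
#' @return list with `t` and `curvature` vectors.
#' @export
generate_bout_trace <- function(f_beat, amplitude, duration, fs = 300,
                                envelope = c("rect", "raised_cosine"),
                                t_start = 0, t_total = t_start + duration) {
  envelope <- match.arg(envelope)
  if (fs <= 2 * f_beat) stopf("fs = %g Hz undersamples f_beat = %g Hz",
                              fs, f_beat)
  n <- as.integer(round(t_total * fs))
  t <- (seq_len(n) - 1L) / fs
  tl <- t - t_start
  inside <- tl >= 0 & tl < duration
  env <- numeric(n)
  env[inside] <- if (envelope == "rect") 1 else {
    0.5 * (1 - cos(2 * pi * tl[inside] / duration))
  }
  list(t = t, curvature = amplitude * env * sin(2 * pi * f_beat * tl) * inside)
}

#' Sum several bouts into one trace
#' @param starts bout onset times, seconds.
#' @param duration per-bout duration, seconds.
#' @param f_beat,amplitude,fs,envelope as in [generate_bout_trace()].
#' @param t_total total trace duration, seconds.
#' @return list with `t` and `curvature`.
#' @export
generate_bout_train <- function(starts, duration, f_beat = 20,
                                amplitude = 0.8, fs = 300,
                                envelope = "raised_cosine",
                                t_total = max(starts) + duration + 0.5) {
  n <- as.integer(round(t_total * fs))
  t <- (seq_len(n) - 1L) / fs
  curv <- numeric(n)
  for (s in starts) {
    b <- generate_bout_trace(f_beat, amplitude, duration, fs,
                             envelope = envelope, t_start = s,
                             t_total = t_total)
    curv <- curv + b$curvature
  }
  list(t = t, curvature = curv)
}

#' Fish body template for scene rendering
#'
#' Proportions mimic a transmitted-light larva: a head disc with two darker
#' eye discs spaced about a third of the head width apart ahead of the
#' center, a darker swim-bladder disc behind, and a thin tail.
#'
#' @param head_radius head disc radius, px.
#' @param eye_fwd,eye_lat eye center offsets from the head center along and
#'   across the heading, px.
#' @param eye_radius eye disc radius, px.
#' @param bladder_back swim-bladder offset behind the head center, px.
#' @param bladder_radius bladder disc radius, px.
#' @param tail_length,tail_width tail polyline geometry, px.
#' @param body_intensity,eye_intensity,bladder_intensity,tail_intensity
#'   rendered intensities (all darker than the arena background).
#' @return a named list of template constants.
#' @export
fish_template <- function(head_radius = 5, eye_fwd = 2.2, eye_lat = 1.9,
                          eye_radius = 1.4, bladder_back = 2.6,
                          bladder_radius = 1.6, tail_length = 14,
                          tail_width = 2, body_intensity = 140,
                          eye_intensity = 40, bladder_intensity = 60,
                          tail_intensity = 150) {
  as.list(environment())
}

#' Simulate a bout-and-glide swim trajectory
#'
#' The fish is stationary between bouts; during each bout the speed follows
#' a raised-cosine envelope with the given peak and the heading changes by a
#' draw from the turn distribution, spread smoothly over the bout. Fully
#' determined by the seed. Errors if the trajectory leaves the arena (the
#' arena must be chosen large enough for the requested bouts).
#'
#' @param n_bouts number of bouts.
#' @param fs sampling rate, Hz (default 300, the recommended acquisition
#'   rate).
#' @param bout_duration seconds per bout.
#' @param interbout quiescent gap between bouts, seconds.
#' @param peak_speed peak bout speed, px/s.
#' @param turn_sd SD of the per-bout turn angle, radians (turns are
#'   `rnorm(n, 0, turn_sd)` unless `turns` is given).
#' @param turns optional fixed vector of per-bout turn angles, radians.
#' @param arena (width, height) in px.
#' @param start_pos,start_heading initial pose.
#' @param margin minimum distance to the arena wall, px.
#' @param lead_in stationary time before the first bout, seconds.
#' @param seed RNG seed.
#' @return a `scene_truth`: list with `t`, `pose` (data.frame `x`, `y`,
#'   `heading`), `bouts` (data.frame `t_start`, `t_end`, `turn`), `fs`,
#'   `arena`.
#' @export
simulate_swim_trajectory <- function(n_bouts, fs = 300, bout_duration = 0.2,
                                     interbout = 0.5, peak_speed = 120,
                                     turn_sd = 0.5, turns = NULL,
                                     arena = c(200, 200),
                                     start_pos = arena / 2,
                                     start_heading = 0, margin = 15,
                                     lead_in = 0.3, seed = 1) {
  if (is.null(turns)) {
    turns <- with_seed(seed, stats::rnorm(max(n_bouts, 1), 0, turn_sd))
  }
  t_total <- lead_in + n_bouts * (bout_duration + interbout)
  n <- as.integer(round(t_total * fs))
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n); y <- numeric(n); h <- numeric(n)
  x[1] <- start_pos[1]; y[1] <- start_pos[2]; h[1] <- start_heading
  bout_starts <- lead_in + (seq_len(n_bouts) - 1) * (bout_duration + interbout)
  bouts <- data.frame(t_start = bout_starts,
                      t_end = bout_starts + bout_duration,
                      turn = if (n_bouts > 0) turns[seq_len(n_bouts)]
                             else numeric(0))
  for (i in seq_len(n - 1L)) {
    ti <- t[i]
    k <- if (n_bouts > 0) which(ti >= bouts$t_start & ti < bouts$t_end)
         else integer(0)
    if (length(k) == 1L) {
      phase <- (ti - bouts$t_start[k]) / bout_duration
      env <- 0.5 * (1 - cos(2 * pi * phase))
      speed <- peak_speed * env
      hdot <- bouts$turn[k] / bout_duration *
        0.5 * (1 - cos(2 * pi * phase)) * 2  # integrates to `turn`
    } else {
      speed <- 0
      hdot <- 0
    }
    h[i + 1] <- h[i] + hdot / fs
    x[i + 1] <- x[i] + speed * cos(h[i]) / fs
    y[i + 1] <- y[i] + speed * sin(h[i]) / fs
  }
  if (any(x < margin | x > arena[1] - margin |
          y < margin | y > arena[2] - margin)) {
    stopf("trajectory leaves the arena; enlarge the arena or reduce bouts")
  }
  structure(
    list(t = t, pose = data.frame(x = x, y = y, heading = h), bouts = bouts,
         fs = fs, arena = as.numeric(arena)),
    class = "scene_truth"
  )
}

#' Render a swim scene
#'
#' Dark fish (head disc, two darker eye discs, darker swim-bladder disc and
#' a tail polyline) on a bright background, with seeded Gaussian noise. One
#' `scene_truth` can hold several fish: pass a list of truths sharing the
#' same time base.
#'
#' @param truths a `scene_truth` or list of them (same `t` and `arena`).
#' @param template a [fish_template()].
#' @param background arena background intensity.
#' @param noise_sigma Gaussian pixel noise SD.
#' @param tail_curvature optional per-frame total tail curvature (radians)
#'   applied as a smooth bend; default straight tail.
#' @param seed noise seed.
#' @return list of `fish_frame`s, one per time sample.
#' @export
render_scene <- function(truths, template = fish_template(),
                         background = 200, noise_sigma = 0,
                         tail_curvature = NULL, seed = NULL) {
  if (inherits(truths, "scene_truth")) truths <- list(truths)
  t <- truths[[1]]$t
  arena <- truths[[1]]$arena
  h <- as.integer(arena[2]); w <- as.integer(arena[1])
  n_seg <- 6L
  noise <- if (noise_sigma > 0) {
    with_seed(seed, lapply(seq_along(t), function(i) {
      matrix(stats::rnorm(h * w, sd = noise_sigma), h, w)
    }))
  } else NULL
  frames <- vector("list", length(t))
  for (i in seq_along(t)) {
    px <- matrix(background, h, w)
    for (tr in truths) {
      p <- tr$pose[i, ]
      hd <- p$heading
      fwd <- c(cos(hd), sin(hd))
      lat <- c(-sin(hd), cos(hd))
      curv <- if (is.null(tail_curvature)) 0 else tail_curvature[i]
      # tail first so the body overdraws its base
      base <- c(p$x, p$y) - fwd * (template$head_radius - 1)
      seg <- template$tail_length / n_seg
      tp <- matrix(NA_real_, n_seg + 1, 2)
      tp[1, ] <- base
      ang <- hd + pi
      for (s in seq_len(n_seg)) {
        ang_s <- ang + curv * (s - 1) / (n_seg - 1)
        tp[s + 1, ] <- tp[s, ] + seg * c(cos(ang_s), sin(ang_s))
      }
      px <- draw_polyline(px, tp, template$tail_width,
                          template$tail_intensity, brighten = FALSE)
      px <- draw_disc(px, p$x, p$y, template$head_radius,
                      template$body_intensity)
      eye1 <- c(p$x, p$y) + fwd * template$eye_fwd + lat * template$eye_lat
      eye2 <- c(p$x, p$y) + fwd * template$eye_fwd - lat * template$eye_lat
      bl <- c(p$x, p$y) - fwd * template$bladder_back
      px <- draw_disc(px, eye1[1], eye1[2], template$eye_radius,
                      template$eye_intensity)
      px <- draw_disc(px, eye2[1], eye2[2], template$eye_radius,
                      template$eye_intensity)
      px <- draw_disc(px, bl[1], bl[2], template$bladder_radius,
                      template$bladder_intensity)
    }
    if (!is.null(noise)) px <- pmin(pmax(px + noise[[i]], 0), 255)
    frames[[i]] <- new_frame(px, t = t[i], frame_id = i - 1L)
  }
  frames
}
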