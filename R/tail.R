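# Head-restrained tail skeletonization. Starting from a user-supplied tail
# base and resting direction, segments are traced iteratively; the direction
# of each new segment comes either from the intensity-weighted center of mass
# of a square sampling window placed one segment-length ahead ("com"), or
# from the brightest pixel along an arc of radius one segment length ("arc").
# Intensities are read with bilinear interpolation so angular resolution is
# not limited by pixel quantization.

#' Tail tracing parameters
#'
#' @param start_xy tail base, (x, y) pixels.
#' @param tail_length total tail length in pixels. Alternatively give
#'   `end_xy` (resting tail tip) from which length and direction are derived.
#' @param tail_dir0 initial direction toward the tail tip at rest, radians.
#' @param end_xy optional resting tip point; overrides `tail_length` and
#'   `tail_dir0`.
#' @param n_segments number of traced segments (7-10 typical).
#' @param window_size side of the center-of-mass sampling square in pixels;
#'   defaults to the segment length.
#' @param method `"com"` (center of mass, default) or `"arc"` (arc arg-max).
#' @param arc_halfwidth half-width of the sampled arc, radians.
#' @param max_bend maximum bend per segment, radians; larger deflections are
#'   clamped so the trace cannot fold back onto the body.
#' @return an object of class `tail_params`.
#' @export
tail_params <- function(start_xy, tail_length = NULL, tail_dir0 = 0,
                        end_xy = NULL, n_segments = 9L, window_size = NULL,
                        method = c("com", "arc"), arc_halfwidth = pi / 4,
                        max_bend = pi / 2) {
  method <- match.arg(method)
  if (!is.null(end_xy)) {
    d <- c(end_xy[1] - start_xy[1], end_xy[2] - start_xy[2])
    tail_length <- sqrt(sum(d^2))
    tail_dir0 <- atan2(d[2], d[1])
  }
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stopf("n_segments must be >= 2")
  if (is.null(tail_length) || tail_length <= 0) stopf("tail_length must be > 0")
  seg_len <- tail_length / n_segments
  if (is.null(window_size)) window_size <- seg_len
  structure(
    list(start_xy = as.numeric(start_xy), tail_dir0 = tail_dir0,
         tail_length = tail_length, n_segments = n_segments,
         seg_len = seg_len, window_size = window_size, method = method,
         arc_halfwidth = arc_halfwidth, max_bend = max_bend),
    class = "tail_params"
  )
}

#' Trace the tail in one frame
#'
#' Expects a preprocessed frame (tail brighter than background). Never raises
#' on poor image content: if a sampling window or arc falls fully outside the
#' frame, or contains no intensity, the previous direction is carried forward
#' and the trace is flagged invalid.
#'
#' @param frame a `fish_frame`.
#' @param params a [tail_params()].
#' @return a `tail_trace`: list with `t`, `theta` (absolute segment angles,
#'   radians), `points` ((n_segments + 1) x 2 matrix of segment endpoints),
#'   `seg_len` and `valid`.
#' @export
trace_tail <- function(frame, params) {
  stopifnot(inherits(frame, "fish_frame"), inherits(params, "tail_params"))
  px <- frame$pixels
  if (!in_frame(px, params$start_xy[1], params$start_xy[2])) {
    stopf("tail start point (%g, %g) lies outside the frame",
          params$start_xy[1], params$start_xy[2])
  }
  n <- params$n_segments
  L <- params$seg_len
  pos <- params$start_xy
  dir <- params$tail_dir0
  theta <- numeric(n)
  pts <- matrix(NA_real_, n + 1, 2)
  pts[1, ] <- pos
  valid <- TRUE

  for (i in seq_len(n)) {
    step <- tail_step(px, pos, dir, params)
    if (!step$ok) valid <- FALSE
    # clamp bend per segment
    bend <- wrap_angle(step$dir - dir)
    bend <- sign(bend) * min(abs(bend), params$max_bend)
    dir <- dir + bend
    theta[i] <- dir
    pos <- pos + L * c(cos(dir), sin(dir))
    pts[i + 1, ] <- pos
  }
  new_tail_trace(frame$t, theta, pts, L, valid)
}

new_tail_trace <- function(t, theta, points, seg_len, valid) {
  structure(
    list(t = t, theta = theta, points = points, seg_len = seg_len,
         valid = valid),
    class = "tail_trace"
  )
}

# One tracing step: propose the direction of the next segment.
tail_step <- function(px, pos, dir, params) {
  L <- params$seg_len
  if (params$method == "com") {
    ctr <- pos + L * c(cos(dir), sin(dir))
    half <- params$window_size / 2
    # symmetric grid at ~1 px spacing; asymmetry would bias the COM
    g <- seq(-half, half, length.out = max(2L, ceiling(params$window_size)) + 1L)
    gx <- rep(ctr[1] + g, times = length(g))
    gy <- rep(ctr[2] + g, each = length(g))
    inside <- in_frame(px, gx, gy)
    if (!any(inside)) return(list(dir = dir, ok = FALSE))
    w <- bilinear_sample(px, gx, gy)
    s <- sum(w)
    if (s <= 0) return(list(dir = dir, ok = FALSE))
    com <- c(sum(w * gx), sum(w * gy)) / s
    d <- com - pos
    if (all(d == 0)) return(list(dir = dir, ok = FALSE))
    list(dir = atan2(d[2], d[1]), ok = TRUE)
  } else {
    hw <- params$arc_halfwidth
    da <- 1 / L  # ~1 px spacing along the arc
    nn <- ceiling(hw / da)
    angs <- (-nn:nn) * da  # symmetric grid: zero deviation is on-grid
    ax <- pos[1] + L * cos(dir + angs)
    ay <- pos[2] + L * sin(dir + angs)
    inside <- in_frame(px, ax, ay)
    if (!any(inside)) return(list(dir = dir, ok = FALSE))
    v <- bilinear_sample(px, ax, ay)
    v[!inside] <- -Inf
    vmax <- max(v)
    if (!is.finite(vmax) || vmax <= 0) return(list(dir = dir, ok = FALSE))
    cand <- which(v == vmax)
    best <- cand[which.min(abs(angs[cand]))]  # tie-break: smallest deviation
    off <- 0
    if (best > 1L && best < length(v) &&
        is.finite(v[best - 1L]) && is.finite(v[best + 1L])) {
      # parabolic sub-sample refinement of the arg-max
      denom <- v[best - 1L] - 2 * v[best] + v[best + 1L]
      if (denom < -1e-9) {
        off <- max(min(0.5 * (v[best - 1L] - v[best + 1L]) / denom, 0.5),
                   -0.5)
      }
    }
    list(dir = dir + angs[best] + off * da, ok = TRUE)
  }
}

#' Resample a tail trace to a fixed number of segments
#'
#' The absolute angle profile is linearly interpolated over normalized arc
#' length, so traces from setups with different camera resolutions become
#' comparable. End angles are preserved exactly, hence so is the total
#' curvature.
#'
#' @param trace a `tail_trace`.
#' @param n_out output segment count (>= 2).
#' @return a resampled `tail_trace`.
#' @export
resample_segments <- function(trace, n_out) {
  stopifnot(inherits(trace, "tail_trace"))
  n_out <- as.integer(n_out)
  if (is.na(n_out) || n_out < 2L) stopf("n_out must be an integer >= 2")
  n_in <- length(trace$theta)
  if (n_out == n_in) return(trace)
  xi <- seq(0, 1, length.out = n_in)
  xo <- seq(0, 1, length.out = n_out)
  theta <- stats::approx(xi, trace$theta, xo)$y
  total_len <- trace$seg_len * n_in
  L <- total_len / n_out
  pts <- matrix(NA_real_, n_out + 1, 2)
  pts[1, ] <- trace$points[1, ]
  for (i in seq_len(n_out)) {
    pts[i + 1, ] <- pts[i, ] + L * c(cos(theta[i]), sin(theta[i]))
  }
  new_tail_trace(trace$t, theta, pts, L, trace$valid)
}

#' Total tail curvature
#'
#' Difference between the last and first segment angles; by the telescoping
#' identity this equals the sum of all successive inter-segment angle
#' differences. Invariant to the choice of the resting direction.
#'
#' @param trace a `tail_trace`.
#' @return curvature in radians.
#' @export
total_curvature <- function(trace) {
  stopifnot(inherits(trace, "tail_trace"))
  th <- trace$theta
  th[length(th)] - th[1]
}
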