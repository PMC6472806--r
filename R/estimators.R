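# Behavior-state estimators and closed-loop laws. Swim vigor is the trailing
# standard deviation of the total tail curvature over a short window (50 ms
# by default); it is proportional to the fish's forward velocity and drives
# the grating-velocity feedback law of the closed-loop optomotor assay.

#' Vigor estimator configuration
#'
#' `vigor_scale` and `swim_threshold` have no universal values — they depend
#' on the preparation and magnification — so they must be supplied
#' explicitly wherever a velocity is derived.
#'
#' @param window trailing window length in seconds (default 0.050).
#' @param vigor_scale (mm/s) of forward velocity per radian of curvature
#'   standard deviation.
#' @param swim_threshold vigor level above which the fish counts as swimming.
#' @return an object of class `vigor_config`.
#' @export
vigor_config <- function(window = 0.050, vigor_scale = NULL,
                         swim_threshold = NULL) {
  if (window <= 0) stopf("window must be > 0")
  structure(list(window = window, vigor_scale = vigor_scale,
                 swim_threshold = swim_threshold),
            class = "vigor_config")
}

#' Swim vigor of a curvature trace
#'
#' Trailing-window population standard deviation of the total tail
#' curvature, one output sample per input sample. The window covers
#' `round(window / dt)` samples including the current one; until it fills,
#' 0 is emitted.
#'
#' @param t uniformly spaced sample times, seconds.
#' @param curvature total tail curvature per sample, radians.
#' @param cfg a [vigor_config()].
#' @return numeric vector of vigor values, same length as the input.
#' @export
vigor <- function(t, curvature, cfg = vigor_config()) {
  n <- length(curvature)
  if (length(t) != n) stopf("t and curvature lengths differ")
  dt <- stats::median(diff(t))
  if (dt > cfg$window) stopf("sampling period %g s exceeds window %g s",
                             dt, cfg$window)
  w <- max(2L, as.integer(round(cfg$window / dt)))
  s1 <- cumsum(curvature)
  s2 <- cumsum(curvature^2)
  out <- numeric(n)
  if (n >= w) {
    i <- w:n
    sum1 <- s1[i] - c(0, s1)[i - w + 1]
    sum2 <- s2[i] - c(0, s2)[i - w + 1]
    v <- sum2 / w - (sum1 / w)^2
    out[i] <- sqrt(pmax(v, 0))
  }
  out
}

#' Vigor-based fish forward velocity
#'
#' Negative values mean forward swimming (the convention under which a
#' swimming fish satisfies `fish_vel < -15` for a threshold of 15 mm/s).
#' Below `swim_threshold` the fish counts as still and 0 is returned.
#'
#' @param vig vigor value(s).
#' @param cfg a [vigor_config()] with `vigor_scale` and `swim_threshold` set.
#' @return velocity in mm/s (<= 0), same length as `vig`.
#' @export
fish_velocity <- function(vig, cfg) {
  if (is.null(cfg$vigor_scale) || is.null(cfg$swim_threshold)) {
    stopf("vigor_scale and swim_threshold must be configured")
  }
  ifelse(vig >= cfg$swim_threshold, -cfg$vigor_scale * vig, 0)
}

#' Closed-loop grating velocity
#'
#' `v_grating = v_base + gain * v_fish`. Since `v_fish <= 0` while swimming,
#' swimming drives the grating backward relative to its open-loop speed;
#' gain 0 recovers the open loop exactly.
#'
#' @param v_base open-loop grating speed, mm/s.
#' @param v_fish estimated fish velocity from [fish_velocity()], mm/s.
#' @param gain unitless feedback gain.
#' @return grating velocity in mm/s.
#' @export
grating_velocity <- function(v_base, v_fish, gain) {
  v_base + gain * v_fish
}

#' Gain protocol specification for the closed-loop optomotor assay
#'
#' @param base_velocity open-loop grating speed, mm/s (default 10).
#' @param spatial_frequency grating spatial frequency, cycles/mm
#'   (default 0.1).
#' @param gain_sequence data.frame with columns `gain` (unitless, >= 0) and
#'   `duration` (seconds, > 0).
#' @return an object of class `gain_protocol_spec`.
#' @export
gain_protocol_spec <- function(base_velocity = 10, spatial_frequency = 0.1,
                               gain_sequence) {
  if (any(gain_sequence$duration <= 0)) stopf("durations must be > 0")
  if (any(gain_sequence$gain < 0)) stopf("gains must be >= 0")
  structure(list(base_velocity = base_velocity,
                 spatial_frequency = spatial_frequency,
                 gain_sequence = gain_sequence),
            class = "gain_protocol_spec")
}

#' Bouts and inter-bout intervals from a vigor trace
#'
#' Bouts are maximal runs with vigor >= `swim_threshold`; gaps shorter than
#' `min_gap` are merged first (tail beats briefly dip through the threshold).
#' The inter-bout interval is the time from the end of one bout to the start
#' of the next.
#'
#' @param t uniformly spaced sample times, seconds.
#' @param vig vigor trace.
#' @param cfg a [vigor_config()] with `swim_threshold` set.
#' @param min_gap gaps below this duration (seconds) are merged.
#' @return list with `bouts` (data.frame `t_start`, `t_end`, `duration`) and
#'   `intervals` (numeric vector, seconds).
#' @export
interbout_intervals <- function(t, vig, cfg, min_gap = 0) {
  if (is.null(cfg$swim_threshold)) stopf("swim_threshold must be configured")
  active <- vig >= cfg$swim_threshold
  if (!any(active)) {
    return(list(bouts = data.frame(t_start = numeric(0), t_end = numeric(0),
                                   duration = numeric(0)),
                intervals = numeric(0)))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge bouts separated by short gaps
  if (min_gap > 0 && nrow(seg) > 1L) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- t[seg$start[i]] - t[merged$end[nrow(merged)]]
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  # half-open sample convention: each sample covers one period, so a bout
  # ends one period after its last supra-threshold sample
  dt <- stats::median(diff(t))
  bouts <- data.frame(t_start = t[seg$start], t_end = t[seg$end] + dt)
  bouts$duration <- bouts$t_end - bouts$t_start
  intervals <- if (nrow(bouts) > 1L) {
    bouts$t_start[-1] - bouts$t_end[-nrow(bouts)]
  } else numeric(0)
  list(bouts = bouts, intervals = intervals)
}

# --- Camera <-> display calibration ----------------------------------------

#' Affine calibration from three point pairs
#'
#' Three non-collinear points determine a planar affine map uniquely (a
#' projective map would need four); the residual on the anchor points is
#' zero to machine precision.
#'
#' @param cam_pts 3 x 2 matrix of camera points (x, y), non-collinear.
#' @param disp_pts 3 x 2 matrix of corresponding display points.
#' @param eps minimum triangle area (px^2) below which the configuration is
#'   rejected as collinear.
#' @return a `calibration_transform`: list with the 2 x 2 linear part `A`
#'   and offset `b`, mapping camera to display coordinates.
#' @export
compute_calibration <- function(cam_pts, disp_pts, eps = 1e-6) {
  cam_pts <- as.matrix(cam_pts)
  disp_pts <- as.matrix(disp_pts)
  stopifnot(all(dim(cam_pts) == c(3, 2)), all(dim(disp_pts) == c(3, 2)))
  area <- abs((cam_pts[2, 1] - cam_pts[1, 1]) * (cam_pts[3, 2] - cam_pts[1, 2]) -
              (cam_pts[3, 1] - cam_pts[1, 1]) * (cam_pts[2, 2] - cam_pts[1, 2])) / 2
  if (area <= eps) stopf("calibration points are collinear (area %g)", area)
  X <- cbind(cam_pts, 1)
  sol <- solve(X, disp_pts)   # 3 x 2: rows = (a_col1, a_col2, b)
  structure(list(A = t(sol[1:2, , drop = FALSE]), b = as.numeric(sol[3, ])),
            class = "calibration_transform")
}

#' Apply a calibration transform to points
#' @param tf a `calibration_transform`.
#' @param pts n x 2 matrix of camera points.
#' @return n x 2 matrix of display points.
#' @export
apply_calibration <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(tf$A), 2, -tf$b)
}

#' Invert a calibration transform
#' @param tf a `calibration_transform`.
#' @return the inverse `calibration_transform` (display to camera).
#' @export
invert_calibration <- function(tf) {
  Ai <- solve(tf$A)
  structure(list(A = Ai, b = as.numeric(-Ai %*% tf$b)),
            class = "calibration_transform")
}

#' Detect the three projected calibration spots in a camera frame
#'
#' Blurs the frame, finds strict local maxima, keeps the three brightest and
#' refines each to sub-pixel precision by the intensity center of mass in a
#' small neighborhood. The result is sorted lexicographically by (x, y) so
#' correspondence with the projected pattern is stable.
#'
#' @param frame a `fish_frame` showing three bright spots.
#' @param blur_sigma pre-detection blur, pixels.
#' @param refine_radius half-size of the center-of-mass window, pixels.
#' @return 3 x 2 matrix of spot centers (x, y).
#' @export
detect_calibration_points <- function(frame, blur_sigma = 2,
                                      refine_radius = 4L) {
  px <- gauss_blur(frame$pixels, blur_sigma)
  h <- nrow(px); w <- ncol(px)
  inner <- px[2:(h - 1), 2:(w - 1)]
  is_max <- inner > px[1:(h - 2), 2:(w - 1)] & inner > px[3:h, 2:(w - 1)] &
    inner > px[2:(h - 1), 1:(w - 2)] & inner > px[2:(h - 1), 3:w] &
    inner > px[1:(h - 2), 1:(w - 2)] & inner > px[1:(h - 2), 3:w] &
    inner > px[3:h, 1:(w - 2)] & inner > px[3:h, 3:w]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) < 3L) stopf("fewer than 3 local maxima found")
  vals <- inner[is_max]
  ord <- order(vals, decreasing = TRUE)[1:3]
  pts <- t(apply(idx[ord, , drop = FALSE], 1, function(ij) {
    # ij is (row, col) within the inner matrix; +1 each for the border crop,
    # -1 for 0-based coordinates
    cy <- ij[1]; cx <- ij[2]
    r <- refine_radius
    rows <- max(1, cy + 1 - r):min(h, cy + 1 + r)
    cols <- max(1, cx + 1 - r):min(w, cx + 1 + r)
    wgt <- px[rows, cols]
    wgt <- pmax(wgt - min(wgt), 0)
    s <- sum(wgt)
    if (s <= 0) return(c(cx, cy))
    gx <- matrix(rep(cols - 1, each = length(rows)), length(rows))
    gy <- matrix(rep(rows - 1, times = length(cols)), length(rows))
    c(sum(wgt * gx), sum(wgt * gy)) / s
  }))
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

# --- Phototaxis geometry ----------------------------------------------------

#' Half-field phototaxis stimulus geometry
#'
#' The light/dark boundary runs along the fish midline: the line through the
#' fish position with the fish heading as direction. A point p is on the
#' bright side iff the sign of the 2-D cross product
#' `heading x (p - pos) = cos(h) dy - sin(h) dx` matches the chosen side
#' (positive = left).
#'
#' @param fish_pos fish position (x, y).
#' @param fish_heading heading, radians.
#' @param bright_side `"left"` or `"right"` of the fish.
#' @return a `phototaxis_field`: list with `pos`, `heading`, `bright_side`.
#' @export
phototaxis_field <- function(fish_pos, fish_heading,
                             bright_side = c("left", "right")) {
  bright_side <- match.arg(bright_side)
  structure(list(pos = as.numeric(fish_pos), heading = fish_heading,
                 bright_side = bright_side),
            class = "phototaxis_field")
}

#' Classify points against a phototaxis field
#' @param field a [phototaxis_field()].
#' @param pts n x 2 matrix of points.
#' @return logical vector: TRUE where the point is on the bright side
#'   (points exactly on the boundary are dark).
#' @export
is_bright <- function(field, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  dx <- pts[, 1] - field$pos[1]
  dy <- pts[, 2] - field$pos[2]
  cross <- cos(field$heading) * dy - sin(field$heading) * dx
  if (field$bright_side == "left") cross > 0 else cross < 0
}
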