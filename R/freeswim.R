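# Freely-swimming fish tracking. Per frame: background subtraction ->
# candidate blobs in an area range -> head localization from the centroid of
# the two eyes and the swim bladder (darker structures inside the blob) ->
# heading initialization from the point of largest background difference on
# a circle of half tail radius, refined by tail tracing -> greedy identity
# matching against the previous frame -> per-fish Kalman smoothing with a
# constant-velocity model over (x, y, heading).

#' Parameters for freely-swimming tracking
#'
#' @param area_range (min, max) blob area in px^2 accepted as one fish.
#' @param fg_threshold threshold on the foreground (background difference)
#'   image that defines candidate blobs.
#' @param eye_bladder_threshold raw-image intensity below which pixels belong
#'   to the eyes or swim bladder.
#' @param tail_radius approximate tail length, pixels; the heading search
#'   circle has half this radius.
#' @param n_tail_segments segments for per-fish tail tracing.
#' @param max_jump maximum displacement in pixels between frames for identity
#'   matching.
#' @param heading_weight cost weight converting heading difference (radians)
#'   into pixels for identity matching.
#' @param nms_radius non-maximum-suppression radius for eye/bladder minima,
#'   pixels (about one eye diameter).
#' @return an object of class `fish_params`.
#' @export
fish_params <- function(area_range, fg_threshold, eye_bladder_threshold,
                        tail_radius, n_tail_segments = 9L, max_jump = 30,
                        heading_weight = 10, nms_radius = 3) {
  if (length(area_range) != 2L || area_range[1] >= area_range[2]) {
    stopf("area_range must be (min, max) with min < max")
  }
  if (tail_radius <= 0) stopf("tail_radius must be > 0")
  structure(
    list(area_range = as.numeric(area_range), fg_threshold = fg_threshold,
         eye_bladder_threshold = eye_bladder_threshold,
         tail_radius = tail_radius,
         n_tail_segments = as.integer(n_tail_segments),
         max_jump = max_jump, heading_weight = heading_weight,
         nms_radius = nms_radius),
    class = "fish_params"
  )
}

#' Initial tail direction at a head position
#'
#' Samples the foreground image on the circle of radius `tail_radius / 2`
#' centered at the head and returns the angle of the strongest sample (the
#' tail is the only structure protruding from the head at that distance).
#' The heading is this angle plus pi. Ties are broken by the smallest angle;
#' a featureless circle is flagged.
#'
#' @param fg foreground `fish_frame` (from [foreground()]).
#' @param head_xy head center (x, y) pixels.
#' @param params a [fish_params()].
#' @return list with `angle` (radians) and `flat` (TRUE when the circle had
#'   no contrast).
#' @export
initial_tail_direction <- function(fg, head_xy, params) {
  px <- fg$pixels
  if (!in_frame(px, head_xy[1], head_xy[2])) stopf("head point outside frame")
  r <- params$tail_radius / 2
  n <- max(16L, as.integer(ceiling(2 * pi * r)))
  angs <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xs <- head_xy[1] + r * cos(angs)
  ys <- head_xy[2] + r * sin(angs)
  inside <- in_frame(px, xs, ys)
  if (!any(inside)) stopf("tail search circle lies fully outside the frame")
  v <- bilinear_sample(px, xs, ys)
  v[!inside] <- -Inf
  vmax <- max(v)
  flat <- !is.finite(vmax) || vmax <= min(v[is.finite(v)]) + 1e-12
  best <- which(v == vmax)[1]  # ties: smallest angle (angs is increasing)
  list(angle = angs[best], flat = flat)
}

#' Detect fish in one foreground frame
#'
#' @param fg foreground `fish_frame`.
#' @param raw the corresponding raw `fish_frame` (eyes/bladder dark).
#' @param params a [fish_params()].
#' @return data.frame with one row per detection: `x`, `y`, `heading`,
#'   `low_confidence`, plus a `theta` list-column of tail segment angles.
#' @export
detect_fish <- function(fg, raw, params) {
  px <- fg$pixels
  mask <- px > params$fg_threshold
  empty <- data.frame(x = numeric(0), y = numeric(0), heading = numeric(0),
                      low_confidence = logical(0))
  empty$theta <- list()
  if (!any(mask)) return(empty)
  labels <- label_components_cpp(mask)
  areas <- tabulate(labels[labels > 0])
  cand <- which(areas >= params$area_range[1] & areas <= params$area_range[2])
  if (length(cand) == 0L) return(empty)

  rows <- lapply(cand, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    blob <- blob_head(pts, raw$pixels, params)
    pos <- blob$pos
    td <- initial_tail_direction(fg, pos, params)
    tp <- tail_params(start_xy = pos, tail_length = params$tail_radius,
                      tail_dir0 = td$angle,
                      n_segments = params$n_tail_segments, method = "com")
    tr <- trace_tail(fg, tp)
    heading <- wrap_angle(tr$theta[1] + pi)  # refined by the first segment
    if (blob$low_confidence && td$flat) heading <- blob$axis_heading
    list(x = pos[1], y = pos[2], heading = heading,
         low_confidence = blob$low_confidence, theta = tr$theta)
  })
  out <- data.frame(
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    heading = vapply(rows, `[[`, numeric(1), "heading"),
    low_confidence = vapply(rows, `[[`, logical(1), "low_confidence")
  )
  out$theta <- lapply(rows, `[[`, "theta")
  out
}

# Head localization within one candidate blob: centroid of the two eyes and
# the swim bladder, found as the three darkest local minima of the raw image
# inside the blob (below eye_bladder_threshold), separated by non-maximum
# suppression of one eye diameter so touching eye discs stay distinct.
# Falls back to the blob centroid + principal axis when fewer than three
# minima exist.
blob_head <- function(pts, raw_px, params) {
  centroid <- colMeans(pts)
  fallback <- function() {
    d <- sweep(pts, 2, centroid)
    cv <- crossprod(d) / nrow(pts)
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    list(pos = centroid, low_confidence = TRUE,
         axis_heading = atan2(ev[2], ev[1]))
  }
  vals <- raw_px[cbind(pts[, 2] + 1, pts[, 1] + 1)]
  dark <- which(vals < params$eye_bladder_threshold)
  if (length(dark) < 3L) return(fallback())
  # local minima of the raw image among the dark blob pixels
  h <- nrow(raw_px); w <- ncol(raw_px)
  is_min <- vapply(dark, function(k) {
    x <- pts[k, 1]; y <- pts[k, 2]
    v <- vals[k]
    xs <- pmin(pmax(x + c(-1, 0, 1, -1, 1, -1, 0, 1), 0), w - 1)
    ys <- pmin(pmax(y + c(-1, -1, -1, 0, 0, 1, 1, 1), 0), h - 1)
    all(v <= raw_px[cbind(ys + 1, xs + 1)])
  }, logical(1))
  cand <- dark[is_min]
  if (length(cand) < 3L) return(fallback())
  cand <- cand[order(vals[cand])]
  # greedy non-maximum suppression, darkest first
  picked <- integer(0)
  for (k in cand) {
    if (length(picked) == 3L) break
    if (all(sqrt((pts[k, 1] - pts[picked, 1])^2 +
                 (pts[k, 2] - pts[picked, 2])^2) >= params$nms_radius) ||
        length(picked) == 0L) {
      picked <- c(picked, k)
    }
  }
  if (length(picked) < 3L) return(fallback())
  # refine each minimum by the center of mass of darkness in a small window
  cents <- t(vapply(picked, function(k) {
    cx <- pts[k, 1]; cy <- pts[k, 2]
    r <- 2L
    xs <- max(0, cx - r):min(w - 1, cx + r)
    ys <- max(0, cy - r):min(h - 1, cy + r)
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    wgt <- pmax(params$eye_bladder_threshold -
                  raw_px[cbind(gy + 1, gx + 1)], 0)
    s <- sum(wgt)
    if (s <= 0) c(cx, cy) else c(sum(wgt * gx), sum(wgt * gy)) / s
  }, numeric(2)))
  list(pos = colMeans(cents), low_confidence = FALSE, axis_heading = NA_real_)
}

#' Match detections to previous fish states
#'
#' Greedy minimum-cost matching with cost
#' `distance + heading_weight * |heading difference|`; pairs farther apart
#' than `max_jump` are never matched. Unmatched detections receive fresh ids,
#' unmatched states become invisible.
#'
#' @param prev data.frame of previous states with columns `id`, `x`, `y`,
#'   `heading` (only visible fish).
#' @param detections data.frame from [detect_fish()].
#' @param params a [fish_params()].
#' @param next_id first id to assign to unmatched detections.
#' @return list with `pairs` (data.frame `det`, `id`), `new_ids` (ids issued),
#'   `lost_ids` and updated `next_id`.
#' @export
assign_identities <- function(prev, detections, params, next_id = 1L) {
  np <- if (is.null(prev)) 0L else nrow(prev)
  nd <- nrow(detections)
  pairs <- data.frame(det = integer(0), id = integer(0))
  if (np > 0L && nd > 0L) {
    cost <- matrix(Inf, np, nd)
    for (i in seq_len(np)) {
      dx <- detections$x - prev$x[i]
      dy <- detections$y - prev$y[i]
      dist <- sqrt(dx^2 + dy^2)
      dh <- abs(wrap_angle(detections$heading - prev$heading[i]))
      c_i <- dist + params$heading_weight * dh
      c_i[dist > params$max_jump] <- Inf
      cost[i, ] <- c_i
    }
    while (any(is.finite(cost))) {
      k <- arrayInd(which.min(cost), dim(cost))
      pairs <- rbind(pairs,
                     data.frame(det = k[2], id = prev$id[k[1]]))
      cost[k[1], ] <- Inf
      cost[, k[2]] <- Inf
    }
  }
  unmatched_det <- setdiff(seq_len(nd), pairs$det)
  new_ids <- integer(0)
  for (d in unmatched_det) {
    pairs <- rbind(pairs, data.frame(det = d, id = next_id))
    new_ids <- c(new_ids, next_id)
    next_id <- next_id + 1L
  }
  lost <- if (np > 0L) setdiff(prev$id, pairs$id) else integer(0)
  pairs <- pairs[order(pairs$det), , drop = FALSE]
  list(pairs = pairs, new_ids = new_ids, lost_ids = lost, next_id = next_id)
}

# --- Kalman filtering -------------------------------------------------------

#' Constant-velocity Kalman filter configuration
#'
#' State is (x, y, heading, vx, vy, heading rate); measurements are
#' (x, y, heading). `q` is the white-acceleration spectral density (px^2/s^3
#' for position, rad^2/s^3 for heading), `r_pos`/`r_ang` the measurement
#' variances.
#'
#' @param q process noise intensity.
#' @param r_pos position measurement variance, px^2.
#' @param r_ang heading measurement variance, rad^2.
#' @return an object of class `kalman_config`.
#' @export
kalman_config <- function(q = 2e4, r_pos = 1, r_ang = 0.05) {
  structure(list(q = q, r_pos = r_pos, r_ang = r_ang),
            class = "kalman_config")
}

kalman_init <- function(z) {
  list(x = c(z, 0, 0, 0), P = diag(c(1, 1, 0.1, 100, 100, 10)))
}

kalman_predict <- function(kf, dt, cfg) {
  F_ <- diag(6)
  F_[1, 4] <- F_[2, 5] <- F_[3, 6] <- dt
  # discrete white-noise acceleration per coordinate
  Qb <- cfg$q * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2)
  Q <- matrix(0, 6, 6)
  for (i in 1:3) {
    sc <- if (i == 3) cfg$r_ang / cfg$r_pos else 1
    Q[c(i, i + 3), c(i, i + 3)] <- Qb * sc
  }
  kf$x <- as.numeric(F_ %*% kf$x)
  kf$P <- F_ %*% kf$P %*% t(F_) + Q
  kf
}

kalman_update <- function(kf, z, cfg) {
  H <- cbind(diag(3), matrix(0, 3, 3))
  R <- diag(c(cfg$r_pos, cfg$r_pos, cfg$r_ang))
  # unwrap the heading measurement against the prediction
  z[3] <- kf$x[3] + wrap_angle(z[3] - kf$x[3])
  y <- z - as.numeric(H %*% kf$x)
  S <- H %*% kf$P %*% t(H) + R
  K <- kf$P %*% t(H) %*% solve(S)
  kf$x <- kf$x + as.numeric(K %*% y)
  kf$P <- (diag(6) - K %*% H) %*% kf$P
  kf
}

#' Kalman-smooth a measured trajectory
#'
#' Causal constant-velocity filter over a uniformly or irregularly sampled
#' sequence of (x, y, heading) measurements. Used by [track_sequence()] and
#' directly testable against jittered ground truth.
#'
#' @param meas data.frame with columns `t`, `x`, `y`, `heading`.
#' @param cfg a [kalman_config()].
#' @return data.frame `t`, `x`, `y`, `heading`, `vx`, `vy`, `ang_vel`.
#' @export
kalman_smooth <- function(meas, cfg = kalman_config()) {
  n <- nrow(meas)
  out <- data.frame(t = meas$t, x = NA_real_, y = NA_real_,
                    heading = NA_real_, vx = NA_real_, vy = NA_real_,
                    ang_vel = NA_real_)
  kf <- NULL
  last_t <- NA_real_
  for (i in seq_len(n)) {
    z <- c(meas$x[i], meas$y[i], meas$heading[i])
    if (is.null(kf)) {
      kf <- kalman_init(z)
    } else {
      kf <- kalman_predict(kf, meas$t[i] - last_t, cfg)
      kf <- kalman_update(kf, z, cfg)
    }
    last_t <- meas$t[i]
    out[i, 2:7] <- kf$x
  }
  out
}

#' Track a frame sequence
#'
#' Full freely-swimming pipeline: background update, foreground, detection,
#' identity assignment and per-fish Kalman smoothing. Deterministic for a
#' fixed input sequence. Per-frame failures are flagged, never raised.
#'
#' @param frames list of raw `fish_frame`s.
#' @param params a [fish_params()].
#' @param bg a [background_model()]; its first `n_init_frames` frames are
#'   used for initialization only (no detection is attempted there).
#' @param kalman a [kalman_config()].
#' @return data.frame with one row per fish per frame: `frame_id`, `t`, `id`,
#'   `x`, `y`, `heading`, `vx`, `vy`, `ang_vel`, `raw_x`, `raw_y`,
#'   `raw_heading`, `visible`.
#' @export
track_sequence <- function(frames, params, bg = background_model(),
                           kalman = kalman_config()) {
  states <- list()   # per id: list(kf, last_t, visible)
  next_id <- 1L
  prev <- NULL
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    detect <- !is.null(bg$mean_image) && bg$n_seen >= bg$n_init_frames
    fg <- if (detect) foreground(bg, fr) else NULL
    bg <- update_background(bg, fr)
    if (!detect) next
    det <- detect_fish(fg, fr, params)
    asg <- assign_identities(prev, det, params, next_id)
    next_id <- asg$next_id
    lost_rows <- lapply(asg$lost_ids, function(id) {
      st <- states[[as.character(id)]]
      states[[as.character(id)]]$visible <<- FALSE
      data.frame(frame_id = fr$frame_id, t = fr$t, id = id,
                 x = st$kf$x[1], y = st$kf$x[2], heading = st$kf$x[3],
                 vx = st$kf$x[4], vy = st$kf$x[5], ang_vel = st$kf$x[6],
                 raw_x = NA_real_, raw_y = NA_real_, raw_heading = NA_real_,
                 visible = FALSE)
    })
    frame_rows <- vector("list", nrow(asg$pairs))
    if (nrow(asg$pairs) > 0L) {
      for (j in seq_len(nrow(asg$pairs))) {
        d <- asg$pairs$det[j]
        id <- asg$pairs$id[j]
        key <- as.character(id)
        z <- c(det$x[d], det$y[d], det$heading[d])
        st <- states[[key]]
        if (is.null(st) || !isTRUE(st$visible)) {
          st <- list(kf = kalman_init(z), last_t = fr$t, visible = TRUE)
        } else {
          st$kf <- kalman_predict(st$kf, fr$t - st$last_t, kalman)
          st$kf <- kalman_update(st$kf, z, kalman)
          st$last_t <- fr$t
        }
        states[[key]] <- st
        frame_rows[[j]] <- data.frame(
          frame_id = fr$frame_id, t = fr$t, id = id,
          x = st$kf$x[1], y = st$kf$x[2], heading = st$kf$x[3],
          vx = st$kf$x[4], vy = st$kf$x[5], ang_vel = st$kf$x[6],
          raw_x = z[1], raw_y = z[2], raw_heading = z[3], visible = TRUE)
      }
    }
    prev <- if (nrow(asg$pairs) > 0L) {
      do.call(rbind, lapply(frame_rows, function(r) {
        data.frame(id = r$id, x = r$x, y = r$y, heading = r$heading)
      }))
    } else NULL
    frame_rows <- c(frame_rows, lost_rows)
    rows[[k]] <- if (length(frame_rows)) do.call(rbind, frame_rows) else NULL
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(frame_id = integer(0), t = numeric(0), id = integer(0),
                      x = numeric(0), y = numeric(0), heading = numeric(0),
                      vx = numeric(0), vy = numeric(0), ang_vel = numeric(0),
                      raw_x = numeric(0), raw_y = numeric(0),
                      raw_heading = numeric(0), visible = logical(0))
  }
  rownames(out) <- NULL
  out
}

# --- Bout kinematics --------------------------------------------------------

#' Segment a trajectory into swim bouts
#'
#' Bouts are detected where the instantaneous speed crosses a hysteresis
#' threshold pair: a bout starts when speed rises to `speed_on` and ends when
#' it falls below `speed_off`. Each bout is rigidly re-aligned so its initial
#' position is the origin and its initial heading is 0, which makes bouts
#' from different places and directions comparable; re-aligning an already
#' aligned bout is the identity.
#'
#' @param traj data.frame with columns `t`, `x`, `y`, `heading`, uniformly
#'   sampled.
#' @param speed_on,speed_off hysteresis thresholds, px/s (`speed_off <=
#'   speed_on`).
#' @return list of bout records, each with `t_start`, `t_end`, `duration`,
#'   `angle_change` (unwrapped heading end - start, radians), `speed`
#'   (profile, px/s) and `aligned` (data.frame `x`, `y`, `heading`). The
#'   inter-bout intervals (end of one bout to start of the next, seconds) are
#'   attached as attribute `"interbout_intervals"`.
#' @export
bout_kinematics <- function(traj, speed_on, speed_off = speed_on / 2) {
  n <- nrow(traj)
  if (n < 3L) return(structure(list(), interbout_intervals = numeric(0)))
  dt <- stats::median(diff(traj$t))
  sp <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2) / diff(traj$t))
  active <- logical(n)
  on <- FALSE
  for (i in seq_len(n)) {
    if (!on && sp[i] >= speed_on) on <- TRUE
    if (on && sp[i] < speed_off) on <- FALSE
    active[i] <- on
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  h_unwrap <- traj$heading[1] + cumsum(c(0, wrap_angle(diff(traj$heading))))
  bouts <- lapply(sel, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    h0 <- h_unwrap[i0]
    ca <- cos(-h0); sa <- sin(-h0)
    dx <- traj$x[i0:i1] - traj$x[i0]
    dy <- traj$y[i0:i1] - traj$y[i0]
    aligned <- data.frame(x = ca * dx - sa * dy, y = sa * dx + ca * dy,
                          heading = h_unwrap[i0:i1] - h0)
    list(t_start = traj$t[i0], t_end = traj$t[i1],
         duration = traj$t[i1] - traj$t[i0],
         angle_change = h_unwrap[i1] - h0,
         speed = sp[i0:i1], aligned = aligned)
  })
  ib <- if (length(bouts) > 1L) {
    vapply(seq_len(length(bouts) - 1L), function(i) {
      bouts[[i + 1L]]$t_start - bouts[[i]]$t_end
    }, numeric(1))
  } else numeric(0)
  structure(bouts, interbout_intervals = ib)
}
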