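# Eye orientation tracking. The eyes of a larval zebrafish seen from above
# are dark ellipses; within a user-placed rectangular region the image is
# binarized below a threshold, the two largest connected components are kept
# and an ellipse is fitted to each from second-order central moments. The
# major-axis angle (an axial quantity, reported in [0, pi)) is the eye angle.

#' Eye region of interest
#'
#' @param origin_xy top-left corner (x, y), 0-based pixels.
#' @param width,height region size in pixels.
#' @param threshold binarization threshold: pixels strictly below it count as
#'   eye pixels (eyes are much darker than the background).
#' @param min_area minimum component area in pixels.
#' @param lr_axis unit 2-vector; components are ordered "left before right"
#'   by their centroid projection on this axis (default image x-axis, the
#'   head-restrained fish-pointing-up convention).
#' @return an object of class `eye_roi`.
#' @export
eye_roi <- function(origin_xy, width, height, threshold, min_area = 20L,
                    lr_axis = c(1, 0)) {
  if (width < 1 || height < 1) stopf("ROI must have positive size")
  structure(
    list(origin_xy = as.numeric(origin_xy), width = as.integer(width),
         height = as.integer(height), threshold = threshold,
         min_area = as.integer(min_area),
         lr_axis = lr_axis / sqrt(sum(lr_axis^2))),
    class = "eye_roi"
  )
}

#' Segment the two eyes inside the ROI
#'
#' Binarizes the ROI below `roi$threshold`, labels 8-connected components and
#' keeps the two largest with area >= `min_area`, ordered left/right by the
#' configured axis. Pixel coordinates are returned in full-frame (x, y).
#'
#' @param frame a `fish_frame` (raw intensities, eyes dark).
#' @param roi an [eye_roi()].
#' @return list with `valid` and, when valid, `left` and `right` n x 2
#'   matrices of pixel coordinates.
#' @export
segment_eyes <- function(frame, roi) {
  stopifnot(inherits(frame, "fish_frame"), inherits(roi, "eye_roi"))
  px <- frame$pixels
  x0 <- roi$origin_xy[1]
  y0 <- roi$origin_xy[2]
  if (x0 < 0 || y0 < 0 || x0 + roi$width > ncol(px) ||
      y0 + roi$height > nrow(px)) {
    stopf("eye ROI exceeds frame bounds")
  }
  sub <- px[(y0 + 1):(y0 + roi$height), (x0 + 1):(x0 + roi$width),
            drop = FALSE]
  mask <- sub < roi$threshold
  if (!any(mask)) return(list(valid = FALSE))
  labels <- label_components_cpp(mask)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= roi$min_area)
  if (length(keep) < 2L) return(list(valid = FALSE))
  top2 <- keep[order(areas[keep], decreasing = TRUE)][1:2]
  comps <- lapply(top2, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    # back to full-frame 0-based (x, y)
    cbind(x = idx[, 2] - 1 + x0, y = idx[, 1] - 1 + y0)
  })
  proj <- vapply(comps, function(p) {
    mean(p[, 1]) * roi$lr_axis[1] + mean(p[, 2]) * roi$lr_axis[2]
  }, numeric(1))
  ord <- order(proj)
  list(valid = TRUE, left = comps[[ord[1]]], right = comps[[ord[2]]])
}

#' Fit an ellipse to a pixel set by second-order moments
#'
#' Semi-axes are `2 * sqrt(lambda)` of the central second-moment matrix
#' (the exact relation for a filled ellipse), with the 1/12 px^2 variance of
#' a unit pixel added to each coordinate. The orientation is the principal
#' axis angle folded to [0, pi). A set whose moment anisotropy
#' `(l1 - l2) / (l1 + l2)` falls below `aniso_eps` (e.g. a disc) carries no
#' orientation information and is flagged `"circular"`; a collinear set is
#' flagged `"collinear"` with minor axis 0.
#'
#' @param pixels n x 2 matrix of (x, y) pixel coordinates, n >= 5.
#' @param aniso_eps circular-degeneracy threshold on moment anisotropy.
#' @return list with `center`, `major`, `minor` (semi-axes, pixels), `angle`
#'   (radians in [0, pi)) and `degenerate` (`"none"`, `"circular"` or
#'   `"collinear"`).
#' @export
fit_ellipse <- function(pixels, aniso_eps = 0.02) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 5L) stopf("ellipse fit needs at least 5 pixels")
  cx <- mean(pixels[, 1])
  cy <- mean(pixels[, 2])
  dx <- pixels[, 1] - cx
  dy <- pixels[, 2] - cy
  eigs <- function(mxx, myy, mxy) {
    tr <- mxx + myy
    disc <- sqrt(max(tr * tr / 4 - (mxx * myy - mxy * mxy), 0))
    c(tr / 2 + disc, tr / 2 - disc)
  }
  # raw moments decide degeneracy; the 1/12 px^2 unit-pixel variance is
  # added only for the axis estimates
  mxx <- mean(dx * dx)
  myy <- mean(dy * dy)
  mxy <- mean(dx * dy)
  l_raw <- eigs(mxx, myy, mxy)
  l <- eigs(mxx + 1 / 12, myy + 1 / 12, mxy)
  angle <- fold_pi(0.5 * atan2(2 * mxy, mxx - myy))
  degenerate <- "none"
  if (l_raw[2] <= 1e-9 * max(l_raw[1], 1)) {
    degenerate <- "collinear"
    l[2] <- 0
  } else if ((l_raw[1] - l_raw[2]) / (l_raw[1] + l_raw[2]) < aniso_eps) {
    degenerate <- "circular"
  }
  list(center = c(cx, cy), major = 2 * sqrt(l[1]),
       minor = 2 * sqrt(max(l[2], 0)), angle = angle, degenerate = degenerate)
}

#' Track both eyes in one frame
#'
#' Composition of [segment_eyes()] and [fit_ellipse()]. Angles are unwrapped
#' against the previous state so a smooth rotation never jumps by pi, then
#' folded back to [0, pi). Failures (missing components, circular
#' degeneracy) carry the previous angles forward with `valid = FALSE` and
#' never raise.
#'
#' @param frame a `fish_frame`.
#' @param roi an [eye_roi()].
#' @param prev previous `eye_state` or NULL.
#' @return an `eye_state`: list with `t`, `angle_left`, `angle_right`,
#'   `centers` (2 x 2 matrix), `axes` (2 x 2 matrix, major/minor per eye),
#'   `valid` and `degenerate` flags.
#' @export
track_eyes <- function(frame, roi, prev = NULL) {
  seg <- segment_eyes(frame, roi)
  carry <- function() {
    list(t = frame$t,
         angle_left = if (is.null(prev)) NA_real_ else prev$angle_left,
         angle_right = if (is.null(prev)) NA_real_ else prev$angle_right,
         centers = if (is.null(prev)) matrix(NA_real_, 2, 2) else prev$centers,
         axes = if (is.null(prev)) matrix(NA_real_, 2, 2) else prev$axes,
         valid = FALSE, degenerate = c("none", "none"))
  }
  if (!seg$valid) return(structure(carry(), class = "eye_state"))
  fl <- fit_ellipse(seg$left)
  fr <- fit_ellipse(seg$right)
  ang <- c(fl$angle, fr$angle)
  degen <- c(fl$degenerate, fr$degenerate)
  prev_ang <- c(if (is.null(prev)) NA else prev$angle_left,
                if (is.null(prev)) NA else prev$angle_right)
  for (i in 1:2) {
    if (degen[i] == "circular") {
      ang[i] <- if (!is.na(prev_ang[i])) prev_ang[i] else 0
    } else if (!is.na(prev_ang[i])) {
      ang[i] <- fold_pi(unwrap_axial(ang[i], prev_ang[i]))
    }
  }
  structure(
    list(t = frame$t, angle_left = ang[1], angle_right = ang[2],
         centers = rbind(fl$center, fr$center),
         axes = rbind(c(fl$major, fl$minor), c(fr$major, fr$minor)),
         valid = TRUE, degenerate = degen),
    class = "eye_state"
  )
}
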