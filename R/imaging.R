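# Frame representation, preprocessing chain and slowly-updating background
# model. All trackers consume frames produced here; after preprocessing the
# convention is "fish bright on dark" (the invert flag adapts sources that
# image the fish dark on bright, as transmitted-IR setups do).

#' Construct a frame
#'
#' A frame is the unit of all tracking: a single-channel intensity image with
#' a timestamp and a monotone frame counter.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param t time of acquisition in seconds.
#' @param frame_id monotone integer frame counter.
#' @param range_max maximum representable intensity (255 for 8-bit sources,
#'   1 for normalized ones). Used by inversion.
#' @return an object of class `fish_frame`.
#' @export
new_frame <- function(pixels, t = 0, frame_id = 0L, range_max = 255) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stopf("frame pixels must be a non-empty matrix")
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, t = as.numeric(t), frame_id = as.integer(frame_id),
         range_max = range_max),
    class = "fish_frame"
  )
}

#' @export
print.fish_frame <- function(x, ...) {
  cat(sprintf("<fish_frame %dx%d t=%.4fs id=%d range=[0,%g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$t, x$frame_id, x$range_max))
  invisible(x)
}

#' Preprocessing specification
#'
#' The preprocessing chain applies, in order: inversion (`range_max - v`),
#' integer block downsampling, Gaussian blur, and clip-to-zero below
#' `clip_level`. Whether clipping precedes or follows the blur is
#' configurable (`clip_before_blur`, default `FALSE`: blur first).
#'
#' @param invert invert intensities so the fish becomes bright on dark.
#' @param downsample integer block size \eqn{\ge} 1; blocks are averaged
#'   (photometry-preserving), trailing rows/columns that do not fill a block
#'   are dropped.
#' @param blur_sigma Gaussian blur standard deviation in pixels (post
#'   downsampling); 0 disables.
#' @param clip_level intensities strictly below this are set to 0.
#' @param clip_before_blur apply the clip before the blur instead of after.
#' @return an object of class `preproc_spec`.
#' @export
preproc_spec <- function(invert = FALSE, downsample = 1L, blur_sigma = 0,
                         clip_level = 0, clip_before_blur = FALSE) {
  downsample <- as.integer(downsample)
  if (is.na(downsample) || downsample < 1L) {
    stopf("downsample factor must be an integer >= 1")
  }
  if (blur_sigma < 0) stopf("blur_sigma must be >= 0")
  structure(
    list(invert = isTRUE(invert), downsample = downsample,
         blur_sigma = blur_sigma, clip_level = clip_level,
         clip_before_blur = isTRUE(clip_before_blur)),
    class = "preproc_spec"
  )
}

#' Preprocess a frame
#'
#' Pure function: the input frame is not modified. With the identity spec
#' (no invert, factor 1, sigma 0, clip 0) the output is bit-identical to the
#' input.
#'
#' @param frame a [new_frame()] object.
#' @param spec a [preproc_spec()].
#' @return the preprocessed `fish_frame` (same timestamp and id).
#' @export
preprocess <- function(frame, spec) {
  stopifnot(inherits(frame, "fish_frame"), inherits(spec, "preproc_spec"))
  px <- frame$pixels
  if (spec$downsample > min(dim(px))) {
    stopf("downsample factor %d exceeds image size %dx%d",
          spec$downsample, nrow(px), ncol(px))
  }
  if (spec$invert) px <- frame$range_max - px
  if (spec$downsample > 1L) px <- block_downsample(px, spec$downsample)
  clip <- function(m) { m[m < spec$clip_level] <- 0; m }
  if (spec$clip_before_blur) {
    px <- gauss_blur(clip(px), spec$blur_sigma)
  } else {
    px <- clip(gauss_blur(px, spec$blur_sigma))
  }
  out <- frame
  out$pixels <- px
  out
}

# Block-average downsampling; trailing rows/columns are dropped.
block_downsample <- function(px, f) {
  nr <- (nrow(px) %/% f) * f
  nc <- (ncol(px) %/% f) * f
  px <- px[seq_len(nr), seq_len(nc), drop = FALSE]
  # sum over f x f blocks via row then column aggregation
  rsum <- rowsum(px, rep(seq_len(nr %/% f), each = f))
  csum <- t(rowsum(t(rsum), rep(seq_len(nc %/% f), each = f)))
  csum / (f * f)
}

#' Background model for freely-swimming tracking
#'
#' The background is a mean image built from the first `n_init_frames` and
#' afterwards updated as an exponential moving average
#' `mean <- (1 - alpha) * mean + alpha * frame` with
#' `alpha = dt / time_constant` (dt from frame timestamps), clamped to
#' \code{[0, 1]} so irregular frame intervals stay stable.
#'
#' @param time_constant update time constant in seconds (> 0).
#' @param n_init_frames number of frames averaged arithmetically before the
#'   exponential regime starts.
#' @return an object of class `background_model`.
#' @export
background_model <- function(time_constant = 10, n_init_frames = 10L) {
  if (time_constant <= 0) stopf("time_constant must be > 0")
  n_init_frames <- as.integer(n_init_frames)
  if (n_init_frames < 1L) stopf("n_init_frames must be >= 1")
  structure(
    list(mean_image = NULL, time_constant = time_constant,
         n_init_frames = n_init_frames, n_seen = 0L, last_t = NA_real_),
    class = "background_model"
  )
}

#' Update the background model with one frame
#'
#' @param model a [background_model()].
#' @param frame a `fish_frame` with the same shape as the model (after the
#'   first frame fixes the shape).
#' @return the updated `background_model`.
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "background_model"), inherits(frame, "fish_frame"))
  px <- frame$pixels
  if (is.null(model$mean_image)) {
    model$mean_image <- px
    model$n_seen <- 1L
    model$last_t <- frame$t
    return(model)
  }
  if (!identical(dim(model$mean_image), dim(px))) {
    stopf("frame shape %dx%d does not match background %dx%d",
          nrow(px), ncol(px), nrow(model$mean_image), ncol(model$mean_image))
  }
  if (model$n_seen < model$n_init_frames) {
    n <- model$n_seen
    model$mean_image <- (model$mean_image * n + px) / (n + 1)
  } else {
    dt <- frame$t - model$last_t
    alpha <- min(max(dt / model$time_constant, 0), 1)
    model$mean_image <- (1 - alpha) * model$mean_image + alpha * px
  }
  model$n_seen <- model$n_seen + 1L
  model$last_t <- frame$t
  model
}

#' Foreground of a frame against the background model
#'
#' Returns `max(mean_image - frame, 0)`: only pixels darker than the
#' background are non-zero, so a dark fish on a bright arena appears as a
#' bright blob on zero.
#'
#' @param model an initialized [background_model()].
#' @param frame a `fish_frame`.
#' @return a `fish_frame` holding the foreground image.
#' @export
foreground <- function(model, frame) {
  stopifnot(inherits(model, "background_model"), inherits(frame, "fish_frame"))
  if (is.null(model$mean_image)) stopf("background model is not initialized")
  if (!identical(dim(model$mean_image), dim(frame$pixels))) {
    stopf("frame shape does not match background")
  }
  out <- frame
  out$pixels <- pmax(model$mean_image - frame$pixels, 0)
  out
}
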