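# Shared numeric helpers.
#
# Coordinate convention used throughout the package: a pixel is addressed by
# (x, y) where x is the 0-based column index and y the 0-based row index,
# origin at the top-left corner. A direction angle theta corresponds to the
# unit displacement (cos(theta), sin(theta)) in (x, y). All angles are radians.

#' Sample an image with bilinear interpolation
#'
#' Values outside the image evaluate to 0; use [in_frame()] to detect
#' out-of-bounds queries when 0 is a meaningful intensity.
#'
#' @param px numeric matrix (rows = y, columns = x).
#' @param x,y numeric vectors of 0-based sample coordinates.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(px, x, y) {
  h <- nrow(px)
  w <- ncol(px)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  val_at <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    if (any(ok)) v[ok] <- px[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  val_at(x0, y0) * (1 - fx) * (1 - fy) +
    val_at(x0 + 1, y0) * fx * (1 - fy) +
    val_at(x0, y0 + 1) * (1 - fx) * fy +
    val_at(x0 + 1, y0 + 1) * fx * fy
}

#' @keywords internal
in_frame <- function(px, x, y) {
  x >= 0 & x <= ncol(px) - 1 & y >= 0 & y <= nrow(px) - 1
}

#' Separable Gaussian blur with edge replication
#' @param px numeric matrix.
#' @param sigma kernel standard deviation in pixels; 0 is the identity.
#' @keywords internal
gauss_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_rows <- function(m) {
    n <- nrow(m)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      ii <- pmin(pmax(idx + (j - r - 1L), 1L), n)
      out <- out + k[j] * m[ii, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(px))))
}

#' Wrap an angle difference to (-pi, pi]
#' @keywords internal
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a <= 0] <- a[a <= 0] + 2 * pi
  a - pi
}

#' Fold an orientation (axial angle) to [0, pi)
#' @keywords internal
fold_pi <- function(a) {
  a %% pi
}

#' Unwrap an axial angle against a reference, then fold back
#'
#' Returns the representative of `a` (mod pi) closest to `ref`, i.e. the
#' continuation of an orientation trace without pi-jumps.
#' @keywords internal
unwrap_axial <- function(a, ref) {
  ref + wrap_pi_half(a - ref)
}

#' @keywords internal
wrap_pi_half <- function(d) {
  ((d + pi / 2) %% pi) - pi / 2
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
stopf <- function(...) stop(sprintf(...), call. = FALSE)
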