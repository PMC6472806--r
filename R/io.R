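# Frame sources and configuration files. Frames can be read from a
# directory of numbered images (ASCII PGM always; PNG when the `png`
# package is available) with timestamps synthesized at a constant rate, or
# from plain-text matrices. Configuration is a flat JSON document mirroring
# the on-disk parameter layout.

#' Write a frame as ASCII PGM (P2)
#' @param frame a `fish_frame`.
#' @param path output file.
#' @export
write_pgm <- function(frame, path) {
  px <- round(pmin(pmax(frame$pixels, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)), "255"), con)
  write(t(px), con, ncolumns = ncol(px))
  invisible(path)
}

#' Read an ASCII PGM (P2) frame
#' @param path input file.
#' @param t,frame_id frame metadata.
#' @return a `fish_frame`.
#' @export
read_pgm <- function(path, t = 0, frame_id = 0L) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stopf("'%s' is not an ASCII PGM (P2) file", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stopf("PGM pixel count mismatch in '%s'", path)
  new_frame(matrix(vals, h, w, byrow = TRUE), t = t, frame_id = frame_id,
            range_max = as.numeric(toks[4]))
}

#' Read a directory of numbered frames
#'
#' Files are ordered by name; timestamps are synthesized at a constant rate.
#' Supports ASCII PGM out of the box and grayscale PNG when the `png`
#' package is installed.
#'
#' @param dir directory of `.pgm` / `.png` files.
#' @param fps frame rate used to synthesize timestamps.
#' @return list of `fish_frame`s.
#' @export
read_frames_dir <- function(dir, fps = 300) {
  files <- sort(list.files(dir, pattern = "\\.(pgm|png)$", full.names = TRUE))
  if (length(files) == 0L) stopf("no frames found in '%s'", dir)
  lapply(seq_along(files), function(i) {
    f <- files[i]
    if (grepl("\\.png$", f)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        stopf("reading PNG frames requires the 'png' package")
      }
      a <- png::readPNG(f)
      if (length(dim(a)) == 3L) a <- a[, , 1]
      new_frame(a * 255, t = (i - 1) / fps, frame_id = i - 1L)
    } else {
      read_pgm(f, t = (i - 1) / fps, frame_id = i - 1L)
    }
  })
}

#' Read a JSON configuration file
#'
#' Returns a [param_tree()] so that every configured value read during a run
#' is recorded for the metadata audit.
#'
#' @param path JSON file with flat or nested parameter groups (e.g. a
#'   `preprocessing` block holding [preproc_spec()] fields).
#' @return a `param_tree`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  flat <- unlist_config(vals)
  param_tree(flat)
}

unlist_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
      out <- c(out, unlist_config(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}
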