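#' Corrosion-front trace
#'
#' Time series of the corrosion-front length extracted from (or
#' simulated for) a droplet time-lapse: `s(t) = r(t0) - r(t)`, the
#' distance the front has advanced under the polymer from the initial
#' protected radius.
#'
#' @param t times, minutes, strictly increasing.
#' @param s front lengths, px (or mm if `mm_per_px` supplied and
#'   applied by the caller), same length as `t`, finite, `s[1] >= 0`.
#' @param r optional per-frame protected radii (px) as measured.
#' @param r0 initial protected radius, px.
#' @param mm_per_px optional pixel calibration; absent means pixel
#'   units.
#' @return A data frame of class `front_trace` with columns `t`, `s`
#'   (and `r` if given) and attributes `r0`, `mm_per_px`.
#' @export
front_trace <- function(t, s, r = NULL, r0 = NULL, mm_per_px = NULL) {
  if (length(t) != length(s))
    stopf("front_trace: t and s must have equal length (%d vs %d)",
          length(t), length(s))
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stopf("front_trace: t must be finite and strictly increasing")
  if (any(!is.finite(s)))
    stopf("front_trace: s must be finite")
  if (s[1] < 0)
    stopf("front_trace: s must start >= 0, got s[1] = %g", s[1])
  out <- data.frame(t = t, s = s)
  if (!is.null(r)) out$r <- r
  attr(out, "r0") <- r0
  attr(out, "mm_per_px") <- mm_per_px
  class(out) <- c("front_trace", "data.frame")
  out
}

#' Binarization rule for corroded-pixel segmentation
#'
#' The image analysis classifies a pixel as corroded (black) when its
#' grayscale value is at or below the contrast margin — a pure global
#' threshold, "up to and equal to" the margin, with no morphological
#' cleanup by default.
#'
#' @param margin contrast margin on the 0-255 grayscale, default 90.
#' @param grayscale grayscale convention: `"rec601"` (luminance
#'   0.299 R + 0.587 G + 0.114 B, rounded; default) or `"mean"` (channel
#'   average, rounded).
#' @return An object of class `binarization_rule`.
#' @export
binarization_rule <- function(margin = 90, grayscale = c("rec601", "mean")) {
  check_number(margin, "margin", 0, upper = 255)
  grayscale <- match.arg(grayscale)
  structure(list(margin = margin, grayscale = grayscale),
            class = "binarization_rule")
}

# RGB array (h x w x 3, 0-255) -> rounded integer grayscale matrix.
rgb_to_gray <- function(frame, grayscale = "rec601") {
  w <- switch(grayscale,
              rec601 = c(0.299, 0.587, 0.114),
              mean = rep(1 / 3, 3),
              stopf("unknown grayscale convention '%s'", grayscale))
  round(w[1] * frame[, , 1] + w[2] * frame[, , 2] + w[3] * frame[, , 3])
}

#' Threshold a frame into a corroded-pixel mask
#'
#' @param frame an 8-bit RGB raster: numeric array `h x w x 3` with
#'   integer values in 0-255.
#' @param rule a [binarization_rule()].
#' @return An integer matrix; 1 where grayscale <= margin
#'   (corroded/black), 0 elsewhere.
#' @export
binarize <- function(frame, rule = binarization_rule()) {
  stopifnot(inherits(rule, "binarization_rule"))
  if (length(dim(frame)) != 3 || dim(frame)[3] != 3)
    stopf("binarize: frame must be an h x w x 3 RGB array")
  if (any(frame < 0) || any(frame > 255) || any(frame != round(frame)))
    stopf(paste0("binarize: frame is not 8-bit (expected integer values ",
                 "in 0-255; rescale e.g. 0-1 PNG data by 255)"))
  gray <- rgb_to_gray(frame, rule$grayscale)
  mask <- matrix(0L, nrow(gray), ncol(gray))
  mask[gray <= rule$margin] <- 1L
  mask
}

#' Circular region of interest
#'
#' The droplet region analysed in each frame.  Default analyses the full
#' frame; a tight circle covering the corroded annulus excludes the
#' bright background from the pixel count.
#'
#' @param center pixel coordinates (row, col) of the circle center.
#' @param radius radius in px, > 0.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center, radius) {
  stopifnot(length(center) == 2)
  check_number(radius, "radius", 0, strict_lower = TRUE)
  structure(list(center = center, radius = radius), class = "circular_roi")
}

roi_mask <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  stopifnot(inherits(roi, "circular_roi"))
  dy2 <- (seq_len(dims[1]) - roi$center[1])^2
  dx2 <- (seq_len(dims[2]) - roi$center[2])^2
  outer(dy2, dx2, `+`) <= roi$radius^2
}

# Remove isolated corroded pixels: a 1-pixel with fewer than `min_nb`
# corroded 8-neighbours is reset to 0.  Optional despeckle behind a
# flag; the default analysis applies the bare threshold.
despeckle <- function(mask, min_nb = 2) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  nb <- matrix(0L, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- nb + pad[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  }
  out <- mask
  out[mask == 1L & nb < min_nb] <- 0L
  out
}

#' Protected radius from a corroded-pixel mask
#'
#' Counts black (corroded) pixels inside the region of interest,
#' subtracts from the total, and derives the radius of the equivalent
#' circular protected area: `A = total - black`, `r = sqrt(A / pi)`.
#' A fully corroded region gives `r = 0`.
#'
#' @param mask binary mask from [binarize()].
#' @param roi optional [circular_roi()]; default uses the full frame.
#' @return Radius in px.
#' @export
estimate_radius <- function(mask, roi = NULL) {
  if (length(mask) == 0) stopf("estimate_radius: empty mask")
  keep <- roi_mask(roi, dim(mask))
  total <- sum(keep)
  black <- sum(mask[keep])
  A <- total - black
  sqrt(A / pi)
}

#' Extract a corrosion-front trace from a time-lapse series
#'
#' Binarizes each frame, derives the protected radius by pixel counting,
#' and reports the front length `s(t) = r(t_1) - r(t)`.  Values are
#' returned raw (unsmoothed); under noise `s` may decrease or go
#' slightly negative, which downstream fits handle.  Set
#' `isotonic = TRUE` to project the trace onto nondecreasing values
#' (pool-adjacent-violators via [stats::isoreg()]) before fitting.
#'
#' @param series a `frame_series` from [render_frames()], a list of
#'   frames, or a character vector of PNG/TIFF paths (read with
#'   [read_frames()]).
#' @param times frame times in minutes (taken from the series if
#'   absent).
#' @param rule a [binarization_rule()].
#' @param roi optional [circular_roi()].
#' @param clean apply the optional despeckle filter before counting.
#' @param isotonic project `s` onto a nondecreasing sequence.
#' @return A [front_trace()] with columns `t`, `s`, `r` and a
#'   `provenance` attribute recording margin, grayscale convention and
#'   roi.
#' @export
extract_front_trace <- function(series, times = NULL,
                                rule = binarization_rule(), roi = NULL,
                                clean = FALSE, isotonic = FALSE) {
  if (is.character(series)) series <- read_frames(series)
  if (inherits(series, "frame_series")) {
    if (is.null(times)) times <- series$t
    frames <- series$frames
  } else frames <- series
  if (length(frames) < 2)
    stopf("extract_front_trace: need >= 2 frames, got %d", length(frames))
  if (is.null(times))
    stopf("extract_front_trace: frame timestamps are missing")
  if (length(times) != length(frames))
    stopf("extract_front_trace: %d frames but %d timestamps",
          length(frames), length(times))
  dims <- dim(frames[[1]])
  r <- vapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (!identical(dim(f), dims))
      stopf("extract_front_trace: frame %d has dimensions %s, expected %s",
            i, paste(dim(f), collapse = "x"), paste(dims, collapse = "x"))
    m <- binarize(f, rule)
    if (clean) m <- despeckle(m)
    estimate_radius(m, roi)
  }, 0)
  s <- r[1] - r
  if (isotonic) s <- stats::isoreg(times, s)$yf
  out <- front_trace(t = times, s = s, r = r, r0 = r[1])
  attr(out, "provenance") <- list(margin = rule$margin,
                                  grayscale = rule$grayscale,
                                  roi = roi, clean = clean,
                                  isotonic = isotonic)
  out
}

#' Read a time-lapse series from PNG or TIFF files
#'
#' @param paths character vector of PNG file paths, or a single
#'   multi-page TIFF path.
#' @return A list of integer 0-255 RGB arrays.
#' @export
read_frames <- function(paths) {
  read_one <- function(img) {
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    a <- round(img * 255)
    storage.mode(a) <- "integer"
    a
  }
  if (length(paths) == 1 && grepl("\\.tiff?$", paths, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    return(lapply(pages, read_one))
  }
  lapply(paths, function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) read_one(png::readPNG(p))
    else if (grepl("\\.tiff?$", p, ignore.case = TRUE))
      read_one(tiff::readTIFF(p))
    else stopf("read_frames: unsupported format: %s", p)
  })
}

#' Write a frame series to disk
#'
#' Filenames carry the zero-padded frame index and the timestamp in
#' minutes, e.g. `frame_0007_t000030min.png`.
#'
#' @param series a `frame_series` from [render_frames()].
#' @param dir output directory (created if needed).
#' @param format `"png"` (one file per frame) or `"tiff"` (single
#'   multi-page file `frames.tiff`).
#' @return Invisibly, the written paths.
#' @export
write_frames <- function(series, dir, format = c("png", "tiff")) {
  stopifnot(inherits(series, "frame_series"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- lapply(series$frames, function(f) {
    a <- f / 255
    storage.mode(a) <- "double"
    a
  })
  if (format == "tiff") {
    path <- file.path(dir, "frames.tiff")
    tiff::writeTIFF(norm, path)
    return(invisible(path))
  }
  paths <- vapply(seq_along(norm), function(i) {
    p <- file.path(dir, sprintf("frame_%04d_t%06dmin.png", i,
                                as.integer(round(series$t[i]))))
    png::writePNG(norm[[i]], p)
    p
  }, "")
  invisible(paths)
}

#' Write / read a front trace as CSV
#'
#' Columns `t_min`, `r_px` (when present), `s_px`; a JSON provenance
#' sidecar (margin, grayscale convention, roi) is written alongside when
#' the trace carries provenance.
#'
#' @param trace a [front_trace()].
#' @param path CSV path.
#' @return `write_front_trace` invisibly returns `path`;
#'   `read_front_trace` returns a [front_trace()].
#' @export
write_front_trace <- function(trace, path) {
  df <- data.frame(t_min = trace$t)
  if (!is.null(trace$r)) df$r_px <- trace$r
  df$s_px <- trace$s
  write.csv(df, path, row.names = FALSE)
  prov <- attr(trace, "provenance")
  if (!is.null(prov)) {
    prov$roi <- if (is.null(prov$roi)) NULL else unclass(prov$roi)
    jsonlite::write_json(prov, sub("\\.csv$", "_provenance.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_front_trace
#' @export
read_front_trace <- function(path) {
  df <- read.csv(path)
  for (col in c("t_min", "s_px"))
    if (!col %in% names(df))
      stopf("read_front_trace: %s is missing required column '%s'",
            path, col)
  front_trace(t = df$t_min, s = df$s_px,
              r = if ("r_px" %in% names(df)) df$r_px else NULL)
}
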