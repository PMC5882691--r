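#' Binary image frame with physical calibration
#'
#' A `binary_frame` wraps a logical pixel grid together with the physical
#' pixel size (mm per pixel side) and an acquisition timestamp (hours).
#' All downstream statistics (densities, areas, chord lengths) are reported
#' in physical units derived from `px_size_mm`.
#'
#' @param pixels logical matrix; `TRUE` = vessel (foreground).
#' @param px_size_mm side length of one pixel in mm (default 0.0064,
#'   i.e. 6.4 um pixels).
#' @param t_h timestamp in hours.
#' @return an object of class `binary_frame`.
#' @export
binary_frame <- function(pixels, px_size_mm = 0.0064, t_h = 0) {
  if (is.numeric(pixels)) {
    pixels <- matrix(pixels != 0, nrow = nrow(pixels), ncol = ncol(pixels))
  }
  if (!is.matrix(pixels) || !is.logical(pixels) || length(pixels) == 0) {
    stop_invalid("pixels must be a non-empty logical matrix")
  }
  if (!is.numeric(px_size_mm) || length(px_size_mm) != 1 || px_size_mm <= 0) {
    stop_invalid("px_size_mm must be a positive scalar")
  }
  structure(list(pixels = pixels, px_size_mm = px_size_mm, t_h = t_h),
            class = "binary_frame")
}

#' @export
print.binary_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<binary_frame> %d x %d px, %.4f mm/px, t = %.3g h, density %.4f\n",
              d[1], d[2], x$px_size_mm, x$t_h, mean(x$pixels)))
  invisible(x)
}

#' Vessel (foreground) density of a frame
#'
#' Fraction of pixels that are foreground, i.e. detected vessel area over
#' total image area.
#'
#' @param frame a [binary_frame()].
#' @return density in \[0, 1\].
#' @export
frame_density <- function(frame) {
  mean(frame$pixels)
}

#' Threshold a grayscale image into a binary vessel frame
#'
#' Converts a grayscale intensity grid into a binary frame.  In bright-field
#' imagery vessels are darker than the background, so by default pixels
#' *below* the threshold become foreground; set `dark_vessels = FALSE` to
#' invert.  The automatic method is Otsu's between-class variance criterion.
#'
#' @param gray numeric matrix of intensities.
#' @param method `"otsu"` (automatic) or `"manual"`.
#' @param level threshold intensity, required for `method = "manual"`;
#'   must lie within the observed intensity range.
#' @param dark_vessels logical; `TRUE` (default) marks pixels darker than
#'   the threshold as vessel.
#' @param px_size_mm,t_h physical calibration passed to [binary_frame()].
#' @return a [binary_frame()].
#' @export
threshold_frame <- function(gray, method = c("otsu", "manual"), level = NULL,
                            dark_vessels = TRUE, px_size_mm = 0.0064, t_h = 0) {
  method <- match.arg(method)
  if (!is.matrix(gray) || !is.numeric(gray) || length(gray) == 0) {
    stop_invalid("gray must be a non-empty numeric matrix")
  }
  rng <- range(gray)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      stop_degenerate("constant image: Otsu threshold is undefined")
    }
    level <- EBImage::otsu(EBImage::Image(gray), range = rng, levels = 256L)
  } else {
    if (is.null(level) || !is.numeric(level) || length(level) != 1) {
      stop_invalid("manual thresholding requires a scalar level")
    }
    if (level < rng[1] || level > rng[2]) {
      warning(sprintf("level %g outside intensity range [%g, %g]",
                      level, rng[1], rng[2]), call. = FALSE)
    }
  }
  fg <- if (dark_vessels) gray < level else gray > level
  binary_frame(fg, px_size_mm = px_size_mm, t_h = t_h)
}

#' Write / read a binary frame as an 8-bit PNG
#'
#' Frames are stored as single-channel 8-bit PNGs with 0 = background and
#' 255 = vessel.  Physical calibration is not stored in the file; supply it
#' again when reading.
#'
#' @param frame a [binary_frame()].
#' @param path file path.
#' @return `write_frame_png` returns `path` invisibly; `read_frame_png`
#'   returns a [binary_frame()].
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$pixels * 1.0, target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @param px_size_mm,t_h calibration to attach to the frame read back.
#' @export
read_frame_png <- function(path, px_size_mm = 0.0064, t_h = 0) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  binary_frame(x > 0.5, px_size_mm = px_size_mm, t_h = t_h)
}
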