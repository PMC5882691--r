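#' Box-counting fractal dimension of a binary pattern
#'
#' Covers the image with aligned square grids of side `s` for a geometric
#' series of box sizes and counts boxes containing at least one foreground
#' pixel.  The dimension estimate is minus the slope of the least-squares
#' line of log(count) against log(s).  The default series doubles from
#' `min_box` and appends `max_box` itself if it is not a power of two
#' (e.g. 2, 4, 8, ..., 128, 200), the canonical "power series" choice.
#'
#' @param frame a [binary_frame()] with at least one foreground pixel.
#' @param min_box,max_box smallest and largest box side in pixels;
#'   `max_box` must not exceed the smaller image dimension.
#' @param offsets number of random grid offsets to average per box size
#'   (0 = single grid anchored at the image origin, the default).
#' @param seed seed used when `offsets > 0`.
#' @return an object of class `fractal_estimate`: list with `d_f`,
#'   `box_sizes_px`, `counts` and `r2` of the log-log fit.
#' @export
box_counting_dimension <- function(frame, min_box = 2, max_box = 200,
                                   offsets = 0, seed = 1) {
  stopifnot(inherits(frame, "binary_frame"))
  fg <- which(frame$pixels, arr.ind = TRUE)
  if (nrow(fg) == 0) stop_undefined("empty frame: fractal dimension undefined")
  d <- dim(frame$pixels)
  if (max_box > min(d)) stop_invalid("max_box exceeds image dimensions")
  if (min_box < 1 || max_box <= min_box) stop_invalid("need 1 <= min_box < max_box")
  sizes <- box_size_series(min_box, max_box)
  if (length(sizes) < 3) stop_invalid("fewer than 3 box sizes; widen the range")

  count_for <- function(s, off_r = 0, off_c = 0) {
    br <- (fg[, 1] - 1 + off_r) %/% s
    bc <- (fg[, 2] - 1 + off_c) %/% s
    length(unique(br * 1e6 + bc))
  }
  if (offsets > 0) {
    counts <- withr::with_seed(seed, {
      vapply(sizes, function(s) {
        orr <- sample.int(s, offsets, replace = TRUE) - 1L
        occ <- sample.int(s, offsets, replace = TRUE) - 1L
        mean(mapply(count_for, s = s, off_r = orr, off_c = occ))
      }, numeric(1))
    })
  } else {
    counts <- vapply(sizes, count_for, numeric(1))
  }
  fit <- lm(log(counts) ~ log(sizes))
  structure(list(d_f = -unname(coef(fit)[2]),
                 box_sizes_px = sizes, counts = counts,
                 r2 = summary(fit)$r.squared),
            class = "fractal_estimate")
}

box_size_series <- function(min_box, max_box) {
  s <- min_box
  sizes <- c()
  while (s <= max_box) {
    sizes <- c(sizes, s)
    s <- s * 2
  }
  if (tail(sizes, 1) != max_box) sizes <- c(sizes, max_box)
  sizes
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> D_f = %.3f (R^2 = %.4f, %d box sizes)\n",
              x$d_f, x$r2, length(x$box_sizes_px)))
  invisible(x)
}
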