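#' Frame stack container
#'
#' A movie as a list of `H x W x 3` numeric arrays with channel intensities
#' in [0, 255] (channel order fixed R, G, B) plus the frame interval in
#' seconds (0.03 s for the chromatophore actuation movies).
#'
#' @param frames List of `H x W x 3` arrays, identical dimensions.
#' @param interval Seconds per frame.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, interval = 0.03) {
  if (length(frames) == 0L) {
    abort("A frame stack needs at least one frame.",
          class = "chromatophore_input_error")
  }
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, integer(1)) != 3L) ||
      any(vapply(dims, function(d) d[3] != 3L, logical(1)))) {
    abort("Each frame must be an H x W x 3 array.",
          class = "chromatophore_input_error")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort("All frames must share the same dimensions.",
          class = "chromatophore_input_error")
  }
  structure(list(frames = frames, interval = interval),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.3g s/frame\n",
              length(x$frames), d[1], d[2], x$interval))
  invisible(x)
}

#' Read a frame stack from PNG or TIFF files
#'
#' Loads a lexicographically ordered directory of single-frame images (or
#' an explicit file vector). Pixel values are rescaled to 0-255; 16-bit
#' TIFF input is supported via the same [0, 1] decoding that the readers
#' provide. Channel order is normalized to R, G, B.
#'
#' @param files Directory path or character vector of PNG/TIFF paths.
#' @param interval Seconds per frame.
#' @return A [frame_stack()].
#' @export
read_frames <- function(files, interval = 0.03) {
  if (length(files) == 1L && dir.exists(files)) {
    files <- sort(list.files(files, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
  }
  if (length(files) == 0L) {
    abort("No frame files found.", class = "chromatophore_input_error")
  }
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 2L) {                 # grayscale -> replicate
      img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    }
    img[, , 1:3, drop = FALSE] * 255
  })
  frame_stack(frames, interval)
}

#' Rectangular region of interest
#'
#' @param row,col Top-left pixel (1-based).
#' @param height,width Extent in pixels (default 20 x 20, the standard
#'   measurement window).
#' @return An object of class `roi`.
#' @export
roi <- function(row, col, height = 20, width = 20) {
  stopifnot(row >= 1, col >= 1, height >= 1, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

#' Mean RGB over a fixed ROI, per frame
#'
#' The core measurement of the color-dynamics analysis: for every frame,
#' the arithmetic mean of each channel over a fixed pixel window. Means are
#' computed in floating point with no rounding.
#'
#' @param stack A [frame_stack()].
#' @param region A [roi()]; must lie fully inside the frame.
#' @return A tibble of class `roi_trace` with `frame`, `time_s`, `R`, `G`,
#'   `B` (floats in [0, 255]); `time_s = (frame - 1) * interval`.
#' @export
roi_mean_rgb <- function(stack, region) {
  stopifnot(inherits(stack, "frame_stack"), inherits(region, "roi"))
  d <- dim(stack$frames[[1]])
  r2 <- region$row + region$height - 1L
  c2 <- region$col + region$width - 1L
  if (r2 > d[1] || c2 > d[2]) {
    abort(sprintf(
      "ROI rows %d-%d, cols %d-%d exceed the %dx%d frame.",
      region$row, r2, region$col, c2, d[1], d[2]),
      class = "chromatophore_input_error")
  }
  rows <- region$row:r2; cols <- region$col:c2
  means <- t(vapply(stack$frames, function(fr) {
    c(mean(fr[rows, cols, 1]), mean(fr[rows, cols, 2]),
      mean(fr[rows, cols, 3]))
  }, numeric(3)))
  out <- tibble(frame = seq_len(nrow(means)),
                time_s = (seq_len(nrow(means)) - 1) * stack$interval,
                R = means[, 1], G = means[, 2], B = means[, 3])
  class(out) <- c("roi_trace", class(out))
  out
}

#' Dominant channel per frame
#'
#' Labels each frame by its argmax channel; exact ties resolve by the fixed
#' priority R > G > B (noted in a message when they occur).
#'
#' @param trace An `roi_trace` tibble (columns `R`, `G`, `B`).
#' @return The trace with a `dominant` factor column (levels R, G, B).
#' @export
dominant_channel_timeline <- function(trace) {
  stopifnot(all(c("R", "G", "B") %in% names(trace)), nrow(trace) > 0)
  m <- as.matrix(trace[, c("R", "G", "B")])
  idx <- apply(m, 1L, which.max)  # which.max takes the first = R > G > B
  ties <- apply(m, 1L, function(x) sum(x == max(x)) > 1L)
  if (any(ties)) {
    inform(sprintf("%d frame(s) had tied channels; priority R > G > B applied.",
                   sum(ties)))
  }
  trace$dominant <- factor(c("R", "G", "B")[idx], levels = c("R", "G", "B"))
  trace
}

#' ROI trace of a synthetic expanding-disc movie
#'
#' End-to-end harness: generates a synthetic movie with [make_movie()] and
#' measures the ROI trace, deterministically for a fixed seed.
#'
#' @param config A [synthetic_movie_config()].
#' @param region A [roi()]; default centers the standard 20 x 20 window on
#'   the disc.
#' @param seed Integer seed.
#' @return An `roi_trace` tibble; the movie's ground-truth color timeline
#'   is attached as attribute `ground_truth`.
#' @export
trace_from_synthetic_movie <- function(config = synthetic_movie_config(),
                                       region = NULL, seed = 1L) {
  movie <- make_movie(config, seed = seed)
  if (is.null(region)) {
    d <- dim(movie$frames[[1]])
    region <- roi(row = floor(d[1] / 2) - 9L, col = floor(d[2] / 2) - 9L)
  }
  trace <- roi_mean_rgb(movie, region)
  attr(trace, "ground_truth") <- attr(movie, "ground_truth")
  trace
}
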