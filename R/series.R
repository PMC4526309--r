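#' Dynamic image series
#'
#' Container for a dynamic contrast-enhanced acquisition: a stack of 2D
#' frames (the first one pre-contrast) with their acquisition times. All
#' downstream kinetic and texture analysis operates on enhancement, i.e.
#' on differences relative to the pre-contrast frame, so the absolute
#' intensity scale of the frames is immaterial.
#'
#' @param frames numeric 3D array, `height x width x n_frames`; frame 1 is
#'   the pre-contrast acquisition.
#' @param times numeric vector of acquisition times in seconds, one per
#'   frame, strictly increasing. Defaults to a 60 s grid starting at 0.
#' @return An object of class `dynamic_series` with elements `frames` and
#'   `times`.
#' @examples
#' s <- dynamic_series(array(0, c(4, 4, 6)))
#' dim(s$frames)
#' @export
dynamic_series <- function(frames, times = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (height x width x time)")
  nt <- dim(frames)[3L]
  if (nt < 2L) stop("a dynamic series needs at least 2 frames")
  if (is.null(times)) times <- (seq_len(nt) - 1) * 60
  times <- as.numeric(times)
  if (length(times) != nt) stop("`times` must have one entry per frame")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing")
  structure(list(frames = frames, times = times), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %d x %d pixels, %d frames (t = %s s)\n",
              d[1], d[2], d[3], paste(format(x$times, trim = TRUE), collapse = ", ")))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3L]

frame_dim <- function(series) dim(series$frames)[1:2]

assert_series <- function(series) {
  if (!inherits(series, "dynamic_series"))
    stop("expected a `dynamic_series` object")
  invisible(series)
}

# Validate a logical mask against a series' frame lattice.
assert_mask <- function(mask, series = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (!is.null(series) && !identical(dim(mask), frame_dim(series)))
    stop("mask shape does not match the series frames")
  invisible(mask)
}

#' Binary region-of-interest mask
#'
#' Tags a logical matrix with a mask kind so that pipeline stages can
#' state what they expect (a manually drawn lesion, a healthy-tissue
#' region, the small kinetic ROI, the rectangular search region of the
#' automated segmentation, or an automatically segmented lesion).
#'
#' @param pixels logical matrix on the frame lattice.
#' @param kind one of `"manual_lesion"`, `"healthy_tissue"`,
#'   `"small_kinetic"`, `"rectangle"`, `"auto_lesion"`.
#' @return The logical matrix with a `"kind"` attribute and class
#'   `roi_mask`.
#' @export
roi_mask <- function(pixels,
                     kind = c("manual_lesion", "healthy_tissue",
                              "small_kinetic", "rectangle", "auto_lesion")) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1, NA))) stop("mask values must be 0/1")
    pixels <- array(pixels != 0, dim(pixels))
  }
  structure(pixels, kind = kind, class = c("roi_mask", class(pixels)))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask:%s> %d x %d, %d pixels set\n",
              attr(x, "kind") %||% "?", nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Rectangular ROI covering a sub-grid
#'
#' @param dim frame dimensions `c(height, width)`.
#' @param rows,cols integer ranges of the rectangle (defaults: all).
#' @return A `roi_mask` of kind `"rectangle"`.
#' @export
rect_mask <- function(dim, rows = seq_len(dim[1]), cols = seq_len(dim[2])) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  roi_mask(m, "rectangle")
}
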