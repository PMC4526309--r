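#' Subtraction image
#'
#' Enhancement image for one post-contrast frame: the post-contrast frame
#' minus the pre-contrast frame. The sign convention is post minus pre so
#' that enhancing tissue is positive; non-enhancing background cancels
#' out, which is why texture analysis is performed on this image. The
#' default is the second post-contrast frame, the usual enhancement peak
#' of malignant breast lesions.
#'
#' @param series a [dynamic_series()].
#' @param post_index which post-contrast frame to subtract (1 = first
#'   post-contrast). Default 2.
#' @return A list of class `subtracted_image`: `pixels` (matrix, AU) and
#'   `source_frame_index` (the frame used, counting the pre-contrast frame
#'   as 1).
#' @examples
#' s <- dynamic_series(array(rep(0:5, each = 16), c(4, 4, 6)))
#' subtract_image(s)$pixels[1, 1]  # frame 3 minus frame 1 = 2
#' @export
subtract_image <- function(series, post_index = 2L) {
  assert_series(series)
  post_index <- as.integer(post_index)
  nt <- n_frames(series)
  if (is.na(post_index) || post_index < 1L || post_index > nt - 1L)
    stop(sprintf("`post_index` must be in 1..%d (number of post-contrast frames)",
                 nt - 1L))
  frame <- post_index + 1L
  structure(
    list(pixels = series$frames[, , frame] - series$frames[, , 1L],
         source_frame_index = frame),
    class = "subtracted_image")
}

#' ROI signal-time curve
#'
#' Mean enhancement over a region of interest at every frame, relative to
#' the pre-contrast frame (so the curve starts at 0 by construction).
#' Kinetic analysis conventionally uses a small ROI of more than nine
#' pixels placed on the most enhancing part of the lesion; a smaller mask
#' is allowed but flagged.
#'
#' @param series a [dynamic_series()].
#' @param mask logical matrix selecting the ROI pixels.
#' @param min_pixels minimum recommended ROI size (default 10).
#' @param strict if `TRUE`, an ROI at or below `min_pixels - 1` pixels is
#'   an error instead of a warning.
#' @return A list of class `kinetic_curve`: `times` (s) and `signal`
#'   (mean enhancement, AU), plus `n_pixels`.
#' @export
roi_curve <- function(series, mask, min_pixels = 10L, strict = FALSE) {
  assert_series(series)
  assert_mask(mask, series)
  n <- sum(mask)
  if (n == 0L) stop("empty ROI mask")
  if (n < min_pixels) {
    msg <- sprintf("ROI has only %d pixels (fewer than %d)", n, min_pixels)
    if (strict) stop(msg) else warning(msg)
  }
  nt <- n_frames(series)
  base <- mean(series$frames[, , 1L][mask])
  signal <- vapply(seq_len(nt),
                   function(t) mean(series$frames[, , t][mask]) - base,
                   numeric(1))
  structure(list(times = series$times, signal = signal, n_pixels = n),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> %d points over %d px ROI\n",
              length(x$times), x$n_pixels))
  print(data.frame(time_s = x$times, signal_au = x$signal), row.names = FALSE)
  invisible(x)
}

# OLS slope of y on x in closed form; NA when x is degenerate.
ols_slope <- function(x, y) {
  mx <- mean(x); sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / sxx
}

#' Semi-quantitative kinetic parameters
#'
#' The three curve descriptors of breast DCE kinetics:
#' * **amplitude** — maximum enhancement over the post-contrast points;
#' * **wash-in** — up-slope between the enhancement peak and the
#'   preceding time point, in AU/s;
#' * **wash-out** — ordinary-least-squares slope over the final three
#'   (time, signal) points, in AU/s (signed: positive for a rising tail,
#'   negative for true wash-out).
#'
#' Ties at the peak resolve to the earliest frame.
#'
#' @param curve a [roi_curve()] result, or any list with numeric `times`
#'   and `signal` of equal length (at least 4 points; the wash-out fit
#'   needs 3 trailing points after the baseline).
#' @return A list of class `kinetic_params` with `amplitude` (AU),
#'   `wash_in` (AU/s), `wash_out` (AU/s), and `peak_index` (frame number,
#'   counting the pre-contrast frame as 1, hence always >= 2).
#' @examples
#' kp <- kinetic_params(list(times = c(0, 60, 120, 180, 240, 300),
#'                           signal = c(0, 50, 80, 70, 65, 60)))
#' kp$amplitude  # 80
#' kp$wash_in    # (80 - 50) / 60 = 0.5
#' kp$wash_out   # -0.0833...
#' @export
kinetic_params <- function(curve) {
  times <- curve$times; signal <- curve$signal
  n <- length(times)
  if (n < 4L) stop("kinetic parameters need at least 4 time points")
  if (length(signal) != n) stop("`times` and `signal` lengths differ")
  post <- signal[-1L]
  peak <- which.max(post) + 1L          # earliest max among post-contrast
  amplitude <- signal[peak]
  wash_in <- (signal[peak] - signal[peak - 1L]) /
    (times[peak] - times[peak - 1L])
  tail_idx <- (n - 2L):n
  wash_out <- ols_slope(times[tail_idx], signal[tail_idx])
  structure(list(amplitude = amplitude, wash_in = wash_in,
                 wash_out = wash_out, peak_index = peak),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> amplitude %.3g AU (peak frame %d), wash-in %.3g AU/s, wash-out %.3g AU/s\n",
              x$amplitude, x$peak_index, x$wash_in, x$wash_out))
  invisible(x)
}

#' Per-pixel kinetic maps
#'
#' Applies the kinetic-parameter definitions to the single-pixel
#' enhancement curve of every pixel in a region, producing amplitude and
#' wash-in maps (the inputs of the automated lesion segmentation).
#' Pixels outside the region are `NA`.
#'
#' @param series a [dynamic_series()].
#' @param rect logical matrix selecting the region (e.g. a rectangle
#'   covering the breast); `NULL` means the whole frame.
#' @return A list of class `kinetic_maps` with matrices `amplitude`,
#'   `wash_in` and integer matrix `peak_index`.
#' @export
kinetic_maps <- function(series, rect = NULL) {
  assert_series(series)
  d <- frame_dim(series)
  if (is.null(rect)) rect <- matrix(TRUE, d[1], d[2])
  assert_mask(rect, series)
  if (!any(rect)) stop("empty region for kinetic maps")
  nt <- n_frames(series)
  idx <- which(rect)
  # npix x nt enhancement matrix
  E <- vapply(seq_len(nt),
              function(t) series$frames[, , t][idx] - series$frames[, , 1L][idx],
              numeric(length(idx)))
  E <- matrix(E, nrow = length(idx))
  post <- E[, -1L, drop = FALSE]
  peak <- max.col(post, ties.method = "first") + 1L
  amp <- post[cbind(seq_along(idx), peak - 1L)]
  prev <- E[cbind(seq_along(idx), peak - 1L)]
  win <- (amp - prev) / (series$times[peak] - series$times[peak - 1L])
  out <- lapply(list(amp, win, peak), function(v) {
    m <- matrix(NA_real_, d[1], d[2]); m[idx] <- v; m
  })
  structure(list(amplitude = out[[1]], wash_in = out[[2]],
                 peak_index = out[[3]]),
            class = "kinetic_maps")
}
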