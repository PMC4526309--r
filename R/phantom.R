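#' Phantom configuration
#'
#' Parameters of a synthetic single-slice dynamic series: a lesion with
#' configurable enhancement kinetics and texture heterogeneity, embedded
#' in weakly enhancing parenchyma with non-enhancing fat, plus additive
#' Gaussian noise. The enhancement curve family is piecewise linear —
#' baseline, linear rise to the configured amplitude at the peak frame,
#' then a linear tail with slope `wash_out` — so that the ground truth is
#' expressed directly in the measured parameters (amplitude, wash-in,
#' wash-out) rather than through a pharmacokinetic model.
#'
#' Texture heterogeneity is introduced by multiplying the lesion
#' enhancement by `exp` of a Gaussian random field with standard
#' deviation `texture_sigma` and correlation length
#' `lesion_texture_corr_len` (pixels), renormalised to unit mean over the
#' lesion so the mean lesion kinetics stay at their configured values.
#' Larger correlation lengths give smoother, more homogeneous lesions.
#'
#' With a positive `wash_out` (a rising tail, as is common for
#' plateau-type curves) the measured enhancement maximum moves to the
#' last frame; configure `wash_out <= 0` when the configured peak frame
#' must also be the measured peak.
#'
#' @param grid_size `c(height, width)` in pixels.
#' @param n_timepoints number of frames (1 pre-contrast + the rest
#'   post-contrast); at least 4 so the wash-out fit has 3 trailing points.
#' @param dt temporal resolution in seconds.
#' @param lesion_shape `"mass_ellipse"` (solid ellipse) or
#'   `"nonmass_patchy"` (patchy enhancement inside the ellipse).
#' @param lesion_center,lesion_radii ellipse centre and radii in pixels
#'   (row, column). Defaults: grid centre, radii 10 x 7.
#' @param lesion_kinetics named vector `c(amplitude=, wash_in=,
#'   wash_out=)` in AU, AU/s, AU/s.
#' @param peak_frame frame (counting the pre-contrast frame as 1) at
#'   which the lesion reaches its configured amplitude; default 3, the
#'   second post-contrast frame.
#' @param lesion_texture_corr_len correlation length (pixels) of the
#'   lesion texture field; 0 disables heterogeneity.
#' @param texture_sigma log-scale standard deviation of the texture
#'   field.
#' @param background_kinetics kinetic triple of the parenchyma.
#' @param fat_fraction proportion of background pixels rendered as
#'   non-enhancing fat.
#' @param noise_sd additive Gaussian noise standard deviation (AU),
#'   applied independently to every frame.
#' @param baseline pre-contrast tissue intensity (AU).
#' @param seed integer seed; every phantom is reproducible from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = c(64, 64),
                           n_timepoints = 6,
                           dt = 60,
                           lesion_shape = c("mass_ellipse", "nonmass_patchy"),
                           lesion_center = NULL,
                           lesion_radii = c(10, 7),
                           lesion_kinetics = c(amplitude = 75, wash_in = 0.72,
                                               wash_out = -0.04),
                           peak_frame = 3,
                           lesion_texture_corr_len = 1.5,
                           texture_sigma = 0.4,
                           background_kinetics = c(amplitude = 15, wash_in = 0.15,
                                                   wash_out = 0),
                           fat_fraction = 0.35,
                           noise_sd = 2,
                           baseline = 100,
                           seed = NULL) {
  lesion_shape <- match.arg(lesion_shape)
  grid_size <- as.integer(grid_size)
  n_timepoints <- as.integer(n_timepoints)
  if (length(grid_size) != 2L || any(grid_size < 4L))
    stop("`grid_size` must be two integers >= 4")
  if (n_timepoints < 4L)
    stop("`n_timepoints` must be at least 4 (the wash-out fit needs 3 trailing points)")
  if (dt <= 0) stop("`dt` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (lesion_texture_corr_len < 0) stop("`lesion_texture_corr_len` must be >= 0")
  if (fat_fraction < 0 || fat_fraction >= 1) stop("`fat_fraction` must be in [0, 1)")
  if (is.null(lesion_center)) lesion_center <- (grid_size + 1) / 2
  peak_frame <- as.integer(peak_frame)
  if (peak_frame < 2L || peak_frame > n_timepoints)
    stop("`peak_frame` must be a post-contrast frame index")
  k <- as.numeric(lesion_kinetics)
  if (length(k) != 3L || k[1] <= 0)
    stop("`lesion_kinetics` must be (amplitude > 0, wash_in, wash_out)")
  # lesion must fit inside the grid
  if (lesion_center[1] - lesion_radii[1] < 1 ||
      lesion_center[1] + lesion_radii[1] > grid_size[1] ||
      lesion_center[2] - lesion_radii[2] < 1 ||
      lesion_center[2] + lesion_radii[2] > grid_size[2])
    stop("lesion (center +/- radii) extends outside the grid")
  structure(list(grid_size = grid_size, n_timepoints = n_timepoints, dt = dt,
                 lesion_shape = lesion_shape, lesion_center = lesion_center,
                 lesion_radii = lesion_radii,
                 lesion_kinetics = setNames(k, c("amplitude", "wash_in", "wash_out")),
                 peak_frame = peak_frame,
                 lesion_texture_corr_len = lesion_texture_corr_len,
                 texture_sigma = texture_sigma,
                 background_kinetics = setNames(as.numeric(background_kinetics),
                                                c("amplitude", "wash_in", "wash_out")),
                 fat_fraction = fat_fraction, noise_sd = noise_sd,
                 baseline = baseline, seed = seed),
            class = "phantom_config")
}

# Smooth white noise to a zero-mean, unit-variance Gaussian random field
# with correlation length `corr_len` (the sd, in pixels, of the Gaussian
# smoothing kernel). Edge effects are handled by per-row kernel
# renormalisation.
gaussian_field <- function(dim, corr_len) {
  w <- matrix(rnorm(prod(dim)), dim[1], dim[2])
  if (corr_len <= 0) return(w)
  smooth1 <- function(n) {
    x <- seq_len(n)
    k <- exp(-outer(x, x, "-")^2 / (2 * corr_len^2))
    k / rowSums(k)
  }
  f <- smooth1(dim[1]) %*% w %*% t(smooth1(dim[2]))
  (f - mean(f)) / sd(as.vector(f))
}

# Piecewise-linear enhancement curve evaluated at frame times.
# Baseline 0 at frame 1; linear rise so that the step into the peak
# frame has slope `wash_in`; amplitude at `peak_frame`; tail slope
# `wash_out` afterwards.
enhancement_curve <- function(times, amplitude, wash_in, wash_out, peak_frame) {
  n <- length(times)
  s <- numeric(n)
  tp <- times[peak_frame]
  s[peak_frame] <- amplitude
  if (peak_frame > 2L) {
    pre_peak <- amplitude - wash_in * (tp - times[peak_frame - 1L])
    if (pre_peak < 0)
      stop("inconsistent lesion kinetics: amplitude - wash_in * dt is negative")
    # linear from 0 at frame 1 to pre_peak at frame peak-1
    ramp <- (times[2:(peak_frame - 1L)] - times[1]) /
      (times[peak_frame - 1L] - times[1])
    s[2:(peak_frame - 1L)] <- pre_peak * ramp
  }
  if (peak_frame < n)
    s[(peak_frame + 1L):n] <- amplitude + wash_out * (times[(peak_frame + 1L):n] - tp)
  s
}

ellipse_mask <- function(dim, center, radii) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

#' Generate a dynamic-series phantom
#'
#' Builds a synthetic single-slice dynamic series from a
#' [phantom_config()], together with its ground truth (lesion mask, true
#' per-pixel amplitude field, configured kinetic parameters). Identical
#' seeds give bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `series` (a [dynamic_series()]) and
#'   `truth` (class `ground_truth`: `lesion_mask`, `amplitude_field`,
#'   `kinetics`, `class_label`).
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("expected a `phantom_config`")
  with_seed(config$seed, {
    d <- config$grid_size
    nt <- config$n_timepoints
    times <- (seq_len(nt) - 1) * config$dt
    lesion <- ellipse_mask(d, config$lesion_center, config$lesion_radii)
    if (config$lesion_shape == "nonmass_patchy") {
      patch <- gaussian_field(d, max(config$lesion_radii) / 3)
      keep <- patch > quantile(patch[lesion], 0.35)
      lesion <- lesion & keep
      if (!any(lesion)) stop("patchy lesion degenerated to an empty mask")
    }
    # fat regions: low values of a smooth field outside the lesion
    fat <- matrix(FALSE, d[1], d[2])
    if (config$fat_fraction > 0) {
      ff <- gaussian_field(d, 4)
      bg <- !lesion
      fat[bg] <- ff[bg] < quantile(ff[bg], config$fat_fraction)
    }
    # per-pixel lesion amplitude multiplier, unit mean over the lesion
    mult <- matrix(1, d[1], d[2])
    if (config$lesion_texture_corr_len > 0 && config$texture_sigma > 0) {
      fld <- gaussian_field(d, config$lesion_texture_corr_len)
      m <- exp(config$texture_sigma * fld)
      mult <- m / mean(m[lesion])
    }
    lk <- config$lesion_kinetics
    bk <- config$background_kinetics
    lesion_curve <- enhancement_curve(times, lk["amplitude"], lk["wash_in"],
                                      lk["wash_out"], config$peak_frame)
    bg_curve <- enhancement_curve(times, bk["amplitude"], bk["wash_in"],
                                  bk["wash_out"], config$peak_frame)
    frames <- array(0, c(d, nt))
    base <- config$baseline + 10 * gaussian_field(d, 3)
    parenchyma <- !lesion & !fat
    for (t in seq_len(nt)) {
      f <- base
      f[lesion] <- f[lesion] + lesion_curve[t] * mult[lesion]
      f[parenchyma] <- f[parenchyma] + bg_curve[t]
      # fat: no enhancement
      if (config$noise_sd > 0)
        f <- f + rnorm(length(f), sd = config$noise_sd)
      frames[, , t] <- f
    }
    truth <- structure(
      list(lesion_mask = roi_mask(lesion, "manual_lesion"),
           amplitude_field = ifelse(lesion, lk["amplitude"] * mult, NA_real_),
           kinetics = structure(list(amplitude = unname(lk["amplitude"]),
                                     wash_in = unname(lk["wash_in"]),
                                     wash_out = unname(lk["wash_out"]),
                                     peak_index = config$peak_frame),
                                class = "kinetic_params"),
           fat_mask = fat,
           class_label = NA_character_),
      class = "ground_truth")
    list(series = dynamic_series(frames, times), truth = truth)
  })
}
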