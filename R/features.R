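#' Names of the 26 model parameters
#'
#' The full multi-parametric candidate set: 20 texture features, 3
#' kinetic parameters, and 3 clinical/imaging binaries (BI-RADS mass
#' enhancement, Ki67 > 14 %, hormone-receptor-negative/HER2-positive).
#'
#' @return Character vector of length 26.
#' @export
parameter_names <- function() {
  c(texture_feature_names(), "wash_in", "amplitude", "wash_out",
    "mass", "ki67_high", "hr_neg_her2_pos")
}

# Small kinetic ROI: the n most-enhancing lesion pixels on the
# amplitude map (the operational version of "a small ROI on the most
# enhancing area").
kinetic_roi <- function(series, lesion_mask, n_pixels = 12L) {
  maps <- kinetic_maps(series, lesion_mask)
  amp <- maps$amplitude
  idx <- which(lesion_mask)
  n_pixels <- min(n_pixels, length(idx))
  top <- idx[order(amp[idx], decreasing = TRUE)[seq_len(n_pixels)]]
  m <- matrix(FALSE, nrow(lesion_mask), ncol(lesion_mask))
  m[top] <- TRUE
  roi_mask(m, "small_kinetic")
}

#' Texture and kinetic features of one lesion
#'
#' Computes the 20 texture features on the subtraction image within the
#' lesion mask, and the 3 kinetic parameters from the signal-time curve
#' of a small ROI over the most enhancing lesion pixels.
#'
#' @param series a [dynamic_series()].
#' @param lesion_mask logical lesion mask.
#' @param kinetic_mask optional explicit small ROI; default: the
#'   `n_kinetic_pixels` most-enhancing lesion pixels.
#' @param bits grey-level depth of the texture quantization.
#' @param post_index post-contrast frame used for the subtraction image.
#' @param n_kinetic_pixels size of the automatic kinetic ROI.
#' @return Named numeric vector of 23 features (20 texture + wash_in,
#'   amplitude, wash_out).
#' @export
extract_features <- function(series, lesion_mask, kinetic_mask = NULL,
                             bits = 5, post_index = 2L,
                             n_kinetic_pixels = 12L) {
  assert_series(series)
  assert_mask(lesion_mask, series)
  if (!any(lesion_mask)) stop("empty lesion mask")
  sub <- subtract_image(series, post_index)
  tex <- texture_features(sub, lesion_mask, bits = bits)
  if (is.null(kinetic_mask))
    kinetic_mask <- kinetic_roi(series, lesion_mask, n_kinetic_pixels)
  curve <- suppressWarnings(roi_curve(series, kinetic_mask))
  kp <- kinetic_params(curve)
  c(tex, wash_in = kp$wash_in, amplitude = kp$amplitude,
    wash_out = kp$wash_out)
}

#' Per-patient feature table of a cohort
#'
#' Runs feature extraction over every patient of a synthetic cohort and
#' assembles the 26-parameter table used by the mono-parametric
#' statistics and the multi-parametric classifiers. Lesion masks come
#' either from the ground truth or from the automated segmentation.
#'
#' @param cohort an `nac_cohort` from [generate_cohort()].
#' @param segment use [segment_lesion()] instead of the ground-truth
#'   mask (slower); default `FALSE`.
#' @param seg_params a [segmentation_params()] (when `segment = TRUE`).
#' @param bits texture grey-level depth.
#' @return A data.frame with `patient_id`, `response`, the 26 parameters
#'   of [parameter_names()] (binaries as 0/1), and `subtype`.
#' @export
build_feature_table <- function(cohort, segment = FALSE,
                                seg_params = segmentation_params(seed = 1),
                                bits = 5) {
  if (!inherits(cohort, "nac_cohort")) stop("expected an `nac_cohort`")
  rows <- lapply(cohort, function(p) {
    mask <- if (segment) segment_lesion(p$series, params = seg_params)
    else p$truth$lesion_mask
    f <- extract_features(p$series, mask, bits = bits)
    cbind(p$record[c("patient_id", "response", "subtype")],
          as.data.frame(as.list(f)),
          data.frame(mass = as.numeric(p$record$mass),
                     ki67_high = as.numeric(p$record$ki67_high),
                     hr_neg_her2_pos = as.numeric(p$record$hr_neg_her2_pos)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
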