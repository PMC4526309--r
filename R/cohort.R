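#' Default biomarker probabilities
#'
#' Conditional probabilities of the molecular subtype and binary markers
#' given response class, as estimated from the observed frequencies of a
#' 69-patient invasive-ductal-carcinoma cohort (19 non-responders, 50
#' partial/complete responders). The subtype is a categorical draw; the
#' binary markers (ER, PgR, Ki67 > 14 %, HER2, BI-RADS mass enhancement)
#' are drawn independently given the class. Partial and complete
#' responders share the pooled responder frequencies.
#'
#' @return A named list with elements `NR`, `PR`, `CR`, each containing
#'   `subtype` (named probability vector summing to 1), and scalars `er`,
#'   `pgr`, `ki67_high`, `her2`, `mass`.
#' @export
default_biomarker_probs <- function() {
  subtype_names <- c("LuminalA", "LuminalB/HER2-", "LuminalB/HER2+",
                     "NonLuminal/HER2+", "TripleNegative")
  nr <- list(subtype = setNames(c(8, 4, 3, 1, 3) / 19, subtype_names),
             er = 15 / 19, pgr = 14 / 19, ki67_high = 11 / 19,
             her2 = 4 / 19, mass = 12 / 19)
  resp <- list(subtype = setNames(c(5, 21, 12, 9, 3) / 50, subtype_names),
               er = 37 / 50, pgr = 28 / 50, ki67_high = 41 / 50,
               her2 = 22 / 50, mass = 27 / 50)
  list(NR = nr, PR = resp, CR = resp)
}

#' Default per-class lesion effects
#'
#' Mean lesion parameters by response class for the synthetic cohort.
#' Non-responding lesions are generated *more homogeneous* (larger
#' texture correlation length) with *lower* wash-in and amplitude than
#' responding lesions; responders share one setting. The directions
#' mirror the group differences the analysis is designed to detect; the
#' magnitudes are a design choice of the generator (see the package
#' vignette).
#'
#' @return A named list with elements `NR`, `PR`, `CR`, each a list with
#'   `amplitude` (AU), `wash_in` (AU/s), `wash_out` (AU/s) and
#'   `corr_len` (pixels).
#' @export
default_class_effect <- function() {
  resp <- list(amplitude = 75, wash_in = 0.75, wash_out = -0.04, corr_len = 1.2)
  list(NR = list(amplitude = 68, wash_in = 0.55, wash_out = -0.04, corr_len = 3.0),
       PR = resp, CR = resp)
}

#' Cohort configuration
#'
#' @param n_nr,n_pr,n_cr patient counts per response class (defaults
#'   19 / 36 / 14).
#' @param class_effect per-class mean lesion parameters, see
#'   [default_class_effect()].
#' @param biomarker_probs conditional biomarker probabilities given
#'   class, see [default_biomarker_probs()].
#' @param grid_size phantom grid, `c(height, width)`.
#' @param noise_sd additive noise sd (AU) of each phantom.
#' @param jitter_sd relative between-patient variability (log-normal sd)
#'   applied to amplitude, wash-in and correlation length.
#' @param seed master integer seed for the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nr = 19, n_pr = 36, n_cr = 14,
                          class_effect = default_class_effect(),
                          biomarker_probs = default_biomarker_probs(),
                          grid_size = c(48, 48),
                          noise_sd = 2,
                          jitter_sd = 0.10,
                          seed = NULL) {
  counts <- c(n_nr, n_pr, n_cr)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("patient counts must be non-negative integers")
  check_probs <- function(p, who) {
    vals <- c(p$er, p$pgr, p$ki67_high, p$her2, p$mass, p$subtype)
    if (any(vals < 0 | vals > 1))
      stop(sprintf("biomarker probabilities for %s must be in [0, 1]", who))
    if (abs(sum(p$subtype) - 1) > 1e-8)
      stop(sprintf("subtype probabilities for %s must sum to 1", who))
  }
  for (cl in c("NR", "PR", "CR")) check_probs(biomarker_probs[[cl]], cl)
  structure(list(n_nr = as.integer(n_nr), n_pr = as.integer(n_pr),
                 n_cr = as.integer(n_cr), class_effect = class_effect,
                 biomarker_probs = biomarker_probs,
                 grid_size = as.integer(grid_size), noise_sd = noise_sd,
                 jitter_sd = jitter_sd, seed = seed),
            class = "cohort_config")
}

#' Sample biomarkers for one patient
#'
#' Draws the molecular subtype from its class-conditional categorical
#' distribution and the binary markers independently given the class.
#' `hr_neg_her2_pos` (hormone-receptor negative, HER2 positive) is
#' derived from the subtype.
#'
#' @param class_label `"NR"`, `"PR"` or `"CR"`.
#' @param biomarker_probs see [default_biomarker_probs()].
#' @return A list: `subtype`, `er`, `pgr`, `ki67_high`, `her2`, `mass`
#'   (logical), `hr_neg_her2_pos` (logical).
#' @export
sample_biomarkers <- function(class_label, biomarker_probs = default_biomarker_probs()) {
  p <- biomarker_probs[[class_label]]
  if (is.null(p)) stop("unknown class label: ", class_label)
  if (any(unlist(p) < 0 | unlist(p) > 1)) stop("probabilities must be in [0, 1]")
  subtype <- sample(names(p$subtype), 1L, prob = p$subtype)
  draw <- function(q) runif(1) < q
  list(subtype = subtype,
       er = draw(p$er), pgr = draw(p$pgr), ki67_high = draw(p$ki67_high),
       her2 = draw(p$her2), mass = draw(p$mass),
       hr_neg_her2_pos = subtype %in% c("NonLuminal/HER2+", "TripleNegative") &
         subtype == "NonLuminal/HER2+")
}

#' Generate a synthetic labelled cohort
#'
#' Generates one phantom dynamic series per patient with class-dependent
#' lesion parameters (non-responders more homogeneous, with lower
#' wash-in) and class-conditional biomarkers. Class labels are fixed by
#' the configuration, not sampled. All randomness flows from the single
#' master seed; identical seeds give identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list of class `nac_cohort`; each element is a list with
#'   `record` (one-row data.frame), `series` and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("expected a `cohort_config`")
  labels <- rep(c("NR", "PR", "CR"), times = c(config$n_nr, config$n_pr, config$n_cr))
  if (length(labels) == 0L) stop("empty cohort")
  with_seed(config$seed, {
    patients <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      cl <- labels[i]
      eff <- config$class_effect[[cl]]
      jit <- function(x) x * exp(rnorm(1, 0, config$jitter_sd))
      amplitude <- jit(eff$amplitude)
      wash_in <- min(jit(eff$wash_in), 0.95 * amplitude / 60)
      corr_len <- jit(eff$corr_len)
      radii <- c(round(runif(1, 8, 11)), round(runif(1, 5, 8)))
      bio <- sample_biomarkers(cl, config$biomarker_probs)
      shape <- if (bio$mass) "mass_ellipse" else "nonmass_patchy"
      pc <- phantom_config(grid_size = config$grid_size,
                           lesion_shape = shape,
                           lesion_radii = radii,
                           lesion_kinetics = c(amplitude = amplitude,
                                               wash_in = wash_in,
                                               wash_out = eff$wash_out),
                           lesion_texture_corr_len = corr_len,
                           noise_sd = config$noise_sd,
                           seed = NULL)
      ph <- generate_phantom(pc)
      ph$truth$class_label <- cl
      record <- data.frame(patient_id = sprintf("P%03d", i), response = cl,
                           subtype = bio$subtype, er = bio$er, pgr = bio$pgr,
                           ki67_high = bio$ki67_high, her2 = bio$her2,
                           mass = bio$mass,
                           hr_neg_her2_pos = bio$hr_neg_her2_pos,
                           stringsAsFactors = FALSE)
      patients[[i]] <- list(record = record, series = ph$series, truth = ph$truth)
    }
    structure(patients, class = "nac_cohort", config = config)
  })
}

#' @export
print.nac_cohort <- function(x, ...) {
  tab <- table(vapply(x, function(p) p$record$response, character(1)))
  cat(sprintf("<nac_cohort> %d patients (%s)\n", length(x),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cohort patient table
#'
#' Collapses a cohort into one data.frame of patient records (the CSV
#' written by the pipeline).
#'
#' @param cohort an `nac_cohort` from [generate_cohort()].
#' @return A data.frame with columns patient_id, response, subtype, er,
#'   pgr, ki67_high, her2, mass, hr_neg_her2_pos.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}
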