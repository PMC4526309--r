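sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read and write dynamic series as NIfTI
#'
#' A dynamic series is stored as one 3D NIfTI-1 file per patient with
#' the frame index on the third axis, plus a small JSON sidecar
#' (`<name>.json`) carrying the acquisition times. When the sidecar is
#' absent, a default 60 s grid is applied with a warning.
#'
#' @param series a [dynamic_series()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param times optional explicit times (seconds) overriding the
#'   sidecar.
#' @return `read_dynamic_series()` returns a [dynamic_series()];
#'   `write_dynamic_series()` returns `path` invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  assert_series(series)
  RNifti::writeNifti(RNifti::asNifti(series$frames), path)
  jsonlite::write_json(list(times_s = series$times), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path, times = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume (height x width x time); got ",
         length(dim(arr)), "D")
  if (is.null(times)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      times <- jsonlite::read_json(sc, simplifyVector = TRUE)$times_s
    } else {
      warning("no timing sidecar found; assuming a 60 s frame grid")
    }
  }
  dynamic_series(arr, times)
}

#' Read and write binary masks as NIfTI
#'
#' Masks are stored as 2D NIfTI-1 volumes with 0/1 voxels.
#'
#' @param mask logical matrix (or [roi_mask()]).
#' @param path file path.
#' @param kind mask kind assigned on read, see [roi_mask()].
#' @return `read_mask()` returns a [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, kind = "manual_lesion") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 2L && all(d[-(1:2)] == 1L)) d <- d[1:2]
  if (length(d) != 2L) stop("expected a 2D mask volume")
  roi_mask(matrix(as.numeric(img), d[1], d[2]) != 0, kind)
}

#' Read and write feature tables as CSV
#'
#' Comma-separated UTF-8 with a header row; unknown columns are
#' preserved. Reading validates that any requested feature columns are
#' present and free of missing values, reporting offending cells
#' explicitly.
#'
#' @param table data.frame (e.g. from [build_feature_table()]).
#' @param path file path.
#' @param required columns that must exist (default none).
#' @return `read_feature_table()` returns a data.frame.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, required = character()) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in intersect(required, names(tab))) {
    bad <- which(is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("missing value(s) in column '%s', row(s) %s", col,
                   paste(bad, collapse = ", ")))
  }
  tab
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences the stages end to end: cohort simulation, lesion masks
#' (ground truth or automated segmentation), feature extraction,
#' per-feature ROC analysis, contingency statistics of the binary
#' markers, and LOOCV evaluation of a chosen multi-parametric model.
#' All outputs are written to `out_dir` as CSV/JSON, together with a
#' manifest recording the configuration and master seed; a rerun with
#' the same seed is byte-identical.
#'
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param cohort a [cohort_config()] (its `seed` is overridden by
#'   `seed`).
#' @param segment use automated segmentation for the lesion masks.
#' @param model_features feature subset of the evaluated model.
#' @param classifier `"kmeans"` or `"logistic"`.
#' @param bits texture grey-level depth.
#' @param seed master seed for the whole run.
#' @return A list (invisibly) with `cohort_table`, `features`,
#'   `roc_table`, `associations`, `model_eval`.
#' @export
run_pipeline <- function(out_dir = NULL, cohort = cohort_config(),
                         segment = FALSE,
                         model_features = c("inv_diff_moment", "gln",
                                            "lrhge", "wash_in"),
                         classifier = c("kmeans", "logistic"),
                         bits = 5, seed = 1) {
  classifier <- match.arg(classifier)
  cohort$seed <- seed
  coh <- generate_cohort(cohort)
  ctab <- cohort_table(coh)
  feats <- build_feature_table(coh, segment = segment,
                               seg_params = segmentation_params(seed = seed),
                               bits = bits)
  numeric_feats <- c(texture_feature_names(), "wash_in", "amplitude", "wash_out")
  labels <- feats$response == "NR"
  roc_table <- do.call(rbind, lapply(numeric_feats, function(f) {
    r <- roc_analysis(feats[[f]], labels)
    data.frame(feature = f, auc = r$auc, p = r$p_vs_half, cutoff = r$cutoff,
               se = r$se, sp = r$sp, direction = r$direction,
               stringsAsFactors = FALSE)
  }))
  associations <- do.call(rbind, lapply(
    c("mass", "ki67_high", "hr_neg_her2_pos"), function(f) {
      present <- feats[[f]] == 1
      tab <- rbind(c(sum(present & labels), sum(present & !labels)),
                   c(sum(!present & labels), sum(!present & !labels)))
      data.frame(feature = f, p_midp = fisher_midp(tab)$p_value,
                 stringsAsFactors = FALSE)
    }))
  model_eval <- loocv(feats, model_features, method = classifier, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(ctab, file.path(out_dir, "cohort.csv"))
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    write_feature_table(roc_table, file.path(out_dir, "roc.csv"))
    write_feature_table(associations, file.path(out_dir, "associations.csv"))
    jsonlite::write_json(
      list(model = list(features = model_features, classifier = classifier,
                        se = model_eval$se, sp = model_eval$sp,
                        accuracy = model_eval$accuracy)),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, segment = segment, bits = bits,
           classifier = classifier, model_features = model_features,
           n_patients = nrow(ctab),
           package_version = as.character(utils::packageVersion("texnac"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(list(cohort_table = ctab, features = feats, roc_table = roc_table,
                 associations = associations, model_eval = model_eval))
}
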