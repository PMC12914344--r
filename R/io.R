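# Volume and configuration I/O. Volumes travel as NIfTI with the package
# axis convention (z, y, x) stored directly as the array dimensions and
# spacing as pixdim; a JSON sidecar carries the ROI label table and
# per-case covariates.

#' Read / write a scalar volume as NIfTI
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: list with `grid` (3-D array) and `spacing`
#'   (numeric length 3, mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop(sprintf("malformed NIfTI file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  grid <- array(as.numeric(img), dim(img))
  list(grid = grid, spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' @rdname read_volume
#' @param grid 3-D numeric array.
#' @param spacing Voxel spacing (mm), length 3.
#' @export
write_volume <- function(grid, spacing, path) {
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a phantom as NIfTI + JSON sidecar
#'
#' Writes `<stem>_ct.nii.gz` (intensity), `<stem>_labels.nii.gz`
#' (unsigned-integer label volume; overlapping ROIs resolved by the
#' structure-map painting order) and `<stem>.json` (ROI label table with
#' one bit-mask file per ROI not being needed at this scale, spacing,
#' anticoagulant flag and prescription assignment).
#'
#' @param phantom A `phantom`.
#' @param stem Output path stem.
#' @return The sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, stem) {
  write_volume(phantom$intensity, phantom$spacing,
               paste0(stem, "_ct.nii.gz"))
  rois <- intersect(structure_roi_order, names(phantom$masks))
  labels <- array(0L, dim(phantom$intensity))
  for (i in seq_along(rois)) labels[phantom$masks[[rois[i]]]] <- i
  write_volume(labels, phantom$spacing, paste0(stem, "_labels.nii.gz"))
  side <- list(
    patient_id = phantom$patient_id,
    spacing_mm = phantom$spacing,
    roi_labels = stats::setNames(as.list(seq_along(rois)), rois),
    anticoagulant_use = phantom$anticoagulant_use,
    dual_gradient = isTRUE(phantom$dual_gradient),
    ptv2_dose_cgy = phantom$ptv2_dose,
    seed = phantom$seed
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ct <- read_volume(paste0(stem, "_ct.nii.gz"))
  lab <- read_volume(paste0(stem, "_labels.nii.gz"))
  masks <- lapply(side$roi_labels, function(i) lab$grid == i)
  # label painting resolves overlaps; restore nesting supersets
  if (!is.null(masks$rectum_wall)) {
    masks$rectum <- masks$rectum | masks$rectum_wall
  }
  for (nm in names(side$roi_labels)) masks$body <- masks$body | masks[[nm]]
  structure(list(
    intensity = ct$grid, masks = masks, spacing = ct$spacing,
    patient_id = side$patient_id,
    anticoagulant_use = as.integer(side$anticoagulant_use),
    dual_gradient = isTRUE(side$dual_gradient),
    ptv2_dose = if (is.null(side$ptv2_dose_cgy)) NA_real_ else side$ptv2_dose_cgy,
    seed = side$seed
  ), class = "phantom")
}

#' Pipeline configuration
#'
#' One object tying together the cohort, engine, predictor, dosimetry,
#' NTCP and decision settings of an end-to-end run; round-trips
#' losslessly through YAML.
#'
#' @param n_cases,seed,fraction_dual_gradient,anticoagulant_prevalence,anatomy_variability
#'   Cohort settings (see [cohort_spec()]).
#' @param predictor_enabled Train/evaluate the learned dose predictor;
#'   when `FALSE`, engine doses stand in for predictions (useful for
#'   pipeline plumbing checks).
#' @param predictor Named list of [predictor_config()] overrides.
#' @param k_folds Cross-validation folds when the predictor is enabled.
#' @param alpha_beta Rectum alpha/beta ratio (Gy) for EQD2.
#' @param step1_threshold,step2_threshold Decision thresholds (percent /
#'   percentage points).
#' @param out_dir Output directory.
#' @param cache Reuse cached intermediates in `out_dir` when present.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_cases = 8L, seed = 1L,
                            fraction_dual_gradient = 0.35,
                            anticoagulant_prevalence = 0.25,
                            anatomy_variability = 1,
                            predictor_enabled = FALSE,
                            predictor = list(), k_folds = 5L,
                            alpha_beta = 3,
                            step1_threshold = 10, step2_threshold = 10,
                            out_dir = tempfile("rtdecide_run_"),
                            cache = TRUE) {
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    fraction_dual_gradient = fraction_dual_gradient,
    anticoagulant_prevalence = anticoagulant_prevalence,
    anatomy_variability = anatomy_variability,
    predictor_enabled = isTRUE(predictor_enabled),
    predictor = predictor, k_folds = as.integer(k_folds),
    alpha_beta = alpha_beta,
    step1_threshold = step1_threshold, step2_threshold = step2_threshold,
    out_dir = out_dir, cache = isTRUE(cache)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
  cfg
}
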