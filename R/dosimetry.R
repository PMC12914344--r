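# DVH construction, dose-volume metrics, fractionation correction, and
# the prescription-normalised mean absolute error.

as_dose_array <- function(dose) {
  if (inherits(dose, "dose_map")) dose$dose else dose
}

#' Cumulative dose-volume histogram
#'
#' Exact voxel counting at each bin edge: the curve starts at 100\% at
#' 0 cGy, is non-increasing, and reaches 0\% above the maximum dose.
#' Binned curves are for reporting; metric computations
#' ([v_at_dose()], [d_max()]) always use exact counting so no model input
#' inherits binning error.
#'
#' @param dose A `dose_map` or 3-D numeric array (cGy).
#' @param mask Logical array, non-empty, same shape.
#' @param bin_width Bin width in cGy (default 10).
#' @param roi Optional ROI name used in error messages and output.
#' @return A tibble of class `rt_dvh` with columns `dose_cgy` and
#'   `volume_pct`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 10, roi = "ROI") {
  d <- as_dose_array(dose)
  stopifnot(identical(dim(d), dim(mask)), bin_width > 0)
  if (!any(mask)) stop(sprintf("ROI '%s' mask is empty", roi), call. = FALSE)
  dv <- d[mask]
  edges <- seq(0, max(dv) + bin_width, by = bin_width)
  vol <- vapply(edges, function(e) 100 * mean(dv >= e), numeric(1))
  vol[1] <- 100  # every voxel receives >= 0 cGy
  out <- tibble::tibble(roi = roi, dose_cgy = edges, volume_pct = vol)
  class(out) <- c("rt_dvh", class(out))
  out
}

#' Relative volume receiving at least a threshold dose (V_D)
#'
#' @param dose A `dose_map` or array (cGy).
#' @param mask Logical array, non-empty.
#' @param threshold Dose threshold in cGy (closed lower bound, `>=`).
#' @param roi Optional name for error messages.
#' @return Percent of ROI volume in `[0, 100]`, by exact voxel counting.
#' @export
v_at_dose <- function(dose, mask, threshold, roi = "ROI") {
  d <- as_dose_array(dose)
  stopifnot(identical(dim(d), dim(mask)))
  if (!any(mask)) stop(sprintf("ROI '%s' mask is empty", roi), call. = FALSE)
  100 * mean(d[mask] >= threshold)
}

#' Maximum dose within an ROI
#'
#' @inheritParams v_at_dose
#' @return Maximum voxel dose in cGy.
#' @export
d_max <- function(dose, mask, roi = "ROI") {
  d <- as_dose_array(dose)
  stopifnot(identical(dim(d), dim(mask)))
  if (!any(mask)) stop(sprintf("ROI '%s' mask is empty", roi), call. = FALSE)
  max(d[mask])
}

#' Fractionation parameters for the EQD2 transform
#'
#' @param n_fractions Number of fractions the physical dose is delivered
#'   in (default 25).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (default 3, the
#'   standard late-toxicity value for rectum).
#' @param reference_dose_per_fraction Reference fraction size in Gy
#'   (fixed at 2 for EQD2).
#' @return Object of class `fractionation_params`.
#' @export
fractionation_params <- function(n_fractions = 25L, alpha_beta = 3,
                                 reference_dose_per_fraction = 2) {
  stopifnot(n_fractions > 0, alpha_beta > 0, reference_dose_per_fraction > 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 alpha_beta = alpha_beta,
                 reference_dose_per_fraction = reference_dose_per_fraction),
            class = "fractionation_params")
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic fractionation correction: a voxel with physical dose
#' D Gy delivered in n fractions (fraction size d = D/n) maps to
#' `EQD2 = D * (d + alpha/beta) / (ref + alpha/beta)`. The transform is
#' the identity at d = 2 Gy per fraction and amplifies doses delivered at
#' larger fraction sizes.
#'
#' @param dose A `dose_map` or array in cGy (physical dose).
#' @param params A [fractionation_params()].
#' @return Same type as the input, in 2-Gy-equivalent cGy.
#' @export
eqd2_transform <- function(dose, params = fractionation_params()) {
  stopifnot(inherits(params, "fractionation_params"))
  d <- as_dose_array(dose)
  gy <- d / 100
  dpf <- gy / params$n_fractions
  eq <- gy * (dpf + params$alpha_beta) /
    (params$reference_dose_per_fraction + params$alpha_beta)
  out <- eq * 100
  if (inherits(dose, "dose_map")) {
    dose$dose <- out
    dose
  } else out
}

#' Rectum-wall V6300cGy after fractionation correction
#'
#' The sole dosimetric input of the logistic rectal-bleeding NTCP model:
#' the percent of rectum-wall volume whose fractionation-corrected (EQD2)
#' dose reaches 6300 cGy.
#'
#' @param dose A `dose_map` (physical cGy).
#' @param phantom A `phantom` with a `rectum_wall` mask.
#' @param params A [fractionation_params()].
#' @param threshold Threshold in 2-Gy-equivalent cGy (default 6300).
#' @return Percent of rectum-wall volume.
#' @export
v6300_rectum_wall <- function(dose, phantom, params = fractionation_params(),
                              threshold = 6300) {
  mask <- phantom$masks$rectum_wall
  if (is.null(mask)) stop("phantom lacks a rectum_wall mask", call. = FALSE)
  v_at_dose(eqd2_transform(dose, params), mask, threshold, roi = "rectum_wall")
}

#' Prescription-normalised mean absolute dose error
#'
#' Per case j the error is `(1/M) * sum_i |D_pred(i) - D_gt(i)| /
#' prescription_dose * 100` over the M voxels of the ROI; the cohort value
#' is the unweighted mean of per-case errors (a two-level average, so
#' cases with different ROI volumes weigh equally).
#'
#' @param pred,gt A `dose_map`/array, or a list of them (one per case).
#' @param mask Logical array or list of arrays (the ROI per case).
#' @param prescription_dose Normalising dose in cGy, `> 0`.
#' @param case_ids Optional case identifiers for error messages.
#' @return Cohort MAE in percent of the prescription dose.
#' @export
dose_mae <- function(pred, gt, mask, prescription_dose, case_ids = NULL) {
  stopifnot(prescription_dose > 0)
  if (!is.list(pred) || inherits(pred, "dose_map")) pred <- list(pred)
  if (!is.list(gt) || inherits(gt, "dose_map")) gt <- list(gt)
  if (!is.list(mask)) mask <- list(mask)
  n <- length(pred)
  stopifnot(length(gt) == n, length(mask) == n)
  if (is.null(case_ids)) case_ids <- as.character(seq_len(n))
  per_case <- vapply(seq_len(n), function(j) {
    p <- as_dose_array(pred[[j]]); g <- as_dose_array(gt[[j]])
    m <- mask[[j]]
    stopifnot(identical(dim(p), dim(g)), identical(dim(p), dim(m)))
    if (!any(m)) {
      stop(sprintf("empty ROI in case '%s'", case_ids[j]), call. = FALSE)
    }
    mean(abs(p[m] - g[m])) / prescription_dose * 100
  }, numeric(1))
  mean(per_case)
}

#' Export a DVH curve to CSV
#' @param dvh An `rt_dvh` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  utils::write.csv(dvh[, c("dose_cgy", "volume_pct")], path, row.names = FALSE)
  invisible(path)
}
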