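# Two-step modality selection: photon NTCP gate, then delta-NTCP rule.

#' Decision thresholds for the two-step selection rule
#'
#' Step 1 examines the photon NTCP: if it does not exceed
#' `step1_ntcp_threshold` percent, photon therapy is selected outright and
#' the proton plan is never evaluated. Otherwise step 2 compares the
#' modalities: proton is chosen only when the photon-minus-proton NTCP
#' difference exceeds `step2_delta_threshold` percentage points.
#' Both comparators are strict ("exceeds") by default and can be flipped
#' to closed bounds for sensitivity analyses.
#'
#' @param step1_ntcp_threshold Percent (default 10).
#' @param step2_delta_threshold Percentage points (default 10).
#' @param step1_strict,step2_strict Use strict `>` comparisons
#'   (defaults `TRUE`, following the rule text "exceeds 10\%" /
#'   "photon if delta <= 10\%").
#' @return Object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(step1_ntcp_threshold = 10,
                                step2_delta_threshold = 10,
                                step1_strict = TRUE, step2_strict = TRUE) {
  stopifnot(step1_ntcp_threshold >= 0, step2_delta_threshold >= 0)
  structure(list(step1_ntcp_threshold = step1_ntcp_threshold,
                 step2_delta_threshold = step2_delta_threshold,
                 step1_strict = step1_strict, step2_strict = step2_strict),
            class = "decision_thresholds")
}

exceeds <- function(x, threshold, strict) {
  if (strict) x > threshold else x >= threshold
}

#' Apply the two-step proton/photon decision rule
#'
#' The proton NTCP may be supplied as a value or as a zero-argument
#' function (deferred provider): the provider is only invoked when step 1
#' passes the case on to step 2, mirroring a workflow where the proton
#' plan or prediction is only produced when needed.
#'
#' @param ntcp_photon Photon NTCP in percent, in `[0, 100]`.
#' @param ntcp_proton Proton NTCP in percent, or a function returning it.
#' @param thresholds A [decision_thresholds()].
#' @param case_id Optional identifier carried into the record.
#' @return One-row tibble (`decision_record`): case_id, ntcp_photon,
#'   ntcp_proton (NA when never evaluated), delta_ntcp, modality
#'   (`"photon"`/`"proton"`), deciding_step (1 or 2).
#' @examples
#' decide(8)                                  # photon at step 1
#' decide(25, 10)                             # delta 15 > 10 -> proton
#' @export
decide <- function(ntcp_photon, ntcp_proton = NULL,
                   thresholds = decision_thresholds(), case_id = NA_character_) {
  if (!is.finite(ntcp_photon) || ntcp_photon < 0 || ntcp_photon > 100) {
    stop("ntcp_photon must be a percent in [0, 100]", call. = FALSE)
  }
  rec <- function(np, delta, modality, step) {
    tibble::new_tibble(list(case_id = case_id, ntcp_photon = ntcp_photon,
                            ntcp_proton = np, delta_ntcp = delta,
                            modality = modality, deciding_step = step),
                       nrow = 1L)
  }
  if (!exceeds(ntcp_photon, thresholds$step1_ntcp_threshold,
               thresholds$step1_strict)) {
    return(rec(NA_real_, NA_real_, "photon", 1L))
  }
  np <- if (is.function(ntcp_proton)) {
    tryCatch(ntcp_proton(), error = function(e) {
      stop(sprintf("proton NTCP provider failed for case '%s': %s",
                   case_id, conditionMessage(e)), call. = FALSE)
    })
  } else ntcp_proton
  if (is.null(np) || !is.finite(np)) {
    stop(sprintf("proton NTCP required at step 2 for case '%s'", case_id),
         call. = FALSE)
  }
  delta <- ntcp_photon - np
  if (exceeds(delta, thresholds$step2_delta_threshold, thresholds$step2_strict)) {
    rec(np, delta, "proton", 2L)
  } else {
    rec(np, delta, "photon", 2L)
  }
}

#' Decide a whole cohort from an NTCP table
#'
#' @param ntcp_tbl Tibble with columns `case_id`, `modality`
#'   (`"photon"`/`"proton"`) and `ntcp` (probability in `[0, 1]`), e.g.
#'   rows of [ntcp_record()].
#' @param thresholds A [decision_thresholds()].
#' @return A `decision_record` tibble, one row per case. Proton NTCP is
#'   consumed lazily per case (only for cases passing step 1); both
#'   modality rows may be present for all cases regardless.
#' @export
decide_cohort <- function(ntcp_tbl, thresholds = decision_thresholds()) {
  stopifnot(all(c("case_id", "modality", "ntcp") %in% names(ntcp_tbl)))
  wide <- ntcp_tbl |>
    dplyr::select("case_id", "modality", "ntcp") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "ntcp")
  if (!"photon" %in% names(wide)) stop("no photon NTCP rows", call. = FALSE)
  purrr::pmap_dfr(wide, function(case_id, photon, proton = NA_real_) {
    provider <- function() {
      if (!is.finite(proton)) {
        stop("no proton NTCP available", call. = FALSE)
      }
      100 * proton
    }
    decide(100 * photon, provider, thresholds, case_id = case_id)
  })
}
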