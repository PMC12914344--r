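# NTCP models: the logistic rectal-bleeding model (operative model of the
# decision pipeline) and the Lyman-Kutcher-Burman probit model.

#' Logistic NTCP model coefficients (rectal bleeding)
#'
#' Published multivariable logistic model for late rectal bleeding:
#' `S = -3.07 + 0.79 * anticoagulant_use + 0.12 * rectum-wall V6300cGy`,
#' with V6300 in percentage points of wall volume.
#'
#' @param intercept,coef_anticoagulant,coef_v6300 Model coefficients.
#' @return Object of class `logistic_ntcp_params`.
#' @export
logistic_ntcp_params <- function(intercept = -3.07, coef_anticoagulant = 0.79,
                                 coef_v6300 = 0.12) {
  stopifnot(is.finite(intercept), is.finite(coef_anticoagulant),
            is.finite(coef_v6300))
  structure(list(intercept = intercept,
                 coef_anticoagulant = coef_anticoagulant,
                 coef_v6300 = coef_v6300),
            class = "logistic_ntcp_params")
}

#' Linear predictor S of the logistic NTCP model
#'
#' @param v6300 Rectum-wall V6300cGy in percent, in `[0, 100]`.
#' @param anticoagulant 0/1 anticoagulant-use flag.
#' @param params A [logistic_ntcp_params()].
#' @return The linear predictor S (dimensionless).
#' @examples
#' logistic_s(0, 0)      # -3.07 (intercept)
#' logistic_s(25, 1)     # -1.28
#' @export
logistic_s <- function(v6300, anticoagulant, params = logistic_ntcp_params()) {
  if (any(v6300 < 0 | v6300 > 100)) {
    stop("v6300 must be in [0, 100] percent", call. = FALSE)
  }
  stopifnot(all(anticoagulant %in% c(0, 1)))
  params$intercept + params$coef_anticoagulant * anticoagulant +
    params$coef_v6300 * v6300
}

#' Logistic NTCP from the linear predictor
#'
#' `NTCP = 1 / (1 + exp(-S))`, strictly increasing in S with range (0,1).
#' `as_printed = TRUE` evaluates `1 / (1 - exp(-S))` instead — a form that
#' appears in print but is not a probability (it exceeds 1 for positive S
#' and diverges at S = 0); it is provided for audit only and never used
#' by the pipeline.
#'
#' @param S Linear predictor(s), finite.
#' @param as_printed Audit-only flag; see Details.
#' @return Probability in (0, 1) (unless `as_printed`).
#' @export
logistic_ntcp <- function(S, as_printed = FALSE) {
  stopifnot(all(is.finite(S)))
  if (as_printed) 1 / (1 - exp(-S)) else 1 / (1 + exp(-S))
}

#' Lyman-Kutcher-Burman model parameters
#'
#' The LKB model is provided for completeness beside the operative
#' logistic model; defaults are literature-style placeholder values for
#' late rectal toxicity (TD50 ~ 76.9 Gy, m ~ 0.13, volume-effect exponent
#' a ~ 11.9) and are fully config-exposed.
#'
#' @param td50 Uniform dose giving 50\% complication probability (Gy).
#' @param m Slope parameter (dimensionless, `> 0`).
#' @param a Volume-effect exponent for the generalized-EUD reduction.
#' @return Object of class `lkb_params`.
#' @export
lkb_params <- function(td50 = 76.9, m = 0.13, a = 11.9) {
  stopifnot(td50 > 0, m > 0)
  structure(list(td50 = td50, m = m, a = a), class = "lkb_params")
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' `gEUD = (mean(D_i^a))^(1/a)` over ROI voxels: the uniform dose with
#' the same effect as the heterogeneous distribution; large `a`
#' approaches the maximum dose (serial organs), `a = 1` the mean dose.
#'
#' @param dose A `dose_map` or array in cGy.
#' @param mask Logical array, non-empty.
#' @param a Exponent, `!= 0`.
#' @return gEUD in Gy.
#' @export
generalized_eud <- function(dose, mask, a) {
  if (a == 0) {
    stop("a = 0 is undefined here; use a geometric-mean variant explicitly",
         call. = FALSE)
  }
  d <- as_dose_array(dose)
  stopifnot(identical(dim(d), dim(mask)))
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  gy <- d[mask] / 100
  mean(gy^a)^(1 / a)
}

#' LKB (probit) NTCP
#'
#' `u = (EUD - TD50) / (m * TD50)`; NTCP is the standard normal CDF at u,
#' i.e. the probit dose-response `(1/sqrt(2*pi)) * integral_{-inf}^{u}
#' exp(-t^2/2) dt`.
#'
#' @param eud Equivalent uniform dose in Gy (see [generalized_eud()]).
#' @param params An [lkb_params()].
#' @return Probability in (0, 1).
#' @export
lkb_ntcp <- function(eud, params = lkb_params()) {
  stopifnot(inherits(params, "lkb_params"))
  u <- (eud - params$td50) / (params$m * params$td50)
  stats::pnorm(u)
}

#' Photon-minus-proton NTCP difference
#'
#' @param ntcp_photon,ntcp_proton Probabilities in `[0, 1]`.
#' @return Difference in percentage points (may be negative when the
#'   proton plan is worse).
#' @export
delta_ntcp <- function(ntcp_photon, ntcp_proton) {
  stopifnot(all(ntcp_photon >= 0 & ntcp_photon <= 1),
            all(ntcp_proton >= 0 & ntcp_proton <= 1))
  100 * (ntcp_photon - ntcp_proton)
}

#' NTCP record for one case and modality
#'
#' Convenience wrapper chaining the dosimetric predictor into the
#' logistic model: rectum-wall V6300 (EQD2) -> S -> NTCP.
#'
#' @param dose A `dose_map`.
#' @param phantom The matching `phantom`.
#' @param frac A [fractionation_params()].
#' @param params A [logistic_ntcp_params()].
#' @return One-row tibble: case_id, modality, provenance, v6300_percent,
#'   anticoagulant, S, ntcp.
#' @export
ntcp_record <- function(dose, phantom, frac = fractionation_params(),
                        params = logistic_ntcp_params()) {
  v63 <- v6300_rectum_wall(dose, phantom, frac)
  s <- logistic_s(v63, phantom$anticoagulant_use, params)
  tibble::tibble(
    case_id = phantom$patient_id,
    modality = dose$modality,
    provenance = dose$provenance,
    v6300_percent = v63,
    anticoagulant = phantom$anticoagulant_use,
    S = s,
    ntcp = logistic_ntcp(s)
  )
}
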