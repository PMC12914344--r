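# Analytic surrogate planning engines.
#
# Both engines ray-trace coplanar beams slice by slice through the body,
# accumulate an analytic depth-dose kernel restricted to a conformal
# aperture, and rescale so the target coverage criterion is met. Photon
# plans use a full arc (dose bath from many directions); proton plans use
# four fixed gantry angles with spread-out Bragg peaks per ray (low
# entrance dose, steep distal falloff). This reproduces the dosimetric
# contrast the modality decision exploits without inverse optimisation.

#' Prescription and plan-compliance criteria
#'
#' Default criteria follow the clinical protocol: PTV coverage
#' V_prescription >= 95\% per protocol (>= 90\% acceptable variation), and
#' organ-at-risk maximum-dose / relative-volume constraints (rectum and
#' rectum wall Dmax < 7000 cGy, rectum V5000 < 30\%, V6000 < 15\%, bladder
#' Dmax < 7100 cGy, V5000 < 30\%, V6000 < 20\%, femoral heads V5000 < 50\%,
#' colon Dmax < 5400 cGy, V5000 < 10\%, intestine Dmax < 5200 cGy,
#' V5000 < 5\%, V4500 < 5\%).
#'
#' @param ptv1_dose Prescription dose to PTV1 in cGy (default 6750, i.e.
#'   67.5 Gy RBE in 25 fractions).
#' @param ptv2_dose Dose to the pelvic lymph-node PTV2 in cGy (4500 or
#'   5000), or `NA` for single-gradient plans.
#' @param n_fractions Number of fractions (default 25).
#' @return Object of class `prescription` with a `criteria` tibble
#'   (columns roi, metric, ref_dose_cgy, limit_pct, comparator,
#'   variation_limit).
#' @export
prescription <- function(ptv1_dose = 6750, ptv2_dose = NA_real_,
                         n_fractions = 25L) {
  stopifnot(ptv1_dose > 0, n_fractions >= 1)
  crit <- tibble::tribble(
    ~roi, ~metric, ~ref_dose_cgy, ~limit, ~comparator, ~variation_limit,
    "PTV1", "V_D", ptv1_dose, 95, ">=", 90,
    "rectum_wall", "Dmax", NA, 7000, "<", 7000,
    "rectum", "Dmax", NA, 7000, "<", 7000,
    "rectum", "V_D", 5000, 30, "<", 30,
    "rectum", "V_D", 6000, 15, "<", 15,
    "bladder", "Dmax", NA, 7100, "<", 7100,
    "bladder", "V_D", 5000, 30, "<", 30,
    "bladder", "V_D", 6000, 20, "<", 20,
    "femur_L", "V_D", 5000, 50, "<", 50,
    "femur_R", "V_D", 5000, 50, "<", 50,
    "colon", "Dmax", NA, 5400, "<", 5400,
    "colon", "V_D", 5000, 10, "<", 10,
    "intestine", "Dmax", NA, 5200, "<", 5200,
    "intestine", "V_D", 5000, 5, "<", 5,
    "intestine", "V_D", 4500, 5, "<", 5
  )
  if (!is.na(ptv2_dose)) {
    stopifnot(ptv2_dose > 0)
    crit <- dplyr::bind_rows(
      crit[1, ],
      tibble::tibble(roi = "PTV2", metric = "V_D", ref_dose_cgy = ptv2_dose,
                     limit = 95, comparator = ">=", variation_limit = 90),
      crit[-1, ]
    )
  }
  vd <- crit$metric == "V_D"
  stopifnot(all(crit$limit[vd] >= 0 & crit$limit[vd] <= 100))
  structure(list(ptv1_dose = ptv1_dose, ptv2_dose = ptv2_dose,
                 n_fractions = as.integer(n_fractions), criteria = crit),
            class = "prescription")
}

#' Prescription for a phantom's assigned plan type
#' @param phantom A `phantom`.
#' @return A [prescription()] (dual-gradient when the phantom carries a
#'   nodal target).
#' @export
phantom_prescription <- function(phantom) {
  if (isTRUE(phantom$dual_gradient)) {
    prescription(ptv2_dose = phantom$ptv2_dose)
  } else {
    prescription()
  }
}

#' Beam configuration
#'
#' @param modality `"photon"` or `"proton"`.
#' @param gantry_angles Degrees in `[0, 360)`. Defaults: proton plans use
#'   the four fixed clinical angles 90, 270, 150, 210; photon plans a
#'   full arc discretised at `arc_step` degrees.
#' @param proton_range_margin Distal range margin beyond the target edge
#'   (mm).
#' @param spot_spacing Lateral scanning-spot spacing (mm, default 6).
#' @param photon_arc Logical; full-arc photon delivery.
#' @param arc_step Arc discretisation step in degrees.
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(modality = c("photon", "proton"),
                        gantry_angles = NULL,
                        proton_range_margin = 4,
                        spot_spacing = 6,
                        photon_arc = NULL,
                        arc_step = 10) {
  modality <- match.arg(modality)
  if (is.null(photon_arc)) photon_arc <- modality == "photon"
  if (is.null(gantry_angles)) {
    gantry_angles <- if (modality == "proton") c(90, 270, 150, 210)
      else seq(0, 360 - arc_step, by = arc_step)
  }
  stopifnot(all(gantry_angles >= 0 & gantry_angles < 360), spot_spacing > 0,
            proton_range_margin >= 0)
  structure(list(modality = modality, gantry_angles = gantry_angles,
                 proton_range_margin = proton_range_margin,
                 spot_spacing = spot_spacing, photon_arc = photon_arc,
                 arc_step = arc_step),
            class = "beam_config")
}

#' Photon percentage-depth-dose kernel
#'
#' Surrogate megavoltage depth dose: linear build-up to 1.0 at `d_max`,
#' then exponential attenuation `exp(-mu * (depth - d_max))`.
#'
#' @param depth Depth(s) in mm, `>= 0`.
#' @param d_max Build-up depth (mm, default 15).
#' @param mu Attenuation coefficient (1/mm, default 0.005).
#' @param surface_dose Relative dose at depth 0 (in (0,1), default 0.4).
#' @return Relative dose in `(0, 1]`.
#' @export
photon_depth_dose <- function(depth, d_max = 15, mu = 0.005,
                              surface_dose = 0.4) {
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  ifelse(depth < d_max,
         surface_dose + (1 - surface_dose) * depth / d_max,
         exp(-mu * (depth - d_max)))
}

#' Pristine Bragg-peak depth-dose kernel
#'
#' Low entrance plateau (entrance/peak ratio about 0.3), maximum 1.0 at
#' `range_mm`, Gaussian distal falloff reaching < 5\% of peak within
#' `distal_falloff_mm`.
#'
#' @param depth Depth(s) in mm, `>= 0`.
#' @param range_mm Proton range (mm), `> 0`.
#' @param proximal_sigma Width of the proximal peak shoulder (mm).
#' @param distal_sigma Width of the distal falloff (mm); the default 2 mm
#'   puts the dose below 5\% of peak 6 mm past the range.
#' @return Relative dose in `(0, 1]`.
#' @export
bragg_depth_dose <- function(depth, range_mm, proximal_sigma = 4,
                             distal_sigma = 2) {
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  if (any(range_mm <= 0)) stop("range_mm must be > 0", call. = FALSE)
  plateau <- function(d) 0.3 + 0.1 * pmin(d / range_mm, 1)
  pk <- plateau(range_mm)
  ifelse(depth <= range_mm,
         plateau(depth) + (1 - pk) * exp(-0.5 * ((depth - range_mm) / proximal_sigma)^2),
         exp(-0.5 * ((depth - range_mm) / distal_sigma)^2))
}

# Spread-out Bragg peak along one ray: flat 1.0 between proximal and
# distal target depths, short proximal ramp, entrance plateau, and the
# pristine distal falloff.
sobp_depth_dose <- function(depth, proximal, distal, distal_sigma = 2.2,
                            entrance = 0.33, ramp = 5) {
  p0 <- pmax(proximal - ramp, 0)
  ifelse(depth > distal,
         exp(-0.5 * ((depth - distal) / distal_sigma)^2),
         ifelse(depth >= proximal, 1,
                ifelse(depth >= p0,
                       entrance + (1 - entrance) * (depth - p0) / pmax(proximal - p0, 1e-6),
                       entrance)))
}

# --- slice rotation machinery -------------------------------------------

# Precompute nearest-neighbour index map for rotating an (ny, nx) slice by
# `theta` degrees about its center. Returns integer vector idx such that
# rotated[i] = slice[idx[i]] (idx 0 -> outside, fill).
rotation_index <- function(ny, nx, theta) {
  th <- theta * pi / 180
  cyx <- c((ny + 1) / 2, (nx + 1) / 2)
  out_y <- rep(seq_len(ny), times = nx) - cyx[1]
  out_x <- rep(seq_len(nx), each = ny) - cyx[2]
  src_y <- round(cos(th) * out_y - sin(th) * out_x + cyx[1])
  src_x <- round(sin(th) * out_y + cos(th) * out_x + cyx[2])
  ok <- src_y >= 1 & src_y <= ny & src_x >= 1 & src_x <= nx
  idx <- ifelse(ok, src_y + (src_x - 1) * ny, NA_integer_)
  as.integer(idx)
}

rotate_slice <- function(slice, idx, fill = 0) {
  v <- slice[idx]
  v[is.na(idx)] <- fill
  matrix(v, nrow = nrow(slice))
}

# Gaussian blur across columns (lateral penumbra), sigma in columns.
blur_cols <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  nc <- ncol(mat)
  out <- matrix(0, nrow(mat), nc)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- pmin(pmax(seq_len(nc) + off, 1L), nc)
    out <- out + mat[, src, drop = FALSE] * k[j]
  }
  out
}

# Dose for one beam direction on one axial slice (matrices ny x nx).
# Beam travels along +rows of the rotated frame.
beam_slice_dose <- function(body_sl, target_sl, idx_fwd, idx_bwd, sp_mm,
                            modality, range_margin, penumbra_sigma_vox) {
  rb <- rotate_slice(body_sl, idx_fwd) > 0.5
  rt <- rotate_slice(target_sl, idx_fwd) > 0.5
  ny <- nrow(rb)
  dose_rot <- matrix(0, ny, ncol(rb))
  tcols <- which(colSums(rt) > 0)
  if (length(tcols) == 0) return(matrix(0, nrow(body_sl), ncol(body_sl)))
  entry <- apply(rb[, tcols, drop = FALSE], 2, function(cl) {
    w <- which(cl); if (length(w)) w[1] else NA_integer_
  })
  rows <- seq_len(ny)
  for (i in seq_along(tcols)) {
    cc <- tcols[i]
    if (is.na(entry[i])) next
    depth <- (rows - entry[i]) * sp_mm
    depth[depth < 0] <- 0
    if (modality == "photon") {
      dose_rot[, cc] <- photon_depth_dose(depth)
    } else {
      tr <- which(rt[, cc])
      prox <- (tr[1] - entry[i]) * sp_mm
      dist <- (tr[length(tr)] - entry[i]) * sp_mm + range_margin
      dose_rot[, cc] <- sobp_depth_dose(depth, prox, dist)
    }
  }
  dose_rot <- blur_cols(dose_rot, penumbra_sigma_vox)
  dose_rot[!rb] <- dose_rot[!rb] * 0.0
  rotate_slice(dose_rot, idx_bwd)
}

# Accumulate one conformal component (one target) over all beams/slices.
component_dose <- function(phantom, target_mask, beams) {
  dm <- dim(phantom$intensity)
  sp <- phantom$spacing
  body <- phantom$masks$body
  dose <- array(0, dm)
  angs <- beams$gantry_angles
  pen_sigma <- 3 / sp[3]   # ~3 mm lateral penumbra
  idx_f <- lapply(angs, function(a) rotation_index(dm[2], dm[3], a))
  idx_b <- lapply(angs, function(a) rotation_index(dm[2], dm[3], -a))
  zs <- which(apply(target_mask, 1, any))
  for (z in zs) {
    bsl <- matrix(body[z, , ], dm[2], dm[3])
    tsl <- matrix(target_mask[z, , ], dm[2], dm[3])
    acc <- matrix(0, dm[2], dm[3])
    for (k in seq_along(angs)) {
      acc <- acc + beam_slice_dose(bsl, tsl, idx_f[[k]], idx_b[[k]], sp[2],
                                   beams$modality, beams$proton_range_margin,
                                   pen_sigma)
    }
    dose[z, , ] <- acc / length(angs)
  }
  dose[!body] <- 0
  dose
}

# Optimiser-like organ-at-risk shaping: inside the rectum the attainable
# dose falls off with distance from the target (the dose gradient an
# optimiser buys by trading rectum dose against conformity), down to
# (1 - depth) of the unshaped value beyond `n_rings` voxel shells.
# Target voxels (including the rectum/PTV overlap) keep near-full dose,
# as clinical plans do. Returns a multiplicative factor field in (0, 1].
oar_shaping <- function(phantom, depth = 0.5, n_rings = 6L) {
  dm <- dim(phantom$intensity)
  rectum <- phantom$masks$rectum
  if (is.null(rectum)) return(array(1, dm))
  ptv <- phantom$masks$PTV1
  if (!is.null(phantom$masks$PTV2)) ptv <- ptv | phantom$masks$PTV2
  # voxel-shell distance from the target by successive unit dilations
  dist <- array(n_rings, dm)
  dist[ptv] <- 0L
  cur <- ptv
  for (k in seq_len(n_rings - 1L)) {
    cur <- dilate_axis(dilate_axis(dilate_axis(cur, 1L, 1L, 1L),
                                   2L, 1L, 1L), 3L, 1L, 1L)
    ring <- cur & (dist == n_rings)
    dist[ring] <- k
  }
  shape <- array(1, dm)
  sel <- rectum & !ptv
  shape[sel] <- 1 - depth * dist[sel] / n_rings
  shape[ptv] <- pmax(shape[ptv], 0.97)
  shape
}

# Scale a component so that >= `coverage` of target voxels receive
# `presc_dose`.
scale_to_coverage <- function(dose, target_mask, presc_dose, coverage = 0.95) {
  tv <- dose[target_mask]
  n <- length(tv)
  q <- sort(tv)[max(1L, floor((1 - coverage) * n) + 1L)]
  if (q <= 0) return(NULL)
  # tiny headroom so the quantile voxel itself stays >= presc_dose after
  # floating-point rounding
  dose * (presc_dose / q) * (1 + 1e-9)
}

#' Compute a surrogate treatment plan dose map
#'
#' Ray-traces the configured beams through the phantom, accumulating the
#' modality's depth-dose kernel within a conformal aperture per target,
#' then rescales each dose component so at least 95\% of its target
#' receives the prescription (falling back to 90\%, the acceptable
#' variation, when 95\% is geometrically infeasible). Dual-gradient plans
#' deliver the nodal dose as a second conformal component; voxels in the
#' overlap take the maximum of the two components. A small seeded
#' multiplicative noise field emulates plan-to-plan delivery variability.
#'
#' @param phantom A `phantom`.
#' @param presc A [prescription()]; defaults to the phantom's own.
#' @param beams A [beam_config()].
#' @param seed Integer seed for the delivery-noise field.
#' @param noise_sd Relative standard deviation of the noise field
#'   (default 0.015); 0 disables it.
#' @return A `dose_map`: list with `dose` (3-D array, cGy), `spacing`,
#'   `modality`, `provenance = "engine"`, and (when coverage below 90\%
#'   was unavoidable) a `failure_report` tibble of violated criteria.
#' @export
plan_dose <- function(phantom, presc = phantom_prescription(phantom),
                      beams = beam_config("photon"), seed = 1L,
                      noise_sd = 0.015) {
  stopifnot(inherits(phantom, "phantom"), inherits(presc, "prescription"))
  for (roi in unique(presc$criteria$roi)) {
    if (!roi %in% names(phantom$masks)) next  # reported by compliance check
  }
  if (!"PTV1" %in% names(phantom$masks)) {
    stop("phantom lacks PTV1 mask", call. = FALSE)
  }
  shape <- oar_shaping(phantom)
  comp1 <- component_dose(phantom, phantom$masks$PTV1, beams) * shape
  d1 <- scale_to_coverage(comp1, phantom$masks$PTV1, presc$ptv1_dose, 0.95)
  dose <- d1
  if (!is.na(presc$ptv2_dose) && "PTV2" %in% names(phantom$masks)) {
    # proton nodal component uses the lateral fields only, keeping the
    # distal edges away from the rectum
    beams2 <- if (beams$modality == "proton") {
      beam_config("proton", gantry_angles = c(90, 270),
                  proton_range_margin = beams$proton_range_margin,
                  spot_spacing = beams$spot_spacing)
    } else beams
    comp2 <- component_dose(phantom, phantom$masks$PTV2, beams2) * shape
    d2 <- scale_to_coverage(comp2, phantom$masks$PTV2, presc$ptv2_dose, 0.95)
    if (!is.null(d2)) {
      # nodal component carries its own homogeneity cap
      dose <- pmax(dose, pmin(d2, 1.035 * presc$ptv2_dose))
    }
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed %% .Machine$integer.max)
    noise <- array(rnorm(prod(dim(dose)), 1, noise_sd), dim(dose))
    # smooth the noise in-plane so it behaves like low-frequency
    # optimisation variability rather than voxel speckle
    for (z in seq_len(dim(dose)[1])) {
      noise[z, , ] <- blur_cols(t(blur_cols(t(matrix(noise[z, , ], dim(dose)[2])),
                                            1.2)), 1.2)
    }
    dose <- dose * pmax(noise, 0)
    # re-normalise so the coverage guarantee holds after the noise field
    renorm <- scale_to_coverage(dose, phantom$masks$PTV1, presc$ptv1_dose,
                                0.95)
    if (!is.null(renorm)) dose <- renorm
  }
  # clinical homogeneity: hotspots capped just under the rectum/bladder
  # Dmax constraints (103.5% of prescription)
  dose <- pmin(dose, 1.035 * presc$ptv1_dose)
  dose[dose < 0] <- 0
  out <- structure(list(dose = dose, spacing = phantom$spacing,
                        modality = beams$modality, provenance = "engine"),
                   class = "dose_map")
  cov <- v_at_dose(out, phantom$masks$PTV1, presc$ptv1_dose)
  if (cov < 90) {
    rep <- check_plan_criteria(out, phantom, presc)
    out$failure_report <- dplyr::filter(rep, .data$status == "fail")
  }
  out
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map %s/%s> grid %s, max %.0f cGy\n", x$modality,
              x$provenance, paste(dim(x$dose), collapse = "x"), max(x$dose)))
  invisible(x)
}

#' Evaluate a plan against its clinical dose criteria
#'
#' @param dose A `dose_map`.
#' @param phantom The matching `phantom`.
#' @param presc A [prescription()].
#' @return A tibble with one row per criterion: roi, metric, measured
#'   value, limit, and status in `pass` / `variation` / `fail` /
#'   `missing` (ROI absent from the phantom).
#' @export
check_plan_criteria <- function(dose, phantom,
                                presc = phantom_prescription(phantom)) {
  stopifnot(identical(dim(dose$dose), dim(phantom$intensity)))
  purrr::pmap_dfr(presc$criteria, function(roi, metric, ref_dose_cgy, limit,
                                           comparator, variation_limit) {
    row <- tibble::tibble(roi = roi, metric = metric,
                          ref_dose_cgy = ref_dose_cgy,
                          limit = limit, comparator = comparator,
                          measured = NA_real_, status = "missing")
    mask <- phantom$masks[[roi]]
    if (is.null(mask) || !any(mask)) return(row)
    meas <- if (metric == "Dmax") d_max(dose, mask)
      else v_at_dose(dose, mask, ref_dose_cgy)
    row$measured <- meas
    row$status <- if (comparator == ">=") {
      if (meas >= limit) "pass"
      else if (meas >= variation_limit) "variation"
      else "fail"
    } else {
      if (meas < limit) "pass" else "fail"
    }
    row
  })
}

#' Integral dose over a mask
#'
#' Sum of dose times voxel volume — the whole-body integral dose is the
#' classic proton-vs-photon contrast measure.
#'
#' @param dose A `dose_map`.
#' @param mask Logical array (defaults to all voxels).
#' @return Integral dose in Gy * litre.
#' @export
integral_dose <- function(dose, mask = NULL) {
  d <- dose$dose
  if (!is.null(mask)) d <- d[mask]
  sum(d) / 100 * prod(dose$spacing) / 1e6
}
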