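# Synthetic pelvic phantoms: parametric anatomy on a regular voxel grid.
#
# Axis convention (fixed throughout the package):
#   array dim = (z, y, x) = (superior -> inferior, anterior -> posterior,
#   patient-right -> patient-left); 0-based voxel positions are voxel
#   centers at index * spacing (mm).

#' Directional margin specification
#'
#' Clinical CTV-to-PTV expansion margins, one length per anatomical
#' direction. All margins are in centimetres, matching clinical usage;
#' they are converted to millimetres internally.
#'
#' @param superior,inferior,left,right,anterior,posterior Margins in cm
#'   (all `>= 0`).
#' @return An object of class `margin_spec`.
#' @examples
#' margin_spec(1, 1, 1, 1, 1, 0.5)  # prostate + seminal vesicle target
#' @export
margin_spec <- function(superior, inferior, left, right, anterior, posterior) {
  m <- list(
    superior = superior, inferior = inferior, left = left,
    right = right, anterior = anterior, posterior = posterior
  )
  vals <- unlist(m)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all margins must be finite and >= 0", call. = FALSE)
  }
  structure(m, class = "margin_spec")
}

#' Default clinical margins for the prostate (PTV1) and nodal (PTV2) targets
#'
#' PTV1 expands the prostate + seminal-vesicle CTV by 1.0 cm in the
#' superior, inferior, left, right and anterior directions and 0.5 cm
#' posteriorly (rectum sparing). PTV2 expands the pelvic lymph-node CTV
#' by 1.0 cm superior/inferior, 0.7 cm left/right/anterior and 0.5 cm
#' posterior.
#'
#' @param target `"PTV1"` or `"PTV2"`.
#' @return A [margin_spec()].
#' @export
default_margins <- function(target = c("PTV1", "PTV2")) {
  target <- match.arg(target)
  if (target == "PTV1") {
    margin_spec(1.0, 1.0, 1.0, 1.0, 1.0, 0.5)
  } else {
    margin_spec(1.0, 1.0, 0.7, 0.7, 0.7, 0.5)
  }
}

# Shift a logical (z,y,x) array by `by` voxels along `axis`, zero-filling.
shift_mask <- function(mask, axis, by) {
  if (by == 0L) return(mask)
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) seq_len(n - by) else seq(1L - by, n)
  dst <- if (by > 0L) seq(1L + by, n) else seq_len(n + by)
  idx_src <- idx_dst <- rep(list(quote(expr = )), 3L)
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        list(as.call(c(list(quote(`[`), quote(mask)), idx_src)))))
  eval(out_call)
}

# Directed 1-D dilation along one axis: grow the mask by `low` voxels
# toward lower indices and `high` voxels toward higher indices. A voxel
# at index i - j (j <= low) of a source voxel i is covered by shifting
# the mask content down by j.
dilate_axis <- function(mask, axis, low, high) {
  out <- mask
  for (j in seq_len(low)) out <- out | shift_mask(mask, axis, -j)
  for (j in seq_len(high)) out <- out | shift_mask(mask, axis, +j)
  out
}

#' Expand a CTV mask to a PTV with anisotropic directional margins
#'
#' A voxel outside the CTV joins the PTV iff its center lies within the
#' direction-dependent margin of some CTV voxel center, testing each
#' signed axis distance against the margin for that direction (a
#' box-shaped, separable dilation). This matches how direction-specific
#' clinical margins are prescribed (e.g. a tighter posterior margin
#' toward the rectum).
#'
#' @param ctv_mask Logical 3-D array in (z, y, x) order; must be non-empty.
#' @param margins A [margin_spec()] (cm).
#' @param spacing Numeric length-3 voxel spacing `(dz, dy, dx)` in mm.
#' @return Logical array of the same shape, a superset of `ctv_mask`.
#' @export
expand_ctv_to_ptv <- function(ctv_mask, margins, spacing) {
  stopifnot(inherits(margins, "margin_spec"), length(spacing) == 3L,
            all(spacing > 0))
  if (!any(ctv_mask)) stop("CTV mask is empty; cannot expand", call. = FALSE)
  mm <- lapply(margins, function(x) 10 * x)  # cm -> mm
  eps <- 1e-9
  nvox <- function(margin_mm, sp) as.integer(floor(margin_mm / sp + eps))
  # z: low index = superior, high = inferior
  out <- dilate_axis(ctv_mask, 1L,
                     low = nvox(mm$superior, spacing[1]),
                     high = nvox(mm$inferior, spacing[1]))
  # y: low index = anterior, high = posterior
  out <- dilate_axis(out, 2L,
                     low = nvox(mm$anterior, spacing[2]),
                     high = nvox(mm$posterior, spacing[2]))
  # x: low index = patient right, high = patient left
  dilate_axis(out, 3L,
              low = nvox(mm$right, spacing[3]),
              high = nvox(mm$left, spacing[3]))
}

#' Cohort specification for synthetic phantom generation
#'
#' @param n_cases Number of phantoms (`>= 1`).
#' @param seed Integer seed; per-case seeds are derived deterministically.
#' @param fraction_dual_gradient Proportion of cases with a second,
#'   lower-dose pelvic lymph-node target (dual dose gradient).
#' @param anticoagulant_prevalence Proportion of anticoagulant users
#'   (covariate of the rectal-bleeding NTCP model). No claim of fidelity
#'   to any clinical cohort; exposed as a knob.
#' @param anatomy_variability Dimensionless scale (`>= 0`) multiplying the
#'   per-case random jitter of organ sizes and positions; 1 gives
#'   millimetre-to-centimetre scale variation typical of pelvic anatomy.
#' @param grid_dim Grid dimensions `(nz, ny, nx)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` in mm.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 20L, seed = 1L,
                        fraction_dual_gradient = 0.35,
                        anticoagulant_prevalence = 0.25,
                        anatomy_variability = 1,
                        grid_dim = c(48L, 64L, 64L),
                        spacing = c(2.5, 2.5, 2.5)) {
  stopifnot(n_cases >= 1, fraction_dual_gradient >= 0,
            fraction_dual_gradient <= 1, anticoagulant_prevalence >= 0,
            anticoagulant_prevalence <= 1, anatomy_variability >= 0,
            length(grid_dim) == 3L, all(grid_dim >= 32L | prod(grid_dim) >= 32^3),
            length(spacing) == 3L, all(spacing > 0))
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    fraction_dual_gradient = fraction_dual_gradient,
    anticoagulant_prevalence = anticoagulant_prevalence,
    anatomy_variability = anatomy_variability,
    grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing)
  ), class = "cohort_spec")
}

# Voxel-center coordinate arrays (mm) for a grid.
grid_coords <- function(dim, spacing) {
  z <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  x <- (seq_len(dim[3]) - 1) * spacing[3]
  list(
    z = array(rep(z, times = dim[2] * dim[3]), dim),
    y = array(rep(rep(y, each = dim[1]), times = dim[3]), dim),
    x = array(rep(x, each = dim[1] * dim[2]), dim)
  )
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$z - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$x - center[3]) / semi[3])^2 <= 1
}

# Tube along z between z0 and z1 with centerline (yc(z), xc(z)) and radius r.
tube_mask <- function(co, z0, z1, yc, xc, r) {
  inz <- co$z >= z0 & co$z <= z1
  inz & ((co$y - yc)^2 + (co$x - xc)^2 <= r^2)
}

roi_extent_check <- function(name, center, semi, dim, spacing) {
  lo <- center - semi
  hi <- center + semi
  ext <- (dim - 1) * spacing
  if (any(lo < 0) || any(hi > ext)) {
    stop(sprintf("grid too small to contain ROI '%s' at requested size", name),
         call. = FALSE)
  }
}

#' Generate one synthetic pelvic phantom
#'
#' Builds a CT-like intensity volume and binary structure masks for the
#' organs involved in prostate radiotherapy planning: prostate +
#' seminal-vesicle CTV, rectum with an inner-air lumen and a wall shell,
#' bladder, femoral heads, colon, small intestine, and (for dual-gradient
#' cases) pelvic lymph-node bands forming a second CTV. PTVs are obtained
#' by anisotropic margin expansion ([expand_ctv_to_ptv()]). The rectum
#' abuts the posterior CTV surface, so the 0.5 cm posterior margin forces
#' a PTV1/rectum overlap across which both dose engines must shape their
#' gradients — the geometry the modality-selection problem hinges on.
#'
#' @param spec A [cohort_spec()] providing grid, spacing and variability.
#' @param seed Integer seed for this case's anatomy.
#' @param dual_gradient Logical; include the pelvic lymph-node target.
#' @param anticoagulant Optional 0/1 override; drawn from
#'   `spec$anticoagulant_prevalence` when `NULL`.
#' @param patient_id Case identifier string.
#' @param wall_thickness_mm Rectum wall shell thickness (mm, default 3).
#' @return An object of class `phantom`: list with `intensity` (3-D
#'   array), `masks` (named list of logical arrays), `spacing`,
#'   `patient_id`, `anticoagulant_use`, `dual_gradient`, `ptv2_dose`.
#' @export
generate_phantom <- function(spec = cohort_spec(), seed = 1L,
                             dual_gradient = FALSE, anticoagulant = NULL,
                             patient_id = sprintf("case_%04d", seed),
                             wall_thickness_mm = 3) {
  dm <- spec$grid_dim; sp <- spec$spacing
  if (prod(dm) < 32^3) stop("grid must be at least 32^3 voxels", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  v <- spec$anatomy_variability
  jit <- function(sd) rnorm(1, 0, sd) * v
  co <- grid_coords(dm, sp)
  ext <- (dm - 1) * sp
  cz <- ext[1] / 2; cy <- ext[2] / 2; cx <- ext[3] / 2

  # body: elliptic cylinder, slightly flattened anterior-posteriorly
  body <- ((co$y - cy) / (0.47 * ext[2]))^2 +
    ((co$x - cx) / (0.49 * ext[3]))^2 <= 1

  # prostate ellipsoid, centered mid-pelvis, slightly inferior-posterior
  pr_c <- c(cz + 14 + jit(3), cy + 6 + jit(3), cx + jit(2))
  pr_s <- c(19, 16, 19) * exp(c(jit(0.07), jit(0.07), jit(0.07)))
  roi_extent_check("prostate", pr_c, pr_s, dm, sp)
  prostate <- ellipsoid_mask(co, pr_c, pr_s)

  # seminal vesicles: superior-posterior to the prostate
  sv_c <- c(pr_c[1] - pr_s[1] - 2, pr_c[2] + 2 + jit(2), pr_c[3])
  sv_s <- c(9, 8, 15) * exp(jit(0.08))
  roi_extent_check("seminal_vesicles", sv_c, sv_s, dm, sp)
  sv <- ellipsoid_mask(co, sv_c, sv_s)

  ctv1 <- (prostate | sv) & body

  # rectum: posterior tube spanning the scan, abutting the CTV surface
  # with a small per-case gap (may be slightly negative); wall = shell
  r_re <- 10.5 * exp(jit(0.10))
  gap <- 1.0 + jit(1.75)               # mm; varies abutment/overlap depth
  yr <- pr_c[2] + pr_s[2] + r_re + gap
  xr <- pr_c[3] + jit(1.5)
  z0 <- 0; z1 <- ext[1]
  roi_extent_check("rectum", c(ext[1] / 2, yr, xr),
                   c(ext[1] / 2, r_re, r_re), dm, sp)
  rectum <- tube_mask(co, z0, z1, yr, xr, r_re) & body
  lumen_r <- max(r_re - wall_thickness_mm, 1)
  lumen <- tube_mask(co, z0, z1, yr, xr, lumen_r)
  rectum_wall <- rectum & !lumen

  # bladder: anterior-superior dome
  bl_c <- c(pr_c[1] - 26 + jit(2), pr_c[2] - 32 + jit(3), cx + jit(2))
  bl_s <- c(20, 22, 25) * exp(jit(0.08))
  roi_extent_check("bladder", bl_c, bl_s, dm, sp)
  bladder <- ellipsoid_mask(co, bl_c, bl_s) & body & !ctv1

  # femoral heads
  f_r <- 16
  fem_l <- ellipsoid_mask(co, c(pr_c[1] + 2, cy + 4, cx + 55 + jit(1.5)),
                          rep(f_r, 3)) & body
  fem_r <- ellipsoid_mask(co, c(pr_c[1] + 2, cy + 4, cx - 55 - jit(1.5)),
                          rep(f_r, 3)) & body

  # sigmoid colon: transverse tube well superior of the target region
  col_z <- max(bl_c[1] - 35 + jit(2), 8)
  colon <- (abs(co$z - col_z) <= 9) &
    ((co$y - (cy - 8 + jit(2)))^2 <= 10^2) &
    (abs(co$x - cx) <= 45) & body

  # small intestine: anterior-superior compartment, excluding other organs
  intestine <- ellipsoid_mask(co, c(max(col_z - 10, 10), cy - 18, cx),
                              c(14, 28, 42)) & body &
    !(bladder | colon | ctv1)

  masks <- list(
    body = body, prostate = prostate, CTV1 = ctv1,
    rectum = rectum, rectum_wall = rectum_wall, bladder = bladder,
    femur_L = fem_l, femur_R = fem_r, colon = colon, intestine = intestine
  )
  masks$PTV1 <- expand_ctv_to_ptv(ctv1, default_margins("PTV1"), sp) & body

  ptv2_dose <- NA_real_
  if (dual_gradient) {
    # pelvic lymph-node bands: two lateral tubes joined by a presacral arc
    nb_r <- 8.5
    nz0 <- max(pr_c[1] - 44, 6); nz1 <- pr_c[1] - 6
    band_l <- tube_mask(co, nz0, nz1, cy + 2 + jit(2), cx + 33, nb_r)
    band_r <- tube_mask(co, nz0, nz1, cy + 2 + jit(2), cx - 33, nb_r)
    presac <- (co$z >= nz0 & co$z <= nz0 + 14) &
      (abs(co$y - (yr + r_re + 5)) <= 6) & (abs(co$x - cx) <= 33)
    ctv2 <- (band_l | band_r | presac) & body & !ctv1 & !rectum
    if (!any(ctv2)) stop("grid too small to contain ROI 'CTV2'", call. = FALSE)
    masks$CTV2 <- ctv2
    masks$PTV2 <- expand_ctv_to_ptv(ctv2, default_margins("PTV2"), sp) & body
    ptv2_dose <- sample(c(4500, 5000), 1L)
  }

  # CT-like intensities (arbitrary units ~ HU + 1000)
  intens <- array(0, dm)
  intens[body] <- 1040
  intens[bladder] <- 1015
  intens[rectum] <- 1020
  intens[lumen & rectum] <- 980
  intens[fem_l | fem_r] <- 1350
  intens[prostate | sv] <- 1045
  intens <- intens + array(rnorm(prod(dm), 0, 8), dm) * ifelse(body, 1, 0)

  ac <- if (is.null(anticoagulant)) {
    rbinom(1L, 1L, spec$anticoagulant_prevalence)
  } else as.integer(anticoagulant)
  stopifnot(ac %in% c(0L, 1L))

  structure(list(
    intensity = intens, masks = masks, spacing = sp,
    patient_id = patient_id, anticoagulant_use = ac,
    dual_gradient = dual_gradient, ptv2_dose = ptv2_dose,
    seed = as.integer(seed)
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s> grid %s @ %s mm, %d ROIs, %s gradient, anticoagulant=%d\n",
              x$patient_id, paste(dim(x$intensity), collapse = "x"),
              paste(format(x$spacing), collapse = "/"),
              length(x$masks),
              if (isTRUE(x$dual_gradient)) "dual" else "single",
              x$anticoagulant_use))
  invisible(x)
}

#' Generate a reproducible cohort of phantoms
#'
#' Per-case seeds are derived deterministically from `spec$seed`, and the
#' dual-gradient and anticoagulant assignments are drawn once up front so
#' that the observed fractions converge to the specified proportions as
#' the cohort grows.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [generate_phantom()] phantoms, class `rt_cohort`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_cases
  case_seeds <- sample.int(2^30, n)
  dual <- runif(n) < spec$fraction_dual_gradient
  ac <- rbinom(n, 1L, spec$anticoagulant_prevalence)
  out <- lapply(seq_len(n), function(i) {
    generate_phantom(spec, seed = case_seeds[i], dual_gradient = dual[i],
                     anticoagulant = ac[i],
                     patient_id = sprintf("case_%03d", i))
  })
  structure(out, class = c("rt_cohort", "list"))
}

#' Summarise a cohort as a tibble
#'
#' @param cohort An `rt_cohort` from [generate_cohort()].
#' @return A tibble with one row per case: id, gradient type, covariates,
#'   and basic mask volumes (cc).
#' @export
cohort_summary <- function(cohort) {
  purrr::map_dfr(cohort, function(ph) {
    vox_cc <- prod(ph$spacing) / 1000
    tibble::tibble(
      patient_id = ph$patient_id,
      dual_gradient = isTRUE(ph$dual_gradient),
      anticoagulant_use = ph$anticoagulant_use,
      ptv2_dose_cgy = ph$ptv2_dose,
      ptv1_cc = sum(ph$masks$PTV1) * vox_cc,
      rectum_cc = sum(ph$masks$rectum) * vox_cc,
      rectum_wall_cc = sum(ph$masks$rectum_wall) * vox_cc
    )
  })
}

# RNG bookkeeping: save/restore the global seed so generators do not
# perturb user RNG state.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
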