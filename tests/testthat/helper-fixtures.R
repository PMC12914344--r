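# Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

fix_phantom <- function(seed = 1L, dual = FALSE) {
  memo(paste0("phantom_", seed, "_", dual),
       generate_phantom(cohort_spec(), seed = seed, dual_gradient = dual))
}

fix_plan <- function(modality = "photon", seed = 1L) {
  memo(paste0("plan_", modality, "_", seed), {
    ph <- fix_phantom(seed)
    plan_dose(ph, beams = beam_config(modality), seed = seed)
  })
}

# Small arbitrary dose map + mask on a tiny grid for dosimetry tests.
tiny_dose <- function(values, dim = c(2L, 2L, 2L), spacing = c(1, 1, 1),
                      modality = "photon") {
  structure(list(dose = array(values, dim), spacing = spacing,
                 modality = modality, provenance = "file"),
            class = "dose_map")
}

# Exhaustive brute-force CTV->PTV expansion used as the geometry oracle.
brute_force_expand <- function(mask, margins, spacing) {
  dm <- dim(mask)
  mm <- lapply(margins, function(x) 10 * x)
  out <- array(FALSE, dm)
  src <- which(mask, arr.ind = TRUE)
  eps <- 1e-9
  for (vi in seq_len(dm[1])) for (vj in seq_len(dm[2])) for (vk in seq_len(dm[3])) {
    dz <- (vi - src[, 1]) * spacing[1]
    dy <- (vj - src[, 2]) * spacing[2]
    dx <- (vk - src[, 3]) * spacing[3]
    okz <- (dz <= 0 & -dz <= mm$superior + eps) | (dz >= 0 & dz <= mm$inferior + eps)
    oky <- (dy <= 0 & -dy <= mm$anterior + eps) | (dy >= 0 & dy <= mm$posterior + eps)
    okx <- (dx <= 0 & -dx <= mm$right + eps) | (dx >= 0 & dx <= mm$left + eps)
    if (any(okz & oky & okx)) out[vi, vj, vk] <- TRUE
  }
  out
}

# Exhaustive pair-ordering AUC oracle (midrank ties count 1/2).
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
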