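# End-to-end cohort pipeline: phantoms -> engine plans -> (optional)
# learned dose prediction -> dosimetric predictor -> NTCP -> two-step
# decisions -> evaluation.

pipeline_log <- function(con, case_id, stage, seed = NA, ...) {
  extra <- list(...)
  kv <- if (length(extra)) {
    paste(names(extra), vapply(extra, format, character(1)), sep = "=",
          collapse = " ")
  } else ""
  line <- sprintf("[%s] case=%s seed=%s %s", stage, case_id,
                  format(seed), kv)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

cache_path <- function(config, name) file.path(config$out_dir, "cache", name)

with_cache <- function(config, name, expr) {
  p <- cache_path(config, paste0(name, ".rds"))
  if (config$cache && file.exists(p)) return(readRDS(p))
  val <- force(expr)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  saveRDS(val, p)
  val
}

stage_error <- function(stage, case_id, e) {
  stop(sprintf("pipeline stage '%s' failed for case '%s': %s",
               stage, case_id, conditionMessage(e)), call. = FALSE)
}

#' Run the full decision pipeline on a synthetic cohort
#'
#' Stages: generate cohort; plan engine doses for both modalities;
#' (optionally) cross-validate the learned dose predictor so every case
#' receives a held-out predicted dose per modality; compute the
#' fractionation-corrected rectum-wall V6300 and logistic NTCP per case,
#' modality and provenance; apply the two-step decision rule to the
#' predicted and to the engine-truth NTCPs; evaluate predicted against
#' truth decisions. Intermediates are cached under `out_dir/cache` so a
#' re-run with the same config resumes instead of recomputing; tables are
#' written as CSV/JSON under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `rt_pipeline`: `cohort_info`, `ntcp`
#'   (per case x modality x provenance tibble), `decisions_truth`,
#'   `decisions_pred`, `evaluation` (`rt_evaluation`), `cv` (per-modality
#'   `rt_cv` or NULL), `agreement` (paired t-tests engine vs predicted
#'   for V6300 and NTCP per modality), `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)

  spec <- cohort_spec(
    n_cases = config$n_cases, seed = config$seed,
    fraction_dual_gradient = config$fraction_dual_gradient,
    anticoagulant_prevalence = config$anticoagulant_prevalence,
    anatomy_variability = config$anatomy_variability
  )
  cohort <- with_cache(config, "cohort", generate_cohort(spec))
  for (ph in cohort) pipeline_log(con, ph$patient_id, "cohort", ph$seed)

  prescs <- lapply(cohort, phantom_prescription)
  frac <- fractionation_params(alpha_beta = config$alpha_beta)
  thresholds <- decision_thresholds(config$step1_threshold,
                                    config$step2_threshold)
  n <- length(cohort)

  engine <- list()
  for (mod in c("photon", "proton")) {
    engine[[mod]] <- with_cache(config, paste0("engine_", mod), {
      lapply(seq_len(n), function(i) {
        tryCatch(
          plan_dose(cohort[[i]], prescs[[i]], beam_config(mod),
                    seed = config$seed + 17L * i),
          error = function(e) stage_error("engine", cohort[[i]]$patient_id, e))
      })
    })
    for (i in seq_len(n)) {
      pipeline_log(con, cohort[[i]]$patient_id, paste0("plan_", mod),
                   config$seed + 17L * i,
                   dmax = round(max(engine[[mod]][[i]]$dose)))
    }
  }

  cv <- NULL
  predicted <- engine
  if (config$predictor_enabled) {
    pcfg <- do.call(predictor_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$predictor))
    cv <- list()
    predicted <- list()
    for (mod in c("photon", "proton")) {
      cv[[mod]] <- with_cache(config, paste0("cv_", mod), {
        crossvalidate(cohort, engine[[mod]], k = config$k_folds,
                      config = pcfg, modality = mod)
      })
      predicted[[mod]] <- cv[[mod]]$predicted
      pipeline_log(con, "cohort", paste0("crossvalidate_", mod), pcfg$seed,
                   rectum_wall_mae = round(cv[[mod]]$pooled$mae[
                     cv[[mod]]$pooled$roi == "rectum_wall"], 3))
    }
  }

  ntcp <- purrr::map_dfr(seq_len(n), function(i) {
    dplyr::bind_rows(lapply(c("photon", "proton"), function(mod) {
      dplyr::bind_rows(
        ntcp_record(engine[[mod]][[i]], cohort[[i]], frac),
        if (!identical(predicted[[mod]][[i]], engine[[mod]][[i]])) {
          ntcp_record(predicted[[mod]][[i]], cohort[[i]], frac)
        }
      )
    }))
  })
  for (i in seq_len(n)) {
    pipeline_log(con, cohort[[i]]$patient_id, "ntcp", NA,
                 rows = sum(ntcp$case_id == cohort[[i]]$patient_id))
  }

  truth_tbl <- dplyr::filter(ntcp, .data$provenance == "engine")
  pred_tbl <- if (config$predictor_enabled) {
    dplyr::filter(ntcp, .data$provenance == "predicted")
  } else truth_tbl
  decisions_truth <- decide_cohort(truth_tbl, thresholds)
  decisions_pred <- decide_cohort(pred_tbl, thresholds)
  for (i in seq_len(n)) {
    pipeline_log(con, decisions_pred$case_id[i], "decide", NA,
                 modality = decisions_pred$modality[i],
                 step = decisions_pred$deciding_step[i])
  }

  evaluation <- evaluate_cohort(decisions_pred, decisions_truth,
                                thresholds = thresholds)
  agreement <- NULL
  if (config$predictor_enabled) {
    agreement <- purrr::map_dfr(c("photon", "proton"), function(mod) {
      eng <- dplyr::filter(ntcp, .data$modality == mod,
                           .data$provenance == "engine") |>
        dplyr::arrange(.data$case_id)
      prd <- dplyr::filter(ntcp, .data$modality == mod,
                           .data$provenance == "predicted") |>
        dplyr::arrange(.data$case_id)
      tv <- paired_t_test(prd$v6300_percent, eng$v6300_percent)
      tn <- paired_t_test(100 * prd$ntcp, 100 * eng$ntcp)
      tibble::tibble(modality = mod,
                     quantity = c("v6300", "ntcp"),
                     t = c(tv$t, tn$t), p = c(tv$p, tn$p),
                     mean_diff = c(tv$mean_diff, tn$mean_diff),
                     normality_p = c(tv$normality$p, tn$normality$p),
                     variance_p = c(tv$variance$p, tn$variance$p))
    })
  }

  paths <- list(
    ntcp = file.path(config$out_dir, "ntcp.csv"),
    decisions_pred = file.path(config$out_dir, "decisions_pred.csv"),
    decisions_truth = file.path(config$out_dir, "decisions_truth.csv"),
    evaluation = file.path(config$out_dir, "evaluation.json"),
    log = log_path
  )
  utils::write.csv(ntcp, paths$ntcp, row.names = FALSE)
  utils::write.csv(decisions_pred, paths$decisions_pred, row.names = FALSE)
  utils::write.csv(decisions_truth, paths$decisions_truth, row.names = FALSE)
  eval_json <- list(
    accuracy = evaluation$accuracy, auc = evaluation$auc,
    auc_binary = evaluation$auc_binary,
    sen = evaluation$sen, spe = evaluation$spe,
    counts = evaluation$counts,
    mae = if (!is.null(cv)) {
      lapply(cv, function(x) {
        stats::setNames(as.list(x$pooled$mae), x$pooled$roi)
      })
    },
    agreement = if (!is.null(agreement)) {
      lapply(split(agreement, seq_len(nrow(agreement))), as.list)
    }
  )
  jsonlite::write_json(eval_json, paths$evaluation, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")

  structure(list(
    cohort_info = cohort_summary(cohort), ntcp = ntcp,
    decisions_truth = decisions_truth, decisions_pred = decisions_pred,
    evaluation = evaluation, cv = cv, agreement = agreement, paths = paths
  ), class = "rt_pipeline")
}

#' @export
print.rt_pipeline <- function(x, ...) {
  cat(sprintf("<rt_pipeline> %d cases; truth decisions: %s\n",
              nrow(x$cohort_info),
              paste(sprintf("%s=%d", names(table(x$decisions_truth$modality)),
                            table(x$decisions_truth$modality)),
                    collapse = ", ")))
  print(x$evaluation)
  invisible(x)
}
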