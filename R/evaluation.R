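# Decision-accuracy and agreement statistics.

#' Sensitivity and specificity from confusion counts
#'
#' Proton selection is the positive class, photon the negative class.
#' `SEN = TP / (TP + FN)`, `SPE = TN / (FP + TN)`.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named list `list(sen = , spe = )`.
#' @export
sen_spe <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0) stop("no positive (proton) samples present", call. = FALSE)
  if (tn + fp == 0) stop("no negative (photon) samples present", call. = FALSE)
  list(sen = tp / (tp + fn), spe = tn / (fp + tn))
}

#' ROC curve and AUC for a continuous decision score
#'
#' Sweeps a threshold over the unique score values (predict positive when
#' score >= threshold), records (1 - SPE, SEN) at each operating point,
#' and integrates by the trapezoidal rule. With midrank tie handling the
#' trapezoidal AUC equals the Mann-Whitney rank statistic
#' `U / (n_pos * n_neg)`.
#'
#' @param scores Numeric decision scores (higher favours the positive,
#'   proton, class).
#' @param labels Binary truth (0/1, or logical): 1 = proton selected.
#' @return Object of class `rt_roc`: list with `points` tibble
#'   (`threshold`, `fpr`, `sen`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be represented in labels", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & labels == 0L) / n_neg,
                   sen = sum(pred & labels == 1L) / n_pos)
  })
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sen, -1) + utils::tail(pts$sen, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "rt_roc")
}

#' @export
print.rt_roc <- function(x, ...) {
  cat(sprintf("<rt_roc> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired two-tailed t-test with advisory distribution checks
#'
#' Parametric paired t-test on the differences `a - b`, two-tailed, with
#' a Shapiro-Wilk normality check on the differences and a Levene
#' equality-of-variances check across the two samples attached as
#' advisory reports (they never switch the test). Degenerate inputs with
#' zero-variance differences are handled explicitly: all-zero differences
#' give the defined limit t = 0, p = 1; constant non-zero differences are
#' flagged degenerate.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return List: `t`, `p`, `df`, `mean_diff`, `degenerate`,
#'   `normality` (list: statistic, p) and `variance` (list: statistic, p).
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  n <- length(d)
  norm <- tryCatch({
    sw <- stats::shapiro.test(d)
    list(statistic = unname(sw$statistic), p = sw$p.value)
  }, error = function(e) list(statistic = NA_real_, p = NA_real_))
  lev <- tryCatch({
    df_lev <- data.frame(value = c(a, b),
                         group = factor(rep(c("a", "b"), each = n)))
    lv <- car::leveneTest(value ~ group, data = df_lev)
    list(statistic = lv[1, "F value"], p = lv[1, "Pr(>F)"])
  }, error = function(e) list(statistic = NA_real_, p = NA_real_))
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, degenerate = FALSE,
                  normality = norm, variance = lev))
    }
    return(list(t = NA_real_, p = NA_real_, df = n - 1, mean_diff = mean(d),
                degenerate = TRUE, normality = norm, variance = lev))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), degenerate = FALSE,
       normality = norm, variance = lev)
}

#' Continuous ranking score behind the decision
#'
#' The decision rule is binary, but ROC analysis needs a continuous
#' ordering. The default score is the predicted photon-minus-proton NTCP
#' difference; cases resolved at step 1 (photon selected without a proton
#' evaluation) are ranked below all step-2 cases via
#' `min(delta, ntcp_photon - step1_threshold)`, which is negative for
#' gated cases. Overridable by supplying any per-case score to
#' [evaluate_cohort()].
#'
#' @param decisions A `decision_record` tibble from [decide_cohort()].
#' @param thresholds The [decision_thresholds()] used.
#' @return Numeric score vector aligned with `decisions` rows.
#' @export
decision_scores <- function(decisions, thresholds = decision_thresholds()) {
  gate <- decisions$ntcp_photon - thresholds$step1_ntcp_threshold
  ifelse(decisions$deciding_step == 1L, pmin(gate, 0), decisions$delta_ntcp)
}

#' Evaluate predicted decisions against ground-truth decisions
#'
#' Accuracy, confusion counts (proton = positive), sensitivity and
#' specificity, ROC/AUC from a continuous score, and the binary-decision
#' AUC `(SEN + SPE) / 2` for transparency.
#'
#' @param decisions_pred,decisions_truth `decision_record` tibbles with
#'   matching `case_id`s.
#' @param scores Optional per-case continuous score (defaults to
#'   [decision_scores()] of the predicted table).
#' @param thresholds [decision_thresholds()] used for the default score.
#' @return List of class `rt_evaluation`: `accuracy`, `counts`
#'   (tp/fp/tn/fn), `sen`, `spe`, `roc` (`rt_roc` or NULL when truth is
#'   single-class), `auc`, `auc_binary`, `per_case` tibble.
#' @export
evaluate_cohort <- function(decisions_pred, decisions_truth, scores = NULL,
                            thresholds = decision_thresholds()) {
  if (!setequal(decisions_pred$case_id, decisions_truth$case_id)) {
    orphans <- c(setdiff(decisions_pred$case_id, decisions_truth$case_id),
                 setdiff(decisions_truth$case_id, decisions_pred$case_id))
    stop(sprintf("case_id mismatch; orphans: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  pred <- decisions_pred[order(decisions_pred$case_id), ]
  truth <- decisions_truth[order(decisions_truth$case_id), ]
  if (is.null(scores)) scores <- decision_scores(pred, thresholds)
  p_pos <- pred$modality == "proton"
  t_pos <- truth$modality == "proton"
  counts <- list(tp = sum(p_pos & t_pos), fp = sum(p_pos & !t_pos),
                 tn = sum(!p_pos & !t_pos), fn = sum(!p_pos & t_pos))
  accuracy <- mean(pred$modality == truth$modality)
  ss <- if (any(t_pos) && any(!t_pos)) {
    sen_spe(counts$tp, counts$fp, counts$tn, counts$fn)
  } else list(sen = NA_real_, spe = NA_real_)
  roc <- if (any(t_pos) && any(!t_pos)) roc_auc(scores, t_pos) else NULL
  per_case <- tibble::new_tibble(list(
    case_id = pred$case_id,
    predicted = pred$modality, truth = truth$modality,
    concordant = pred$modality == truth$modality,
    score = scores
  ), nrow = nrow(pred))
  structure(list(
    accuracy = accuracy, counts = counts, sen = ss$sen, spe = ss$spe,
    roc = roc, auc = if (is.null(roc)) NA_real_ else roc$auc,
    auc_binary = if (is.na(ss$sen)) NA_real_ else (ss$sen + ss$spe) / 2,
    per_case = per_case
  ), class = "rt_evaluation")
}

#' @export
print.rt_evaluation <- function(x, ...) {
  cat(sprintf("<rt_evaluation> accuracy %.4f, AUC %.4f (binary %.4f), SEN %.3f, SPE %.3f\n",
              x$accuracy, x$auc, x$auc_binary, x$sen, x$spe))
  invisible(x)
}
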