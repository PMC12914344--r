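# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC result into its operating points
#' @param x An `rt_roc` from [roc_auc()].
#' @param ... Unused.
#' @return Tibble with `threshold`, `fpr`, `sen`.
#' @export
tidy.rt_roc <- function(x, ...) x$points

#' @rdname tidy.rt_roc
#' @export
glance.rt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a trained dose model into its loss history
#' @param x An `rt_dose_model`.
#' @param ... Unused.
#' @export
tidy.rt_dose_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.rt_dose_model
#' @export
glance.rt_dose_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = x$n_parameters,
    base_filters = x$config$base_filters,
    blocks = paste(x$config$block_counts, collapse = ","),
    epochs = length(x$loss_history),
    final_loss = if (length(x$loss_history)) {
      x$loss_history[length(x$loss_history)]
    } else NA_real_,
    trained = x$trained
  )
}

#' Tidy cross-validation metrics
#' @param x An `rt_cv` from [crossvalidate()].
#' @param ... Unused.
#' @export
tidy.rt_cv <- function(x, ...) x$metrics

#' @rdname tidy.rt_cv
#' @export
glance.rt_cv <- function(x, ...) {
  tidyr::pivot_wider(x$pooled, names_from = "roi",
                     values_from = c("mae", "baseline_mae"))
}

#' Tidy a cohort evaluation into per-case concordance
#' @param x An `rt_evaluation` from [evaluate_cohort()].
#' @param ... Unused.
#' @export
tidy.rt_evaluation <- function(x, ...) x$per_case

#' @rdname tidy.rt_evaluation
#' @export
glance.rt_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc,
                 auc_binary = x$auc_binary, sen = x$sen, spe = x$spe,
                 tp = x$counts$tp, fp = x$counts$fp,
                 tn = x$counts$tn, fn = x$counts$fn)
}

#' Plot a cumulative DVH
#' @param object An `rt_dvh` from [compute_dvh()] (curves for several
#'   ROIs may be row-bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_dvh <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_cgy,
                                       y = .data$volume_pct,
                                       colour = .data$roi)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (cGy)", y = "Volume (%)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#' @param object An `rt_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$sen)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an axial dose slice with structure overlays
#'
#' @param phantom A `phantom`.
#' @param dose A `dose_map`.
#' @param z Axial slice index (defaults to the PTV1 mid-slice).
#' @param rois ROI outlines to overlay.
#' @return A ggplot.
#' @export
plot_dose_slice <- function(phantom, dose, z = NULL,
                            rois = c("PTV1", "rectum", "bladder")) {
  if (is.null(z)) {
    zs <- which(apply(phantom$masks$PTV1, 1, any))
    z <- zs[ceiling(length(zs) / 2)]
  }
  d <- as_dose_array(dose)
  df <- expand.grid(y = seq_len(dim(d)[2]), x = seq_len(dim(d)[3]))
  df$dose <- as.numeric(d[z, , ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dose)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "cGy") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  for (roi in intersect(rois, names(phantom$masks))) {
    m <- phantom$masks[[roi]][z, , ]
    if (!any(m)) next
    edge <- m & !(shift2(m, 1, 0) & shift2(m, -1, 0) &
                    shift2(m, 0, 1) & shift2(m, 0, -1))
    dfe <- df[as.logical(edge), ]
    dfe$roi <- roi
    p <- p + ggplot2::geom_point(data = dfe,
                                 ggplot2::aes(colour = .data$roi),
                                 size = 0.3)
  }
  p + ggplot2::scale_colour_brewer(palette = "Set1", name = NULL)
}

shift2 <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)) - di
  cj <- seq_len(ncol(m)) - dj
  ok_r <- ri >= 1 & ri <= nrow(m)
  ok_c <- cj >= 1 & cj <= ncol(m)
  out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
  out
}

#' @importFrom rlang .data
NULL
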