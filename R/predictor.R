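# Learned dose prediction: three-channel slice-to-dose regression with an
# encoder-decoder bottleneck architecture and fivefold cross-validation.

#' Configuration for the dose-prediction model
#'
#' The architecture is a residual encoder-decoder: a 7x7 stem convolution
#' (stride 2) with max pooling, four bottleneck stages (each bottleneck =
#' 1x1 reduce, 3x3, 1x1 expand convolutions with a residual connection;
#' the second stage strided so the deepest feature map sits at 1/8 of the
#' input resolution), then a fractionally-strided deconvolution restoring
#' the x8 resolution and a 3x3 regression head. The full-depth
#' configuration uses `block_counts = c(3, 4, 23, 5)` with
#' `base_filters = 64`; the default here is a desk-scale variant
#' trainable on one CPU.
#'
#' @param block_counts Integer vector of 4 bottleneck counts per stage.
#' @param base_filters Stem/stage-1 internal width (paper-scale: 64).
#' @param epochs,batch_size,learning_rate Training scalars.
#' @param seed Integer seed governing initialisation and shuffling.
#' @param loss Loss identifier; only `"mse"` (mean squared error on
#'   prescription-normalised dose) is implemented.
#' @param slice_step Train on every `slice_step`-th axial slice
#'   (prediction always uses all slices); 1 = use all.
#' @return Object of class `predictor_config`. `input_channels` is fixed
#'   at 3 and `downscale_factor` at 8.
#' @export
predictor_config <- function(block_counts = c(1L, 1L, 2L, 1L),
                             base_filters = 4L, epochs = 10L, batch_size = 8L,
                             learning_rate = 2e-3, seed = 1L, loss = "mse",
                             slice_step = 2L) {
  stopifnot(length(block_counts) == 4L, all(block_counts >= 1L),
            base_filters >= 1L, epochs >= 1L, batch_size >= 1L,
            learning_rate >= 0, loss == "mse", slice_step >= 1L)
  structure(list(block_counts = as.integer(block_counts),
                 base_filters = as.integer(base_filters),
                 input_channels = 3L, downscale_factor = 8L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss = loss, slice_step = as.integer(slice_step)),
            class = "predictor_config")
}

# Canonical ROI ordering for the structure-map channel.
structure_roi_order <- c("body", "bladder", "colon", "intestine", "femur_L",
                         "femur_R", "rectum", "rectum_wall", "CTV2", "PTV2",
                         "CTV1", "PTV1")

#' Build the three-channel model input for a phantom
#'
#' Channel 1: CT intensities min-max normalised to `[0, 1]`. Channel 2:
#' structure map, each ROI painted as a distinct integer level scaled to
#' `[0, 1]` (later ROIs overwrite earlier ones in overlaps, targets on
#' top). Channel 3: the dose-valued target (DPTV) map — the prescription
#' dose painted into each PTV voxel (dual-gradient cases carry both
#' levels) and 0 elsewhere, normalised by the PTV1 prescription.
#'
#' @param phantom A `phantom` (must have a PTV1 mask).
#' @param presc A [prescription()].
#' @param dose Optional ground-truth `dose_map`; when given, each case
#'   carries a `target` vector (dose / PTV1 prescription).
#' @return List of training cases, one per axial slice intersecting the
#'   body: each a list with `x` ((H*W) x 3 matrix), `target` (numeric or
#'   NULL), `case_id`, `slice_index`, `H`, `W`.
#' @export
make_input_channels <- function(phantom, presc = phantom_prescription(phantom),
                                dose = NULL) {
  if (!"PTV1" %in% names(phantom$masks)) {
    stop("phantom lacks PTV1 mask", call. = FALSE)
  }
  dm <- dim(phantom$intensity)
  ct <- phantom$intensity
  rng <- range(ct)
  ct <- (ct - rng[1]) / max(rng[2] - rng[1], 1e-12)
  struct <- array(0, dm)
  rois <- intersect(structure_roi_order, names(phantom$masks))
  for (i in seq_along(rois)) {
    struct[phantom$masks[[rois[i]]]] <- i
  }
  struct <- struct / length(structure_roi_order)
  dptv <- array(0, dm)
  if (!is.na(presc$ptv2_dose) && "PTV2" %in% names(phantom$masks)) {
    dptv[phantom$masks$PTV2] <- presc$ptv2_dose / presc$ptv1_dose
  }
  dptv[phantom$masks$PTV1] <- 1
  darr <- if (!is.null(dose)) as_dose_array(dose) / presc$ptv1_dose
  zs <- which(apply(phantom$masks$body, 1, any))
  lapply(zs, function(z) {
    x <- cbind(as.numeric(ct[z, , ]), as.numeric(struct[z, , ]),
               as.numeric(dptv[z, , ]))
    list(x = x,
         target = if (!is.null(darr)) as.numeric(darr[z, , ]) else NULL,
         case_id = phantom$patient_id, slice_index = z,
         H = dm[2], W = dm[3])
  })
}

#' Build an (untrained) encoder-decoder dose-regression model
#'
#' @param config A [predictor_config()]; `config$seed` fixes the initial
#'   weights.
#' @return Object of class `rt_dose_model` with the layer stack, the
#'   config and the parameter count (`n_parameters`).
#' @export
build_model <- function(config = predictor_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  bf <- config$base_filters
  layers <- list(new_conv(3L, bf, 7L, 2L, 3L), new_relu(), new_maxpool())
  c_in <- bf
  strides <- c(1L, 2L, 1L, 1L)
  for (s in 1:4) {
    c_mid <- bf * 2L^min(s - 1L, 3L)
    c_out <- 4L * c_mid
    for (b in seq_len(config$block_counts[s])) {
      layers <- c(layers, list(new_bottleneck(
        c_in, c_mid, c_out, stride = if (b == 1L) strides[s] else 1L)))
      c_in <- c_out
    }
  }
  # decoder: three fractionally-strided (x2) deconvolutions interleaved
  # with 3x3 convolutions restore the x8 resolution smoothly
  dch <- c(4L * bf, 2L * bf, bf)
  for (d in seq_len(3L)) {
    layers <- c(layers, list(new_deconv(c_in, dch[d], 2L), new_relu(),
                             new_conv(dch[d], dch[d], 3L, 1L, 1L), new_relu()))
    c_in <- dch[d]
  }
  layers <- c(layers, list(new_conv(bf, 1L, 3L, 1L, 1L)))
  model <- structure(list(layers = layers, config = config,
                          modality = NA_character_, trained = FALSE,
                          input_dim = NULL, loss_history = numeric(0)),
                     class = "rt_dose_model")
  model$n_parameters <- n_params(collect_params(layers))
  model
}

#' @export
print.rt_dose_model <- function(x, ...) {
  cat(sprintf("<rt_dose_model> blocks (%s), base %d, %d parameters, %s\n",
              paste(x$config$block_counts, collapse = ","),
              x$config$base_filters, x$n_parameters,
              if (x$trained) sprintf("trained (%s, %d epochs)", x$modality,
                                     length(x$loss_history))
              else "untrained"))
  invisible(x)
}

pad_to_multiple <- function(H, W, f = 8L) {
  list(H2 = as.integer(ceiling(H / f) * f), W2 = as.integer(ceiling(W / f) * f))
}

# Stack a list of (H*W, 3) slices into a padded batch matrix.
stack_batch <- function(xs, H, W, H2, W2) {
  B <- length(xs)
  X <- matrix(0, B * H2 * W2, ncol(xs[[1]]))
  keep <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * H2, "+"))
  keep_all <- as.vector(outer(keep, (seq_len(B) - 1L) * H2 * W2, "+"))
  for (b in seq_len(B)) {
    X[keep + (b - 1L) * H2 * W2, ] <- xs[[b]]
  }
  list(X = X, keep = keep_all, B = B)
}

model_forward <- function(model, X, B, H, W) {
  for (l in model$layers) {
    r <- switch(l$type,
      conv = conv_forward(l, X, B, H, W),
      relu = list(Y = relu_forward(l, X), H = H, W = W),
      maxpool = maxpool_forward(l, X, B, H, W, ncol(X)),
      bottleneck = bottleneck_forward(l, X, B, H, W),
      deconv = deconv_forward(l, X, B, H, W))
    X <- r$Y; H <- r$H; W <- r$W
  }
  list(Y = X, H = H, W = W)
}

model_backward <- function(model, dY) {
  for (l in rev(model$layers)) {
    dY <- switch(l$type,
      conv = conv_backward(l, dY),
      relu = relu_backward(l, dY),
      maxpool = maxpool_backward(l, dY),
      bottleneck = bottleneck_backward(l, dY),
      deconv = deconv_backward(l, dY))
  }
  invisible(NULL)
}

#' Train the dose-prediction model
#'
#' Mean-squared-error regression of prescription-normalised dose slices
#' on the three input channels, optimised by Adam with seeded shuffling;
#' fully reproducible on one CPU for a fixed config.
#'
#' @param cases List of training cases from [make_input_channels()] (with
#'   targets); at least 2.
#' @param config A [predictor_config()].
#' @param modality Modality tag stored on the model.
#' @return A trained `rt_dose_model` with `loss_history` (mean training
#'   loss per epoch).
#' @export
train_model <- function(cases, config = predictor_config(),
                        modality = NA_character_) {
  if (length(cases) < 2L) stop("need at least 2 training cases", call. = FALSE)
  if (any(vapply(cases, function(cs) is.null(cs$target), logical(1)))) {
    stop("training cases must carry targets", call. = FALSE)
  }
  model <- build_model(config)
  H <- cases[[1]]$H; W <- cases[[1]]$W
  pd <- pad_to_multiple(H, W)
  params <- collect_params(model$layers)
  adam_init(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  n <- length(cases)
  bs <- min(config$batch_size, n)
  t_step <- 0L
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      sel <- ord[start:min(start + bs - 1L, n)]
      sb <- stack_batch(lapply(cases[sel], `[[`, "x"), H, W, pd$H2, pd$W2)
      yt <- matrix(0, nrow(sb$X), 1L)
      yt[sb$keep, 1L] <- unlist(lapply(cases[sel], `[[`, "target"))
      out <- model_forward(model, sb$X, sb$B, pd$H2, pd$W2)
      resid <- out$Y - yt
      loss <- mean(resid^2)
      zero_grads(params)
      model_backward(model, 2 * resid / length(resid))
      clip_grads(params)
      t_step <- t_step + 1L
      adam_step(params, config$learning_rate, t_step)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  model$trained <- TRUE
  model$modality <- modality
  model$input_dim <- c(H, W)
  model$loss_history <- losses
  model
}

#' Predict a dose map for a phantom
#'
#' Runs every axial slice through the trained model, denormalises to cGy
#' using the PTV1 prescription, clips at zero, and re-stacks the slices
#' into a `dose_map` with provenance `"predicted"`.
#'
#' @param model A trained `rt_dose_model`.
#' @param phantom A `phantom` on the training grid resolution.
#' @param presc A [prescription()].
#' @return A `dose_map`.
#' @export
predict_dose <- function(model, phantom,
                         presc = phantom_prescription(phantom)) {
  if (!isTRUE(model$trained)) stop("model is not trained", call. = FALSE)
  dm <- dim(phantom$intensity)
  if (!identical(as.integer(dm[2:3]), as.integer(model$input_dim))) {
    stop(sprintf("phantom grid %dx%d does not match training resolution %dx%d",
                 dm[2], dm[3], model$input_dim[1], model$input_dim[2]),
         call. = FALSE)
  }
  cases <- make_input_channels(phantom, presc)
  H <- dm[2]; W <- dm[3]
  pd <- pad_to_multiple(H, W)
  dose <- array(0, dm)
  chunk <- 8L
  idx <- seq_along(cases)
  for (start in seq(1L, length(cases), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(cases))]
    sb <- stack_batch(lapply(cases[sel], `[[`, "x"), H, W, pd$H2, pd$W2)
    out <- model_forward(model, sb$X, sb$B, pd$H2, pd$W2)
    pred <- out$Y[sb$keep, 1L] * presc$ptv1_dose
    pred[pred < 0] <- 0
    for (b in seq_along(sel)) {
      z <- cases[[sel[b]]]$slice_index
      dose[z, , ] <- matrix(pred[((b - 1L) * H * W + 1L):(b * H * W)], H, W)
    }
  }
  structure(list(dose = dose, spacing = phantom$spacing,
                 modality = model$modality, provenance = "predicted"),
            class = "dose_map")
}

#' Save / load a dose model checkpoint as a single file
#'
#' The checkpoint stores the config, modality, training metadata and all
#' layer weights; loading rebuilds the architecture from the config and
#' restores the weights.
#'
#' @param model A trained `rt_dose_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_model()`: the path, invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  params <- collect_params(model$layers)
  saveRDS(list(
    config = model$config, modality = model$modality,
    trained = model$trained, input_dim = model$input_dim,
    loss_history = model$loss_history,
    weights = lapply(params, function(p) list(W = p$W, b = p$b))
  ), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  params <- collect_params(model$layers)
  stopifnot(length(params) == length(ck$weights))
  for (i in seq_along(params)) {
    params[[i]]$W <- ck$weights[[i]]$W
    params[[i]]$b <- ck$weights[[i]]$b
  }
  model$modality <- ck$modality
  model$trained <- ck$trained
  model$input_dim <- ck$input_dim
  model$loss_history <- ck$loss_history
  model
}

#' Seeded near-equal k-fold partition
#'
#' Cases are shuffled with the seed and dealt round-robin into k folds,
#' so fold sizes differ by at most one (48 cases, k = 5 gives sizes
#' 10, 10, 10, 9, 9).
#'
#' @param n Number of cases.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed.
#' @return Integer fold assignment of length `n`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("cohort smaller than k", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- rep(seq_len(k), length.out = n)
  fold[sample.int(n)]
}

#' Cross-validate the dose predictor against engine ground truth
#'
#' Fivefold (by default) cross-validation: each fold's model is trained
#' on the remaining folds and predicts the held-out cases; accuracy is
#' the prescription-normalised MAE per ROI, with the approved engine
#' doses as ground truth. A voxelwise mean-dose baseline (the mean of
#' the training-fold ground-truth maps) is evaluated alongside as the
#' non-learning reference.
#'
#' @param cohort `rt_cohort` list of phantoms (size `>= k`).
#' @param doses_gt List of ground-truth `dose_map`s aligned with
#'   `cohort` (computed with [plan_dose()] when `NULL`).
#' @param k Number of folds (default 5).
#' @param config A [predictor_config()].
#' @param modality Modality tag (used when computing engine doses).
#' @param rois ROI names to report MAE for.
#' @return List of class `rt_cv`: `metrics` (tibble fold x roi with
#'   `mae` and `baseline_mae`), `pooled` (per-roi two-level cohort MAE),
#'   `folds`, `predicted` (list of predicted `dose_map`s, cohort order).
#' @export
crossvalidate <- function(cohort, doses_gt = NULL, k = 5L,
                          config = predictor_config(),
                          modality = c("photon", "proton"),
                          rois = c("PTV1", "rectum", "rectum_wall", "bladder")) {
  modality <- match.arg(modality)
  n <- length(cohort)
  if (is.null(doses_gt)) {
    doses_gt <- lapply(seq_len(n), function(i) {
      plan_dose(cohort[[i]], beams = beam_config(modality),
                seed = config$seed + i)
    })
  }
  stopifnot(length(doses_gt) == n)
  folds <- make_folds(n, k, config$seed)
  prescs <- lapply(cohort, phantom_prescription)
  all_cases <- lapply(seq_len(n), function(i) {
    make_input_channels(cohort[[i]], prescs[[i]], doses_gt[[i]])
  })
  predicted <- vector("list", n)
  metrics <- list()
  for (f in seq_len(k)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    tr_cases <- unlist(lapply(all_cases[train_idx], function(cs) {
      cs[seq(1L, length(cs), by = config$slice_step)]
    }), recursive = FALSE)
    model <- train_model(tr_cases, config, modality)
    mean_map <- Reduce(`+`, lapply(doses_gt[train_idx], as_dose_array)) /
      length(train_idx)
    for (i in test_idx) {
      predicted[[i]] <- predict_dose(model, cohort[[i]], prescs[[i]])
    }
    for (roi in rois) {
      have <- test_idx[vapply(test_idx, function(i) {
        m <- cohort[[i]]$masks[[roi]]; !is.null(m) && any(m)
      }, logical(1))]
      if (length(have) == 0) next
      mae_pred <- dose_mae(predicted[have], doses_gt[have],
                           lapply(have, function(i) cohort[[i]]$masks[[roi]]),
                           prescription_dose = prescs[[1]]$ptv1_dose,
                           case_ids = vapply(have, function(i)
                             cohort[[i]]$patient_id, character(1)))
      mae_base <- dose_mae(rep(list(mean_map), length(have)), doses_gt[have],
                           lapply(have, function(i) cohort[[i]]$masks[[roi]]),
                           prescription_dose = prescs[[1]]$ptv1_dose)
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        fold = f, roi = roi, n_test = length(have),
        mae = mae_pred, baseline_mae = mae_base)
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  pooled <- metrics |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      mae = stats::weighted.mean(.data$mae, .data$n_test),
      baseline_mae = stats::weighted.mean(.data$baseline_mae, .data$n_test),
      .groups = "drop")
  structure(list(metrics = metrics, pooled = pooled, folds = folds,
                 predicted = predicted, modality = modality),
            class = "rt_cv")
}

#' @export
print.rt_cv <- function(x, ...) {
  cat(sprintf("<rt_cv %s> %d folds\n", x$modality, max(x$folds)))
  print(x$pooled)
  invisible(x)
}
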