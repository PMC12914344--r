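test_that("input channels follow the normalisation contracts", {
  ph <- fix_phantom(4, dual = TRUE)
  presc <- phantom_prescription(ph)
  cases <- make_input_channels(ph, presc)
  expect_equal(length(cases), sum(apply(ph$masks$body, 1, any)))
  cs <- cases[[which(vapply(cases, function(x) x$slice_index, integer(1)) ==
                       round(mean(which(apply(ph$masks$PTV1, 1, any)))))]]
  z <- cs$slice_index
  dm <- dim(ph$intensity)
  x <- cs$x
  expect_true(all(x[, 1] >= 0 & x[, 1] <= 1))  # CT min-max
  expect_true(all(x[, 2] >= 0 & x[, 2] <= 1))  # structure levels
  # DPTV: 1 inside PTV1, ptv2/ptv1 ratio inside PTV2 only, 0 outside
  in1 <- as.numeric(ph$masks$PTV1[z, , ])
  in2 <- as.numeric(ph$masks$PTV2[z, , ])
  expect_true(all(x[in1 == 1, 3] == 1))
  only2 <- in2 == 1 & in1 == 0
  if (any(only2)) {
    expect_true(all(abs(x[only2, 3] - presc$ptv2_dose / presc$ptv1_dose)
                    < 1e-12))
  }
  outside <- in1 == 0 & in2 == 0
  expect_true(all(x[outside, 3] == 0))

  ph_bad <- ph
  ph_bad$masks$PTV1 <- NULL
  expect_error(make_input_channels(ph_bad, presc), "PTV1")
})

test_that("model construction honours shape, depth and seeding contracts", {
  cfg <- predictor_config(block_counts = c(1, 1, 2, 1), base_filters = 4,
                          seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  expect_gt(m1$n_parameters, 0)

  # shape contract on a 64x64 slice through the untrained stack
  x <- matrix(stats::rnorm(64 * 64 * 3), ncol = 3)
  out <- rtdecide:::model_forward(m1, x, 1L, 64L, 64L)
  expect_equal(out$H, 64L)
  expect_equal(out$W, 64L)
  expect_equal(dim(out$Y), c(64L * 64L, 1L))

  # full-depth configuration builds (not trained here)
  big <- build_model(predictor_config(block_counts = c(3, 4, 23, 5),
                                      base_filters = 64, seed = 1))
  expect_gt(length(rtdecide:::collect_params(big$layers)), 100)
  expect_gt(big$n_parameters, 1e7)
})

test_that("training reduces the loss, reproducibly, and lr 0 freezes it", {
  ph <- fix_phantom(1)
  gt <- fix_plan("photon", 1)
  cases <- make_input_channels(ph, phantom_prescription(ph), gt)
  cases <- cases[seq(1, length(cases), by = 6)]
  cfg <- predictor_config(epochs = 5, seed = 2)
  m1 <- train_model(cases, cfg, "photon")
  expect_lt(m1$loss_history[5], m1$loss_history[1])
  m2 <- train_model(cases, cfg, "photon")
  expect_identical(m1$loss_history, m2$loss_history)

  frozen <- train_model(cases, predictor_config(epochs = 3, seed = 2,
                                                learning_rate = 0), "photon")
  expect_equal(max(abs(diff(frozen$loss_history))), 0, tolerance = 1e-12)
  expect_error(train_model(cases[1], cfg), "at least 2")
})

test_that("prediction respects shape, non-negativity and resolution checks", {
  ph <- fix_phantom(1)
  gt <- fix_plan("photon", 1)
  cases <- make_input_channels(ph, phantom_prescription(ph), gt)
  mod <- train_model(cases[seq(1, length(cases), by = 4)],
                     predictor_config(epochs = 6, seed = 4), "photon")
  pred <- predict_dose(mod, ph)
  expect_identical(dim(pred$dose), dim(ph$intensity))
  expect_true(all(pred$dose >= 0))
  expect_identical(pred$provenance, "predicted")

  # a near-converged model beats predicting nothing at all on its own case
  mae_pred <- dose_mae(pred, gt, ph$masks$PTV1, 6750)
  mae_zero <- dose_mae(tiny_dose(0, dim(gt$dose), ph$spacing), gt,
                       ph$masks$PTV1, 6750)
  expect_lt(mae_pred, mae_zero)

  small <- generate_phantom(cohort_spec(grid_dim = c(36L, 48L, 48L),
                                        spacing = c(3, 3, 3)), seed = 9)
  expect_error(predict_dose(mod, small), "resolution")
  untrained <- build_model(predictor_config())
  expect_error(predict_dose(untrained, ph), "not trained")
})

test_that("fold partitions are seeded, near-equal and exhaustive", {
  f1 <- make_folds(10, 5, seed = 3)
  expect_identical(f1, make_folds(10, 5, seed = 3))
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(f1) == 2))
  f2 <- make_folds(48, 5, seed = 1)
  expect_equal(sort(as.integer(table(f2)), decreasing = TRUE),
               c(10L, 10L, 10L, 9L, 9L))
  expect_error(make_folds(10, 1), "k must be")
  expect_error(make_folds(3, 5), "smaller")
})
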