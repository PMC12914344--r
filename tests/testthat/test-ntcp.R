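test_that("logistic linear predictor matches the published coefficients", {
  expect_equal(logistic_s(0, 0), -3.07)
  expect_equal(logistic_s(25, 1), -3.07 + 0.79 + 0.12 * 25)
  expect_equal(logistic_s(10, 0), -1.87)
  expect_error(logistic_s(120, 0), "\\[0, 100\\]")
  expect_error(logistic_s(-1, 0), "\\[0, 100\\]")
})

test_that("logistic NTCP is the standard logistic with complement symmetry", {
  expect_equal(logistic_ntcp(0), 0.5)
  expect_equal(logistic_ntcp(-3.07), stats::plogis(-3.07))
  expect_equal(logistic_ntcp(3.07), 1 - logistic_ntcp(-3.07))
  s <- seq(-8, 8, by = 0.25)
  expect_true(all(diff(logistic_ntcp(s)) > 0))
  expect_true(all(logistic_ntcp(s) > 0 & logistic_ntcp(s) < 1))
  # the as-printed audit form is not a probability
  expect_gt(logistic_ntcp(3, as_printed = TRUE), 1)
})

test_that("LKB NTCP is the probit response in the standard parameterisation", {
  p <- lkb_params(td50 = 80, m = 0.15)
  expect_equal(lkb_ntcp(80, p), 0.5)
  expect_equal(lkb_ntcp(68, p), stats::pnorm(-1))   # u = -12 / 12
  euds <- seq(10, 150, by = 5)
  expect_true(all(diff(lkb_ntcp(euds, p)) > 0))
  expect_lt(lkb_ntcp(1e-9, lkb_params(td50 = 80, m = 0.15)), 1e-6)
})

test_that("generalized EUD reduces dose distributions correctly", {
  m <- array(TRUE, c(2, 2, 2))
  expect_equal(generalized_eud(tiny_dose(4200), m, a = 7), 42)
  expect_equal(generalized_eud(tiny_dose(c(200, 800, 200, 800, 200, 800,
                                           200, 800)), m, a = 1), 5)
  d <- tiny_dose(c(200, 800, rep(0, 6)))
  m2 <- array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  expect_equal(generalized_eud(d, m2, a = 2), sqrt((4 + 64) / 2))
  expect_error(generalized_eud(d, m2, a = 0), "geometric")
})

test_that("delta NTCP is the photon-minus-proton difference in points", {
  expect_equal(delta_ntcp(0.20, 0.08), 12)
  expect_equal(delta_ntcp(0.3, 0.3), 0)
  expect_equal(delta_ntcp(0.08, 0.20), -12)
  expect_error(delta_ntcp(1.2, 0.1), ">=")
})

test_that("NTCP increases with V6300 and with anticoagulant use", {
  v <- seq(0, 100, by = 1)
  n0 <- logistic_ntcp(logistic_s(v, 0))
  n1 <- logistic_ntcp(logistic_s(v, 1))
  expect_true(all(diff(n0) > 0))
  expect_true(all(n1 > n0))
})
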