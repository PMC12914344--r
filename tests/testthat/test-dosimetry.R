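test_that("DVH and point metrics match exhaustive voxel counting", {
  set.seed(101)
  for (rep in 1:10) {
    dm <- c(sample(3:8, 1), sample(3:8, 1), sample(3:8, 1))
    dose <- array(runif(prod(dm), 0, 8000), dm)
    mask <- array(runif(prod(dm)) < 0.5, dm)
    if (!any(mask)) mask[1] <- TRUE
    d <- tiny_dose(dose, dm)
    thr <- runif(1, 0, 8000)
    expect_equal(v_at_dose(d, mask, thr),
                 100 * sum(dose[mask] >= thr) / sum(mask))
    expect_equal(d_max(d, mask), max(dose[mask]))
    dvh <- compute_dvh(d, mask, bin_width = 500)
    expect_equal(dvh$volume_pct[1], 100)
    expect_true(all(diff(dvh$volume_pct) <= 0))
    expect_equal(dvh$volume_pct[nrow(dvh)], 0)
    # every binned point equals exact counting at that edge
    for (k in seq_len(nrow(dvh))) {
      ref <- if (dvh$dose_cgy[k] == 0) 100
        else 100 * sum(dose[mask] >= dvh$dose_cgy[k]) / sum(mask)
      expect_equal(dvh$volume_pct[k], ref)
    }
  }
})

test_that("point metrics handle boundary thresholds and tiny ROIs", {
  d <- tiny_dose(c(10, 20, 30, 40, 0, 0, 0, 0))
  mask <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
  expect_equal(v_at_dose(d, mask, 0), 100)
  expect_equal(v_at_dose(d, mask, 25), 50)
  expect_equal(v_at_dose(d, mask, 41), 0)
  expect_equal(d_max(d, mask), 40)
  empty <- array(FALSE, c(2, 2, 2))
  expect_error(v_at_dose(d, empty, 10, roi = "rectum"), "rectum")
  expect_error(d_max(d, empty), "empty")
  expect_error(compute_dvh(d, empty), "empty")

  # two-voxel DVH: 50% between the two dose values
  d2 <- tiny_dose(c(4000, 8000, 0, 0, 0, 0, 0, 0))
  m2 <- array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  expect_equal(v_at_dose(d2, m2, 4001), 50)
  expect_equal(v_at_dose(d2, m2, 8000), 50)
  expect_equal(v_at_dose(d2, m2, 8001), 0)
})

test_that("EQD2 transform has its closed-form fixed points", {
  # at 2 Gy per fraction the transform is the identity
  p50 <- fractionation_params(n_fractions = 25)
  d <- tiny_dose(5000)  # 50 Gy / 25 fx = 2 Gy per fraction
  expect_equal(eqd2_transform(d, p50)$dose, d$dose)
  # 67.5 Gy in 25 fractions at alpha/beta = 3: 67.5 * 5.7 / 5 = 76.95 Gy
  d2 <- tiny_dose(6750)
  expect_equal(eqd2_transform(d2, p50)$dose[1], 7695, tolerance = 1e-12)
  expect_equal(eqd2_transform(tiny_dose(0), p50)$dose[1], 0)
  # amplifying above 2 Gy per fraction, reducing below
  expect_gt(eqd2_transform(tiny_dose(6000), p50)$dose[1], 6000)
  expect_lt(eqd2_transform(tiny_dose(4000), p50)$dose[1], 4000)
})

test_that("rectum-wall V6300 chains EQD2 into exact counting", {
  ph <- fix_phantom(1)
  dm <- dim(ph$intensity)
  wall <- ph$masks$rectum_wall
  unif <- tiny_dose(6750, dm, ph$spacing)
  expect_equal(v6300_rectum_wall(unif, ph), 100)
  expect_equal(v6300_rectum_wall(tiny_dose(0, dm, ph$spacing), ph), 0)
  # half the wall at prescription, half at zero
  dose <- array(0, dm)
  w <- which(wall)
  dose[w[seq_len(floor(length(w) / 2))]] <- 6750
  expect_equal(v6300_rectum_wall(tiny_dose(dose, dm, ph$spacing), ph),
               100 * floor(length(w) / 2) / length(w))
  ph_nowall <- ph
  ph_nowall$masks$rectum_wall <- NULL
  expect_error(v6300_rectum_wall(unif, ph_nowall), "rectum_wall")
})

test_that("prescription-normalised MAE is a two-level average", {
  a <- tiny_dose(7000); b <- tiny_dose(6750)
  m <- array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))
  expect_equal(dose_mae(a, a, m, 6750), 0)
  expect_equal(dose_mae(a, b, m, 6750), 100 * 250 / 6750)
  # symmetry
  expect_equal(dose_mae(a, b, m, 6750), dose_mae(b, a, m, 6750))
  # outer average over cases: per-case MAEs 2% and 4% pool to 3%
  base <- tiny_dose(1000)
  p1 <- tiny_dose(1000 + 0.02 * 5000)
  p2 <- tiny_dose(1000 + 0.04 * 5000)
  mall <- array(TRUE, c(2, 2, 2))
  expect_equal(dose_mae(list(p1, p2), list(base, base), list(mall, mall),
                        5000), 3)
  expect_error(dose_mae(a, b, array(FALSE, c(2, 2, 2)), 6750,
                        case_ids = "case_X"), "case_X")
})
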