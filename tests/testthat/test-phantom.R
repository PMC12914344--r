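test_that("phantom generation is deterministic and satisfies mask algebra", {
  spec <- cohort_spec()
  ph1 <- generate_phantom(spec, seed = 1)
  ph2 <- generate_phantom(spec, seed = 1)
  expect_identical(ph1, ph2)

  for (seed in c(1, 2, 3)) {
    ph <- generate_phantom(spec, seed = seed)
    dims <- lapply(ph$masks, dim)
    expect_true(all(vapply(dims, identical, logical(1), dim(ph$intensity))))
    expect_true(all(ph$spacing > 0))
    # rectum wall is a shell of the rectum
    expect_equal(sum(ph$masks$rectum_wall & !ph$masks$rectum), 0)
    expect_true(all(ph$masks$CTV1 <= ph$masks$PTV1))
    expect_true(ph$anticoagulant_use %in% c(0L, 1L))
    expect_true(all(c("PTV1", "CTV1", "rectum", "rectum_wall", "bladder")
                    %in% names(ph$masks)))
  }

  ph_dual <- generate_phantom(spec, seed = 4, dual_gradient = TRUE)
  expect_true(all(ph_dual$masks$CTV2 <= ph_dual$masks$PTV2))
  expect_true(ph_dual$ptv2_dose %in% c(4500, 5000))
})

test_that("posterior margin forces a rectum/PTV1 overlap", {
  ph <- generate_phantom(cohort_spec(), seed = 2)
  expect_gt(sum(ph$masks$rectum & ph$masks$PTV1), 0)
})

test_that("phantom generation rejects grids too small for the anatomy", {
  spec <- cohort_spec(grid_dim = c(34L, 34L, 34L), spacing = c(1, 1, 1))
  expect_error(generate_phantom(spec, seed = 1), "grid too small")
})

test_that("margin expansion matches the exhaustive directional oracle", {
  # single voxel, isotropic margin
  m <- array(FALSE, c(11L, 11L, 11L))
  m[6, 6, 6] <- TRUE
  sp <- c(2, 2, 2)
  mg <- margin_spec(1, 1, 1, 1, 1, 1)  # 10 mm isotropic
  expect_identical(expand_ctv_to_ptv(m, mg, sp), brute_force_expand(m, mg, sp))

  # anisotropic margins on random blobs
  set.seed(42)
  for (rep in 1:3) {
    m <- array(FALSE, c(10L, 12L, 9L))
    idx <- cbind(sample(4:7, 4, TRUE), sample(5:8, 4, TRUE),
                 sample(4:6, 4, TRUE))
    m[idx] <- TRUE
    sp <- c(2.5, 2, 3)
    mg <- margin_spec(0.4, 0.8, 0.5, 0.3, 0.7, 0.5)
    expect_identical(expand_ctv_to_ptv(m, mg, sp),
                     brute_force_expand(m, mg, sp))
  }
})

test_that("margin expansion identity, supersetting and layer counts", {
  m <- array(FALSE, c(9L, 15L, 9L))
  m[4:6, 7:9, 4:6] <- TRUE
  sp <- c(2.5, 2.5, 2.5)
  expect_identical(expand_ctv_to_ptv(m, margin_spec(0, 0, 0, 0, 0, 0), sp), m)
  out <- expand_ctv_to_ptv(m, default_margins("PTV2"), sp)
  expect_true(all(m <= out))
  # nodal-target margins: posterior face extends floor(5/2.5) = 2 layers,
  # anterior floor(7/2.5) = 2, left/right floor(7/2.5) = 2
  ys <- range(which(apply(out, 2, any)))
  expect_equal(ys, c(7 - 2, 9 + 2))
  expect_error(expand_ctv_to_ptv(array(FALSE, c(4, 4, 4)),
                                 default_margins("PTV1"), sp), "empty")
})

test_that("cohorts are reproducible with near-spec covariate prevalences", {
  spec <- cohort_spec(n_cases = 5, seed = 7,
                      grid_dim = c(40L, 40L, 40L), spacing = c(3, 3, 3))
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 5)
  expect_length(generate_cohort(cohort_spec(n_cases = 1, seed = 3,
                                            grid_dim = c(40L, 40L, 40L),
                                            spacing = c(3, 3, 3))), 1)

  spec_big <- cohort_spec(n_cases = 400, seed = 11,
                          anticoagulant_prevalence = 0.25,
                          grid_dim = c(40L, 52L, 52L), spacing = c(3, 3, 3))
  big <- generate_cohort(spec_big)
  prev <- mean(vapply(big, `[[`, integer(1), "anticoagulant_use"))
  expect_lt(abs(prev - 0.25), 0.07)  # binomial 99% interval
})
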