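test_that("two-step rule handles the canonical cases and boundaries", {
  r <- decide(8)
  expect_equal(r$modality, "photon"); expect_equal(r$deciding_step, 1L)
  expect_true(is.na(r$ntcp_proton))

  r <- decide(15, 8)
  expect_equal(r$modality, "photon"); expect_equal(r$deciding_step, 2L)
  expect_equal(r$delta_ntcp, 7)

  r <- decide(25, 10)
  expect_equal(r$modality, "proton"); expect_equal(r$deciding_step, 2L)

  # boundaries: "exceeds" is strict at both steps
  expect_equal(decide(10)$deciding_step, 1L)
  expect_equal(decide(10)$modality, "photon")
  expect_equal(decide(20.0, 10.0)$modality, "photon")  # delta exactly 10
  expect_equal(decide(20.0 + 1e-9, 10.0)$modality, "proton")

  # negative delta (proton worse) selects photon
  expect_equal(decide(15, 20)$modality, "photon")
  expect_error(decide(150), "\\[0, 100\\]")
  expect_error(decide(15, NULL), "required at step 2")
})

test_that("proton branch is evaluated lazily", {
  calls <- 0L
  provider <- function() { calls <<- calls + 1L; 5 }
  decide(8, provider)
  expect_equal(calls, 0L)
  decide(12, provider)
  expect_equal(calls, 1L)
  failing <- function() stop("proton plan unavailable")
  expect_error(decide(12, failing, case_id = "p7"), "p7")
  expect_silent(decide(9, failing))
})

test_that("rule agrees with brute-force enumeration over the NTCP grid", {
  th <- decision_thresholds()
  grid <- seq(0, 100, by = 2.5)
  for (np in grid) {
    for (npr in grid) {
      rec <- decide(np, npr, th)
      expected <- if (!(np > 10)) "photon"
        else if ((np - npr) > 10) "proton" else "photon"
      expect_identical(rec$modality, expected)
      if (rec$modality == "proton") expect_equal(rec$deciding_step, 2L)
    }
  }
})

test_that("decreasing proton NTCP never flips proton back to photon", {
  for (np in c(15, 30, 60)) {
    mods <- vapply(seq(np, 0, by = -1),
                   function(npr) decide(np, npr)$modality, character(1))
    first_proton <- match("proton", mods)
    if (!is.na(first_proton)) {
      expect_true(all(mods[first_proton:length(mods)] == "proton"))
    }
  }
})

test_that("cohort decisions consume NTCP tables lazily per case", {
  tbl <- tibble::tibble(
    case_id = rep(c("a", "b", "c"), each = 2),
    modality = rep(c("photon", "proton"), 3),
    ntcp = c(0.05, 0.02, 0.30, 0.10, 0.15, 0.12)
  )
  dec <- decide_cohort(tbl)
  expect_equal(dec$modality, c("photon", "proton", "photon"))
  expect_equal(dec$deciding_step, c(1L, 2L, 2L))
  expect_true(is.na(dec$ntcp_proton[1]))  # step-1 case never looked it up

  # a missing proton row only matters when step 2 is reached
  tbl2 <- tbl[-2, ]
  expect_equal(decide_cohort(tbl2)$modality[1], "photon")
  tbl3 <- tbl[-4, ]
  expect_error(decide_cohort(tbl3), "case 'b'")
})
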