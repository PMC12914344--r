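test_that("sensitivity and specificity follow their definitions", {
  expect_equal(sen_spe(5, 0, 7, 0), list(sen = 1, spe = 1))
  expect_equal(sen_spe(8, 1, 9, 2), list(sen = 0.8, spe = 0.9))
  expect_equal(sen_spe(0, 0, 5, 5), list(sen = 0, spe = 1))
  expect_error(sen_spe(0, 3, 4, 0), "positive")
  expect_error(sen_spe(2, 0, 0, 1), "negative")
})

test_that("ROC/AUC equals the exhaustive pair-ordering statistic", {
  # hand-checkable case: 3 of 4 pairs ordered correctly
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1)
  # random instances incl. ties
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq_len(max(2, n %/% 2)), n, TRUE) +
      sample(c(0, 0.5), n, TRUE)
    expect_equal(roc_auc(scores, labels)$auc, pair_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC points run from (0,0) to (1,1) monotonically", {
  set.seed(8)
  r <- roc_auc(rnorm(40), rbinom(40, 1, 0.4))
  expect_equal(unlist(r$points[1, c("fpr", "sen")], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "sen")],
                      use.names = FALSE), c(1, 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$sen) >= 0))
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:5) {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("label permutation drives AUC to one half", {
  # one permutation of 10^4 pairs has null sd ~0.04, so the 0.05 band is
  # checked on the mean over permutations (se ~0.006)
  set.seed(10)
  scores <- rnorm(200)
  labels <- rep(c(0, 1), each = 100)   # 10^4 positive-negative pairs
  aucs <- replicate(40, roc_auc(scores, sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("paired t-test matches the closed form and reference implementation", {
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), df = 2), tolerance = 1e-12)
  expect_equal(r$df, 2)

  a <- c(5, 6, 7)
  expect_equal(paired_t_test(a, a)$t, 0)
  expect_equal(paired_t_test(a, a)$p, 1)
  # constant non-zero difference is degenerate
  expect_true(paired_t_test(a + 2, a)$degenerate)

  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, sd = 2)
    ours <- paired_t_test(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    swapped <- paired_t_test(y, x)
    expect_equal(swapped$t, -ours$t, tolerance = 1e-12)
    expect_equal(swapped$p, ours$p, tolerance = 1e-12)
  }
})

test_that("advisory distribution checks are attached but never gate", {
  set.seed(12)
  x <- rexp(20); y <- rexp(20)
  r <- paired_t_test(x, y)
  expect_true(is.numeric(r$normality$p))
  expect_true(is.numeric(r$variance$p))
  # result identical to the parametric test regardless of the checks
  expect_equal(r$p, stats::t.test(x, y, paired = TRUE)$p.value)
})

test_that("cohort evaluation computes accuracy, confusion and ROC", {
  mk <- function(mods, ids = sprintf("c%02d", seq_along(mods))) {
    tibble::tibble(case_id = ids, ntcp_photon = 20,
                   ntcp_proton = ifelse(mods == "proton", 5, 15),
                   delta_ntcp = ifelse(mods == "proton", 15, 5),
                   modality = mods, deciding_step = 2L)
  }
  truth <- mk(rep(c("proton", "photon"), c(5, 7)))
  expect_equal(evaluate_cohort(truth, truth)$accuracy, 1)

  pred <- truth
  pred$modality[1] <- "photon"; pred$delta_ntcp[1] <- 5
  pred$modality[6] <- "proton"; pred$delta_ntcp[6] <- 15
  ev <- evaluate_cohort(pred, truth)
  expect_equal(ev$accuracy, 10 / 12)
  expect_equal(ev$counts, list(tp = 4, fp = 1, tn = 6, fn = 1))
  expect_equal(ev$sen, 0.8); expect_equal(ev$spe, 6 / 7)
  expect_equal(ev$auc_binary, (0.8 + 6 / 7) / 2)
  expect_true(ev$auc >= 0 && ev$auc <= 1)

  flipped <- truth
  flipped$modality <- ifelse(truth$modality == "proton", "photon", "proton")
  flipped$delta_ntcp <- ifelse(flipped$modality == "proton", 15, 5)
  ev2 <- evaluate_cohort(flipped, truth)
  expect_equal(ev2$accuracy, 0)
  expect_equal(ev2$sen, 0); expect_equal(ev2$spe, 0)

  orphan <- truth[-1, ]
  expect_error(evaluate_cohort(orphan, truth), "c01")
})

test_that("gated cases rank below step-2 cases in the default score", {
  dec <- tibble::tibble(
    case_id = c("a", "b", "c"),
    ntcp_photon = c(6, 30, 12),
    ntcp_proton = c(NA, 10, 8),
    delta_ntcp = c(NA, 20, 4),
    modality = c("photon", "proton", "photon"),
    deciding_step = c(1L, 2L, 2L)
  )
  s <- decision_scores(dec)
  expect_lt(s[1], 0)
  expect_true(all(s[1] < s[2:3]))
})
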