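test_that("ROC from rankings matches hand-counted examples", {
  # cases ranked on top: perfect separation
  expect_equal(roc_from_ranking(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 1)
  # interleaved: 3 of 4 case-control pairs concordant
  expect_equal(roc_from_ranking(c(1, 2, 3, 4), c(1, 0, 1, 0))$auc, 0.75)
  # reversing the ranking reflects the AUC
  r <- withr::with_seed(1, sample(1:8))
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  a <- roc_from_ranking(r, y)$auc
  b <- roc_from_ranking(9 - r, y)$auc
  expect_equal(a, 1 - b)
  expect_error(roc_from_ranking(1:3, c(1, 1, 1)),
               class = "saccadom_domain_error")
})

test_that("ROC/AUC equals the exhaustive pair-counting oracle (n <= 10)", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(4:10, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      scores <- sample(seq_len(5), n, replace = TRUE)  # ties likely
      out <- roc_from_ranking(rank(-scores, ties.method = "average"), y)
      expect_equal(out$auc, auc_bruteforce(scores, y))
      # trapezoidal area under the returned curve agrees with the identity
      curve <- out$curve
      trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
      expect_equal(trap, out$auc, tolerance = 1e-12)
    }
  })
})

test_that("TLPO follows its combinatorial identities for all n", {
  for (n_half in c(2, 3, 5)) {
    ft <- feature_cohort(n_half, n_half, p = 3, shift = 1, seed = n_half)
    res <- tlpo_cv(ft, centroid_trainer(), seed = 1)
    n <- 2L * n_half
    expect_equal(res$n_fits, choose(n, 2))
    expect_equal(res$train_size_per_fit, n - 2L)
    expect_true(all(res$wins$wins >= 0 & res$wins$wins <= n - 1))
    expect_equal(sum(res$wins$wins), choose(n, 2))
  }
})

test_that("an oracle trainer attains AUC 1 and a coin-flip trainer stays near 0.5", {
  ft <- feature_cohort(8, 8, p = 3, seed = 2)
  ft$f01 <- as.numeric(ft$group == "pd")  # feature 1 equals the label
  res <- tlpo_cv(ft, first_feature_trainer(), seed = 1)
  expect_equal(res$auc, 1)
  expect_identical(res$n_failed, 0L)

  aucs <- vapply(1:10, function(s) {
    ft0 <- feature_cohort(10, 10, p = 3, seed = 100 + s)
    tlpo_cv(ft0, coin_trainer(), seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("TLPO results are reproducible and order-independent", {
  ft <- feature_cohort(6, 6, p = 4, shift = 0.8, seed = 3)
  a <- tlpo_cv(ft, logistic_trainer(select = FALSE), seed = 9)
  b <- tlpo_cv(ft, logistic_trainer(select = FALSE), seed = 9)
  expect_identical(a$wins, b$wins)
  # permuting participants leaves each participant's win count unchanged
  perm <- withr::with_seed(4, ft[sample(nrow(ft)), ])
  c_ <- tlpo_cv(perm, centroid_trainer(), seed = 9)
  d_ <- tlpo_cv(ft, centroid_trainer(), seed = 9)
  expect_equal(
    c_$wins[order(c_$wins$participant_id), ]$wins,
    d_$wins[order(d_$wins$participant_id), ]$wins)
})

test_that("identical classifiers give a degenerate 5x2 comparison", {
  ft <- feature_cohort(8, 8, p = 3, shift = 1, seed = 6)
  same <- five_by_two_f_test(ft, centroid_trainer(), centroid_trainer(),
                             seed = 5)
  expect_true(same$degenerate)
  expect_equal(same$p.value, 1)
})

test_that("the 5x2 test separates an oracle from a coin flip", {
  ft <- feature_cohort(50, 50, p = 3, seed = 7)
  ft$f01 <- as.numeric(ft$group == "pd")
  res <- five_by_two_f_test(ft, first_feature_trainer(), coin_trainer(),
                            seed = 11)
  expect_false(res$degenerate)
  expect_lt(res$p.value, 0.05)
  expect_identical(nrow(res$differences), 10L)
  # all test-fold AUCs of the oracle are 1
  expect_true(all(res$differences$auc_a == 1))
})
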