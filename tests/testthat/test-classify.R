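test_that("Yeo-Johnson standardisation centres, scales and symmetrises", {
  out <- yeo_johnson_standardize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(mean(out$train), 0, tolerance = 1e-12)
  expect_equal(sd(out$train), 1, tolerance = 1e-12)
  # lambda = 1 is the identity transform
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(yeo_johnson(x, 1), x)
  # a right-skewed lognormal sample becomes nearly symmetric (the +1 offset
  # in the transform leaves a small residual skew)
  z <- withr::with_seed(3, exp(rnorm(1e4)))
  tz <- yeo_johnson(z, saccadom:::yeo_johnson_lambda(z))
  expect_lt(abs(e1071::skewness(tz)), 0.2)
  expect_lt(abs(e1071::skewness(tz)), abs(e1071::skewness(z)) / 10)
})

test_that("Yeo-Johnson lambda agrees with the car::powerTransform oracle", {
  skip_if_not_installed("car")
  z <- withr::with_seed(4, exp(rnorm(500)) - 0.5)
  ours <- saccadom:::yeo_johnson_lambda(z)
  ref <- car::powerTransform(z, family = "yjPower")$lambda
  expect_equal(ours, unname(ref), tolerance = 0.02)
})

test_that("train-only estimation keeps held-out data out of the transform", {
  tr <- matrix(withr::with_seed(5, rexp(60)), ncol = 2)
  te <- matrix(withr::with_seed(6, rexp(20)), ncol = 2)
  a <- yeo_johnson_standardize(tr, te)
  b <- yeo_johnson_standardize(rbind(tr, te), te)
  # refitting on all data changes the applied transform: leak detector
  expect_false(isTRUE(all.equal(a$apply, b$apply)))
  # applying the train parameters to the train data reproduces train output
  c2 <- yeo_johnson_standardize(tr, tr)
  expect_equal(c2$apply, c2$train)
})

test_that("constant training columns are dropped, not fabricated", {
  m <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  out <- yeo_johnson_standardize(m)
  expect_identical(out$dropped, "a")
  expect_identical(colnames(out$train), "b")
})

test_that("mutual information ranks dependence sensibly", {
  y <- withr::with_seed(7, rbinom(300, 1, 0.5))
  noise <- withr::with_seed(8, rnorm(300))
  expect_gt(mutual_information(y, y), 0.5)
  expect_lt(mutual_information(noise, y), 0.05)
  x <- withr::with_seed(9, rnorm(300))
  expect_gt(mutual_information(x, x + rnorm(300, 0, 0.1)),
            mutual_information(x, noise))
})

test_that("forward selection picks a label-equal feature first", {
  y <- withr::with_seed(10, rbinom(100, 1, 0.5))
  x <- cbind(n1 = rnorm(100), label_copy = y, n2 = rnorm(100))
  s <- rmi_forward_select(x, y, seed = 1)
  expect_identical(s$selected[1], "label_copy")
})

test_that("the residual step recovers the second XOR parent", {
  withr::with_seed(12, {
    x1 <- rbinom(200, 1, 0.5); x2 <- rbinom(200, 1, 0.5)
    y <- as.numeric(xor(x1, x2))
    # marginal MI of each parent is null...
    expect_lt(mutual_information(x1, y), 0.02)
    expect_lt(mutual_information(x2, y), 0.02)
    # ...but once one parent is modelled, the model residual encodes the
    # (parent, label) pair and the other parent becomes near-deterministic
    fit <- train_logistic(matrix(x1, ncol = 1), y)
    r <- y - predict(fit, matrix(x1, ncol = 1))
    expect_gt(mutual_information(x2, r), 0.5)
    expect_lt(mutual_information(rbinom(200, 1, 0.5), r), 0.05)
  })
})

test_that("selection stops early on pure-noise features", {
  sizes <- withr::with_seed(13, replicate(10, {
    x <- matrix(rnorm(60 * 15), 60, 15,
                dimnames = list(NULL, paste0("f", 1:15)))
    y <- rbinom(60, 1, 0.5)
    length(rmi_forward_select(x, y, seed = sample.int(1e6, 1))$selected)
  }))
  expect_lte(median(sizes), 2)
})

test_that("ridge logistic behaves at its limits", {
  x <- cbind(f = c(-2, -1.5, -1, 1, 1.5, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- train_logistic(x, y, l2_strength = 0.01)
  expect_equal(saccadom:::auc_mw(predict(fit, x), y), 1)
  # infinite penalty: predictions collapse to the class prior
  strong <- train_logistic(x, c(0, 0, 0, 0, 1, 1), l2_strength = 1e8)
  expect_equal(predict(strong, x), rep(1 / 3, 6), tolerance = 1e-3)
  # duplicating every row leaves fitted probabilities unchanged
  fit2 <- train_logistic(rbind(x, x), c(y, y))
  fit1 <- train_logistic(x, y)
  expect_equal(predict(fit2, x), predict(fit1, x), tolerance = 1e-6)
  expect_error(train_logistic(x, rep(1, 6)), class = "saccadom_domain_error")
})

test_that("the forest is seeded and finds a perfect split", {
  y <- withr::with_seed(14, rbinom(80, 1, 0.5))
  x <- cbind(noise1 = rnorm(80), label_copy = y + rnorm(80, 0, 0.01),
             noise2 = rnorm(80))
  f1 <- train_forest(x, y, n_trees = 100, seed = 5)
  f2 <- train_forest(x, y, n_trees = 100, seed = 5)
  expect_identical(predict(f1, x), predict(f2, x))
  imp <- f1$fit$variable.importance
  expect_identical(names(which.max(imp)), "label_copy")
})

test_that("subset ranking scores behave and favour a label-equal feature", {
  ft <- feature_cohort(12, 12, p = 6, seed = 20)
  ft$f01 <- as.numeric(ft$group == "pd")
  rk_log <- rank_features(ft, "logistic", n_subsets = 8, seed = 2)
  expect_true(all(rk_log$score >= 0 & rk_log$score <= 1))
  expect_identical(rk_log$feature[1], "f01")
  rk_rf <- rank_features(ft, "forest", n_subsets = 5, seed = 3, n_trees = 100)
  expect_equal(sum(rk_rf$score), 1, tolerance = 1e-12)
  expect_identical(rk_rf$feature[1], "f01")
  # subset size contract: 2/3 of n participants (floor)
  expect_identical(floor(51 * 2 / 3), 34)
})

test_that("missing features are imputed with training medians", {
  tr <- matrix(c(1, 2, 3, NA, 10, 20, 30, 40), ncol = 2)
  te <- matrix(c(NA, 5, NA, 1), ncol = 2)
  out <- impute_median(tr, te)
  expect_equal(out$train[4, 1], 2)
  expect_equal(out$apply[1, 1], 2)
  expect_equal(out$apply[1, 2], 25)
  expect_false(anyNA(out$train))
})
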