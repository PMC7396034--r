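test_that("CART recovers a hand-checkable split and pure leaves", {
  x <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(-1L, -1L, 1L, 1L)
  tree <- fit_decision_tree(x, y, max_depth = 3, min_leaf = 1)
  expect_false(tree$root$leaf)
  expect_equal(tree$root$threshold, 1.5)
  expect_identical(predict(tree, x), y)
  pure <- fit_decision_tree(matrix(rnorm(10), 5, 2), rep(1L, 5))
  expect_true(pure$root$leaf)
  expect_identical(pure$root$pred, 1L)
  # leaf ties go to +1
  tied <- fit_decision_tree(matrix(c(1, 1, 1, 1), 4, 1), c(-1L, -1L, 1L, 1L),
                            max_depth = 2, min_leaf = 1)
  expect_identical(tied$root$pred, 1L)
})

test_that("CART agrees with rpart on clean separable data", {
  skip_if_not_installed("rpart")
  ft <- toy_table(n = 200, p = 5, seed = 13)
  y <- ifelse(ft$label == 1L, 1L, -1L)
  ours <- fit_decision_tree(ft$values, y, max_depth = 4, min_leaf = 5)
  df <- data.frame(ft$values, y = factor(y))
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(maxdepth = 4, minbucket = 5,
                                                    cp = 0, xval = 0))
  pr_ours <- predict(ours, ft$values)
  pr_rp <- as.integer(as.character(predict(rp, df, type = "class")))
  expect_gte(mean(pr_ours == pr_rp), 0.98)
  expect_gte(mean(pr_ours == y), 0.98)
})

test_that("bootstrap sampling has the right size, determinism and unique fraction", {
  x <- matrix(rnorm(1000), 1000, 1)
  y <- rep(c(-1L, 1L), 500)
  expect_identical(bootstrap_sample(x[1, , drop = FALSE], y[1], seed = 1)$x,
                   x[1, , drop = FALSE])
  s1 <- bootstrap_sample(x, y, seed = 42)
  s2 <- bootstrap_sample(x, y, seed = 42)
  expect_identical(s1$indices, s2$indices)
  fracs <- vapply(1:30, function(s) {
    length(unique(bootstrap_sample(x, y, seed = s)$indices)) / 1000
  }, numeric(1))
  expect_lt(abs(mean(fracs) - (1 - (1 - 1 / 1000)^1000)), 0.02)
})

test_that("a single-learner ensemble equals its lone tree exactly", {
  ft <- toy_table(n = 80, p = 3, seed = 21)
  y <- ifelse(ft$label == 1L, 1L, -1L)
  ens <- fit_bagging(ft$values, y, n_learners = 1, seed = 5)
  bs <- bootstrap_sample(ft$values, y, seed = ens$seeds[1])
  lone <- fit_decision_tree(bs$x, bs$y)
  expect_identical(as.integer(vote_predict(ens, ft$values)),
                   as.integer(predict(lone, ft$values)))
})

test_that("voting is sign-of-sum with ties to +1 and a tie counter", {
  # hand-built learners via the factory contract
  const_learner <- function(value) {
    structure(list(value = value), class = "const_learner")
  }
  assign("predict.const_learner",
         function(object, x, ...) rep(object$value, nrow(x)),
         envir = globalenv())
  on.exit(rm("predict.const_learner", envir = globalenv()))
  mk <- function(values) {
    structure(list(learners = lapply(values, const_learner),
                   n_learners = length(values), seeds = seq_along(values),
                   in_bag = list(), n_features = 2L),
              class = "bagging_ensemble")
  }
  x <- matrix(0, 3, 2)
  expect_identical(as.integer(vote_predict(mk(c(1, 1, -1)), x)), rep(1L, 3))
  expect_identical(as.integer(vote_predict(mk(c(-1, -1, -1)), x)), rep(-1L, 3))
  two <- vote_predict(mk(c(1, -1)), x)
  expect_identical(as.integer(two), rep(1L, 3))
  expect_identical(attr(two, "ties"), 3L)
})

test_that("ensembles are seed-deterministic and permutation-invariant", {
  ft <- toy_table(n = 100, p = 4, seed = 31)
  y <- ifelse(ft$label == 1L, 1L, -1L)
  e1 <- fit_bagging(ft$values, y, n_learners = 7, seed = 9)
  e2 <- fit_bagging(ft$values, y, n_learners = 7, seed = 9)
  expect_identical(vote_predict(e1, ft$values), vote_predict(e2, ft$values))
  shuffled <- e1
  shuffled$learners <- rev(e1$learners)
  expect_identical(as.integer(vote_predict(shuffled, ft$values)),
                   as.integer(vote_predict(e1, ft$values)))
  expect_error(vote_predict(e1, ft$values[, 1:2]), "width")
})

test_that("bagging reduces variance relative to single trees across refits", {
  ds <- generate_dataset(synthetic_spec(n_samples = 400, imbalance_ratio = 0.4,
                                        missing_rate = 0, outlier_rate = 0,
                                        noise_sd = 2, seed = 55))
  te <- generate_dataset(synthetic_spec(n_samples = 400, imbalance_ratio = 0.4,
                                        missing_rate = 0, outlier_rate = 0,
                                        noise_sd = 2, seed = 56))
  y <- ifelse(ds$table$label == 1L, 1L, -1L)
  yte <- ifelse(te$table$label == 1L, 1L, -1L)
  acc_ens <- acc_tree <- numeric(10)
  for (s in 1:10) {
    ens <- fit_bagging(ds$table$values, y, n_learners = 11, seed = s)
    acc_ens[s] <- mean(vote_predict(ens, te$table$values) == yte)
    bs <- bootstrap_sample(ds$table$values, y, seed = s * 100)
    acc_tree[s] <- mean(predict(fit_decision_tree(bs$x, bs$y),
                                te$table$values) == yte)
  }
  expect_lte(var(acc_ens), var(acc_tree) + 1e-6)
})
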