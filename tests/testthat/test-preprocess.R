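# Cleaning, balancing, importance ranking, feature selection, grid encoding.

test_that("cleaning is the identity on complete tables and logs zero actions", {
  ft <- toy_table()
  out <- clean_table(ft)
  expect_equal(out$values, ft$values)
  expect_identical(out$label, ft$label)
  log <- cleaning_log(out)
  expect_identical(unname(unlist(log)), c(0L, 0L, 0L))
})

test_that("rows beyond the missing-fraction policy and missing labels drop", {
  ft <- toy_table(n = 10, p = 5)
  ft$values[1, 1:3] <- NA             # 60% missing -> dropped at 0.5 policy
  ft <- feature_table(ft$values, ft$label)
  out <- clean_table(ft)
  expect_identical(n_rows(out), 9L)
  expect_identical(cleaning_log(out)$dropped_missing_fraction, 1L)

  ft2 <- toy_table(n = 6)
  lab <- ft2$label
  lab[3] <- NA
  ft2 <- feature_table(ft2$values, lab)
  expect_identical(n_rows(clean_table(ft2)), 5L)
  expect_error(clean_table(feature_table(matrix(NA_real_, 2, 2,
                             dimnames = list(NULL, c("a", "b"))),
                           c(NA, NA))), "every row")
})

test_that("imputation uses the class-conditional median", {
  x <- matrix(c(1, NA, 3,  5, 6, 7), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  ft <- feature_table(x, c(1, 1, 1))                # one class
  out <- clean_table(ft)
  expect_identical(unname(out$values[2, "a"]), 2)   # median of {1, 3}
  # class-conditional: the other class's values do not leak in
  ft2 <- feature_table(rbind(x, c(40, 8), c(60, 9)), c(1, 1, 1, 0, 0))
  out2 <- clean_table(ft2)
  expect_identical(unname(out2$values[2, "a"]), 2)
})

test_that("balancing equalizes counts exactly and keeps originals", {
  ft <- withr::with_seed(4, {
    y <- c(rep(0L, 800), rep(1L, 200))
    feature_table(matrix(rnorm(1000 * 3), 1000, 3,
                         dimnames = list(NULL, c("a", "b", "c"))), y)
  })
  for (method in c("random_oversample", "smote")) {
    out <- balance_classes(ft, method = method, seed = 9)
    expect_identical(sum(out$label == 0L), sum(out$label == 1L))
    expect_identical(sum(out$label == 0L), 800L)
    # originals preserved, in order, at the top
    expect_identical(out$values[1:1000, ], ft$values)
  }
  expect_identical(balance_classes(toy_table(), seed = 1), toy_table())
  expect_error(balance_classes(feature_table(matrix(1:4, 2, 2,
                 dimnames = list(NULL, c("a", "b"))), c(0, 0)), seed = 1),
               "one class")
})

test_that("smote rows lie inside the minority bounding box", {
  ft <- withr::with_seed(5, {
    y <- c(rep(0L, 50), rep(1L, 12))
    feature_table(matrix(rnorm(62 * 4), 62, 4,
                         dimnames = list(NULL, paste0("f", 1:4))), y)
  })
  out <- balance_classes(ft, method = "smote", seed = 2)
  minority <- ft$values[ft$label == 1L, ]
  synth <- out$values[-seq_len(62), ]
  for (j in seq_len(ncol(synth))) {
    expect_true(all(synth[, j] >= min(minority[, j]) - 1e-12))
    expect_true(all(synth[, j] <= max(minority[, j]) + 1e-12))
  }
  tiny <- feature_table(matrix(rnorm(6), 3, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        c(0L, 0L, 1L))
  expect_error(balance_classes(tiny, method = "smote", seed = 1),
               "insufficient")
})

test_that("importance ranking puts the predictive feature first, noise near zero", {
  ft <- toy_table(n = 120, p = 6, seed = 8)
  rk <- rank_feature_importance(ft, seed = 3)
  expect_identical(rk$ordering[1], "v01")
  expect_true(all(rk$scores >= 0))
  # pure-noise features score ~0 within resampling tolerance
  expect_lt(max(rk$scores[-1]), rk$scores[1] / 4)
  # deterministic per seed
  rk2 <- rank_feature_importance(ft, seed = 3)
  expect_identical(rk, rk2)
  expect_error(rank_feature_importance(
    feature_table(ft$values, rep(1L, 120)), seed = 1), "one class")
})

test_that("selection keeps top-k in ranking order and honours keep-lists", {
  ft <- toy_table(n = 60, p = 8)
  rk <- rank_feature_importance(ft, seed = 2)
  sel <- select_features(ft, rk, k = 3)
  expect_identical(colnames(sel$values), rk$ordering[1:3])
  expect_identical(sel$label, ft$label)
  # full retention is a pure reordering
  all_sel <- select_features(ft, rk, k = 8)
  expect_setequal(colnames(all_sel$values), colnames(ft$values))
  # boundary and error cases
  expect_identical(n_features(select_features(ft, rk, k = 1)), 1L)
  expect_error(select_features(ft, rk, k = 9), "exceeds")
  keep <- select_features(ft, rk, k = 3, keep = "v08")
  expect_identical(colnames(keep$values)[1], "v08")
})

test_that("grid encoding is shape-correct, invertible and standardized", {
  ds <- make_fixture("separable_small")
  rk <- rank_feature_importance(ds$table, seed = 6)
  sel <- select_features(ds$table, rk, k = 36)
  g <- encode_grid(sel)
  expect_identical(dim(g), c(400L, 6L, 6L, 1L))
  # cell (r, c) holds the feature at importance rank 6(r-1)+c
  fo <- attr(g, "feature_order")
  sc <- attr(g, "scaler")
  expect_identical(fo, colnames(sel$values))
  z24 <- (sel$values[, fo[24]] - sc$mean[fo[24]]) / sc$sd[fo[24]]
  expect_equal(g[, 4, 6, 1], unname(z24))
  # decode is the exact inverse
  dec <- decode_grid(g)
  expect_equal(dec[, fo[11]],
               unname((sel$values[, fo[11]] - sc$mean[fo[11]]) / sc$sd[fo[11]]))
  # standardized columns
  expect_lt(max(abs(colMeans(dec))), 1e-12)
  expect_error(encode_grid(toy_table()), "36")
})

test_that("zero-variance columns encode as zeros with a warning", {
  ds <- make_fixture("separable_small")
  sel <- select_features(ds$table,
                         rank_feature_importance(ds$table, seed = 6), k = 36)
  sel$values[, 5] <- 7
  sel <- feature_table(sel$values, sel$label)
  expect_warning(g <- encode_grid(sel), "zero-variance")
  expect_true(all(decode_grid(g)[, colnames(sel$values)[5]] == 0))
})
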