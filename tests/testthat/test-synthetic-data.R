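test_that("degenerate rates give a clean, complete table", {
  ds <- generate_dataset(synthetic_spec(n_samples = 100, imbalance_ratio = 0.5,
                                        missing_rate = 0, outlier_rate = 0,
                                        noise_sd = 0, seed = 1))
  expect_identical(n_rows(ds$table), 100L)
  expect_identical(sum(is.na(ds$table$values)), 0L)
  expect_identical(sum(ds$truth$is_outlier), 0L)
  expect_true(all(ds$table$label %in% c(0L, 1L)))
})

test_that("positive-class count matches the imbalance ratio", {
  ds <- generate_dataset(synthetic_spec(n_samples = 2000, imbalance_ratio = 0.2,
                                        seed = 7))
  n_pos <- sum(ds$table$label)
  # central 99% binomial interval, computed from the closed form
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.2)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})

test_that("identical spec and seed give bit-identical output", {
  s <- synthetic_spec(n_samples = 300, seed = 11)
  a <- generate_dataset(s)
  b <- generate_dataset(s)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$table$label, b$table$label)
  expect_identical(a$truth, b$truth)
})

test_that("invalid spec ranges name the offending field", {
  expect_error(synthetic_spec(n_samples = 100, imbalance_ratio = 0.7),
               "imbalance_ratio")
  expect_error(synthetic_spec(n_samples = 100, missing_rate = 0.5),
               "missing_rate")
  expect_error(synthetic_spec(n_samples = 100, n_features_raw = 5,
                              n_informative = 10), "n_informative")
})

test_that("fixture catalogue matches its documented definitions", {
  bench <- make_fixture("imbalanced_benchmark")
  expect_identical(n_rows(bench$table), 4000L)
  expect_identical(n_features(bench$table), 49L)
  expect_identical(length(bench$truth$informative_features), 36L)
  scr <- make_fixture("outlier_screen")
  expect_identical(n_rows(scr$table), 2000L)
  expect_identical(sum(scr$truth$is_outlier), 100L)
  expect_error(make_fixture("nope"), "separable_small")
})

test_that("outlier rows carry a >= 6 SD displacement from their class mean", {
  ds <- make_fixture("outlier_screen")
  cm <- ds$truth$class_feature_means
  cont <- setdiff(colnames(ds$table$values), ds$truth$categorical_features)
  for (i in which(ds$truth$is_outlier)) {
    dev <- abs(ds$table$values[i, cont] -
                 cm[as.character(ds$truth$clean_label[i]), cont])
    expect_gte(max(dev, na.rm = TRUE), 6)
  }
})

test_that("separable fixture is recoverable by a plain logistic fit", {
  ds <- make_fixture("separable_small")
  x <- ds$table$values[, ds$truth$informative_features]
  fit <- suppressWarnings(
    glm.fit(cbind(1, x), ds$table$label, family = binomial()))
  pred <- as.integer(drop(cbind(1, x) %*% fit$coefficients) > 0)
  expect_gte(mean(pred == ds$table$label), 0.99)
})

test_that("truth sidecar and CSV are written together", {
  ds <- generate_dataset(synthetic_spec(n_samples = 50, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, csv, js)
  expect_identical(n_rows(read_feature_table(csv)), 50L)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(sort(truth$informative_features),
                   sort(ds$truth$informative_features))
})
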