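test_that("the default architecture traces exactly as specified", {
  tr <- shape_trace(default_network_spec())
  expect_equal(tr, list(c(6L, 6L, 1L), c(6L, 6L, 32L), c(5L, 5L, 32L),
                        c(5L, 5L, 64L), c(4L, 4L, 64L), 128L, 128L, 2L))
  expect_error(network_spec(list(layer_input(2, 2, 1),
                                 layer_pool(c(3, 3)),
                                 layer_output(2))), "window")
})

test_that("analytic gradients match finite differences on the miniature net", {
  for (seed in 1:2) {
    gc <- gradient_check(seed = seed)
    expect_lt(gc$max_relative_error, 1e-5)
  }
})

test_that("compiled epoch step equals the R layer-by-layer path exactly", {
  spec <- cnnbag:::miniature_network_spec()
  withr::with_seed(77, {
    x <- array(rnorm(16 * 8), dim = c(1, 4, 4, 8))
  })
  y <- rep(c(0L, 1L), 4)
  cfg <- train_config(max_iterations = 1, batch_size = 4, seed = 9,
                      learning_rate = 1e-3)
  net <- train_network(spec, x, y, cfg)
  # replay the same minibatch sequence through the exported layer ops
  params <- withr::with_seed(9, cnnbag:::init_network_params(spec))
  perm <- withr::with_seed(9, {
    cnnbag:::init_network_params(spec)
    sample.int(8)
  })
  xm <- x; dim(xm) <- c(16, 8)
  yoh <- unname(rbind(1 - y, y))
  for (b0 in seq(1, 8, by = 4)) {
    idx <- perm[b0:(b0 + 3)]
    xb <- xm[, idx]; dim(xb) <- c(1, 4, 4, 4)
    fwd <- cnnbag:::forward_network(spec, params, xb)
    grads <- cnnbag:::backward_network(spec, params, fwd, yoh[, idx])
    params <- update_params(params, grads, 1e-3)
  }
  for (l in seq_along(params)) {
    if (is.null(params[[l]])) next
    expect_equal(net$params[[l]]$w, params[[l]]$w, tolerance = 1e-14)
    expect_equal(net$params[[l]]$b, params[[l]]$b, tolerance = 1e-14)
  }
})

test_that("updates use batch-summed gradients, alpha scaling and zero fixpoint", {
  spec <- cnnbag:::miniature_network_spec()
  params <- init_network_params(spec, seed = 3)
  withr::with_seed(5, {
    x <- array(rnorm(16 * 2), dim = c(1, 4, 4, 2))
  })
  y <- rbind(c(1, 0), c(0, 1))
  fwd <- cnnbag:::forward_network(spec, params, x)
  grads <- cnnbag:::backward_network(spec, params, fwd, y)
  # per-sample accumulation oracle
  g1 <- cnnbag:::backward_network(spec, params,
          cnnbag:::forward_network(spec, params,
            array(x[, , , 1], c(1, 4, 4, 1))), y[, 1, drop = FALSE])
  g2 <- cnnbag:::backward_network(spec, params,
          cnnbag:::forward_network(spec, params,
            array(x[, , , 2], c(1, 4, 4, 1))), y[, 2, drop = FALSE])
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    expect_equal(grads[[l]]$d_w, g1[[l]]$d_w + g2[[l]]$d_w, tolerance = 1e-12)
  }
  upd <- update_params(params, grads, 0.1)
  expect_equal(upd[[2]]$w, params[[2]]$w - 0.1 * grads[[2]]$d_w)
  expect_identical(update_params(params, grads, 0), params)
  bad <- grads
  bad[[2]]$d_w[1] <- NaN
  expect_error(update_params(params, bad, 0.1), "divergence")
})

test_that("training with alpha = 0 leaves parameters bit-identical", {
  spec <- cnnbag:::miniature_network_spec()
  withr::with_seed(6, {
    x <- array(rnorm(16 * 10), dim = c(1, 4, 4, 10))
  })
  y <- rep(c(0L, 1L), 5)
  net <- train_network(spec, x, y,
                       train_config(learning_rate = 0, max_iterations = 3,
                                    batch_size = 5, seed = 2))
  expect_identical(net$params, init_network_params(spec, seed = 2))
})

test_that("an infinite tolerance stops after exactly one iteration", {
  spec <- cnnbag:::miniature_network_spec()
  withr::with_seed(6, {
    x <- array(rnorm(16 * 10), dim = c(1, 4, 4, 10))
  })
  y <- rep(c(0L, 1L), 5)
  net <- train_network(spec, x, y,
                       train_config(tolerance = Inf, max_iterations = 50,
                                    batch_size = 5, seed = 2))
  expect_identical(nrow(net$history), 1L)
})

test_that("a non-finite loss aborts naming the iteration", {
  spec <- cnnbag:::miniature_network_spec()
  withr::with_seed(8, {
    x <- array(rnorm(16 * 12), dim = c(1, 4, 4, 12))
  })
  x[1, 1, 1, 1] <- Inf                  # poisons softmax via Inf - Inf
  y <- rep(c(0L, 1L), 6)
  expect_error(train_network(spec, x, y,
                 train_config(max_iterations = 20, batch_size = 12, seed = 4)),
               "divergence.*iteration 1")
})

test_that("loss is non-increasing early in training at the default rate", {
  ds <- make_fixture("separable_small")
  rk <- rank_feature_importance(ds$table, seed = 1)
  g <- encode_grid(select_features(ds$table, rk, 36))
  net <- train_network(default_network_spec(), g, ds$table$label,
                       train_config(max_iterations = 10, seed = 3))
  expect_true(all(diff(net$history$loss) <= 1e-8))
})

test_that("feature extraction taps the last hidden dense layer", {
  ds <- make_fixture("separable_small")
  rk <- rank_feature_importance(ds$table, seed = 1)
  g <- encode_grid(select_features(ds$table, rk, 36))
  net <- train_network(default_network_spec(), g, ds$table$label,
                       train_config(max_iterations = 3, seed = 3))
  f <- extract_features(net, g)
  expect_identical(dim(f), c(400L, 128L))
  expect_true(all(f >= 0))                        # ReLU range
  # identical inputs give identical features
  g2 <- g[c(1, 1), , , , drop = FALSE]
  attributes(g2) <- c(attributes(g2),
                      attributes(g)[c("feature_order", "scaler", "class")])
  f2 <- extract_features(net, g2)
  expect_identical(f2[1, ], f2[2, ])
})

test_that("softmax predictions are normalized with ties broken to class 0", {
  ds <- make_fixture("separable_small")
  rk <- rank_feature_importance(ds$table, seed = 1)
  g <- encode_grid(select_features(ds$table, rk, 36))
  net <- train_network(default_network_spec(), g, ds$table$label,
                       train_config(max_iterations = 3, seed = 3))
  p <- predict_softmax(net, g)
  expect_equal(rowSums(p$probabilities), rep(1, 400), tolerance = 1e-12)
  expect_true(all(p$labels %in% c(0L, 1L)))
  # tie rule: equal probabilities -> class 0 (first index wins)
  expect_identical(as.integer(apply(matrix(c(0.5, 0.5), 2, 1), 2,
                                    which.max) - 1L), 0L)
})
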