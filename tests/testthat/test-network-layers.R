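# Layer primitives against brute-force oracles and hand-worked cases.
# Activations are channel-first: (c, h, w, n).

test_that("convolution matches the brute-force sliding-window oracle", {
  cases <- list(list(ci = 1, h = 3, w = 3, kh = 2, kw = 2, co = 1, pad = "valid"),
                list(ci = 2, h = 5, w = 4, kh = 3, kw = 3, co = 3, pad = "same"),
                list(ci = 3, h = 6, w = 6, kh = 3, kw = 3, co = 2, pad = "same"),
                list(ci = 2, h = 5, w = 5, kh = 2, kw = 3, co = 2, pad = "valid"))
  for (cs in cases) {
    withr::with_seed(cs$h * 10 + cs$co, {
      x <- array(rnorm(cs$ci * cs$h * cs$w), c(cs$ci, cs$h, cs$w))
      w <- array(rnorm(cs$kh * cs$kw * cs$ci * cs$co),
                 c(cs$kh, cs$kw, cs$ci, cs$co))
      b <- rnorm(cs$co)
      out <- conv_forward(x, w, b, stride = 1, padding = cs$pad)
      z1 <- out$z
      dim(z1) <- dim(z1)[1:3]
      expect_equal(z1, conv_brute(x, w, b, 1, cs$pad), tolerance = 1e-12)
      expect_equal(out$a, pmax(out$z, 0))
    })
  }
})

test_that("hand case: 3x3 input, 2x2 ones kernel, valid = window sums", {
  x <- array(0, c(1, 3, 3))
  x[1, , ] <- matrix(1:9, 3, 3)
  out <- conv_forward(x, array(1, c(2, 2, 1, 1)), 0, padding = "valid")
  expect_equal(out$a[1, , , 1], matrix(c(12, 16, 24, 28), 2, 2))
})

test_that("same padding preserves the 6x6 spatial size at 32 channels", {
  x <- array(rnorm(36), c(1, 6, 6))
  w <- array(rnorm(3 * 3 * 32), c(3, 3, 1, 32))
  out <- conv_forward(x, w, numeric(32), padding = "same")
  expect_identical(dim(out$a), c(32L, 6L, 6L, 1L))
})

test_that("all-zero kernels with bias beta output ReLU(beta) everywhere", {
  x <- array(rnorm(2 * 16), c(2, 4, 4))
  b <- c(1.5, -2)
  out <- conv_forward(x, array(0, c(3, 3, 2, 2)), b, padding = "same")
  expect_true(all(out$a[1, , , 1] == 1.5))
  expect_true(all(out$a[2, , , 1] == 0))
})

test_that("conv backward returns zero gradients for zero error and correct db", {
  withr::with_seed(1, {
    x <- array(rnorm(2 * 25 * 3), c(2, 5, 5, 3))
    w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    fwd <- conv_forward(x, w, rnorm(4), padding = "same")
    zero <- array(0, dim(fwd$a))
    bwd <- conv_backward(zero, fwd, w)
    expect_true(all(bwd$d_w == 0) && all(bwd$d_b == 0) &&
                  all(bwd$d_input == 0))
    # db is the error summed over spatial positions and samples per channel
    d_act <- array(rnorm(length(fwd$a)), dim(fwd$a))
    bwd2 <- conv_backward(d_act, fwd, w)
    dz <- d_act * (fwd$z > 0)
    expect_equal(bwd2$d_b, apply(dz, 1, sum), tolerance = 1e-12)
  })
})

test_that("max pooling matches the brute-force oracle and Table-1 shapes", {
  withr::with_seed(2, {
    x <- array(rnorm(32 * 36), c(32, 6, 6))
    out <- max_pool_forward(x, c(2, 2), stride = 1)
    expect_identical(dim(out$a), c(32L, 5L, 5L, 1L))
    expect_equal(out$a[, , , 1], pool_brute(x, c(2, 2), 1), tolerance = 1e-15)
    # non-overlapping variant
    out2 <- max_pool_forward(x, c(2, 2), stride = 2)
    expect_equal(out2$a[, , , 1], pool_brute(x, c(2, 2), 2), tolerance = 1e-15)
  })
  expect_equal(max_pool_forward(array(c(1, 3, 2, 4), c(1, 2, 2)))$a[1, 1, 1, 1], 4)
  const <- max_pool_forward(array(7, c(1, 3, 3)))
  expect_true(all(const$a == 7))
  expect_error(max_pool_forward(array(1, c(1, 1, 1))), "window")
})

test_that("pool backward routes errors to argmax and conserves error mass", {
  withr::with_seed(3, {
    x <- array(rnorm(2 * 5 * 5), c(2, 5, 5, 1))
    fwd <- max_pool_forward(x, c(2, 2), stride = 1)
    d_out <- array(rnorm(length(fwd$a)), dim(fwd$a))
    d_in <- max_pool_backward(d_out, fwd$cache)
    expect_equal(sum(d_in), sum(d_out), tolerance = 1e-12)
    # non-overlapping windows: each max receives exactly its window's error
    fwd2 <- max_pool_forward(x, c(2, 2), stride = 2)
    d2 <- array(rnorm(length(fwd2$a)), dim(fwd2$a))
    din2 <- max_pool_backward(d2, fwd2$cache)
    expect_equal(sum(din2 != 0), sum(d2 != 0))
    expect_equal(sort(as.vector(din2)[as.vector(din2) != 0]),
                 sort(as.vector(d2)[d2 != 0]))
  })
})

test_that("a single global maximum collects every overlapping window's error", {
  x <- array(0, c(1, 3, 3))
  x[1, 2, 2] <- 10                      # centre cell wins all four 2x2 windows
  fwd <- max_pool_forward(x, c(2, 2), stride = 1)
  d_out <- array(c(1, 2, 3, 4), c(1, 2, 2, 1))
  d_in <- max_pool_backward(d_out, fwd$cache)
  expect_equal(d_in[1, 2, 2, 1], 10)
  expect_equal(sum(d_in), 10)
})

test_that("dense forward computes z = W a + b and stable softmax", {
  a_prev <- matrix(c(0.3, -1, 2), 3, 1)
  idm <- diag(3)
  out <- dense_forward(a_prev, idm, numeric(3), activation = "linear")
  expect_equal(out$z, a_prev)
  sm <- dense_forward(matrix(0, 2, 1), diag(2), c(0, 0), "softmax")
  expect_equal(sm$a, matrix(c(0.5, 0.5), 2, 1))
  sm2 <- dense_forward(matrix(c(log(1), log(3)), 2, 1), diag(2), c(0, 0),
                       "softmax")
  expect_equal(sm2$a, matrix(c(0.25, 0.75), 2, 1))
  # max-subtraction keeps huge logits finite
  sm3 <- dense_forward(matrix(c(1000, 999), 2, 1), diag(2), c(0, 0), "softmax")
  expect_true(all(is.finite(sm3$a)))
  expect_error(dense_forward(matrix(1, 3, 1), matrix(1, 2, 2), c(0, 0)),
               "dense layer")
})

test_that("dense backward propagates zeros and kills dead ReLU units", {
  w_next <- matrix(rnorm(6), 2, 3)
  z <- matrix(c(-1, -2, -3), 3, 1)
  expect_true(all(dense_backprop_delta(matrix(0, 2, 1), w_next, z) == 0))
  d <- dense_backprop_delta(matrix(c(1, 1), 2, 1), w_next, z)
  expect_true(all(d == 0))              # all-negative pre-activations
  # finite-difference check of a 2-unit toy layer
  withr::with_seed(4, {
    w1 <- matrix(rnorm(4), 2, 2); b1 <- rnorm(2)
    w2 <- matrix(rnorm(4), 2, 2); b2 <- rnorm(2)
    x <- matrix(rnorm(2), 2, 1); y <- c(0, 1)
    loss <- function(w1v) {
      h <- dense_forward(x, matrix(w1v, 2, 2), b1, "relu")
      p <- dense_forward(h$a, w2, b2, "softmax")
      -log(max(sum(p$a[, 1] * y), 1e-12))
    }
    h <- dense_forward(x, w1, b1, "relu")
    p <- dense_forward(h$a, w2, b2, "softmax")
    delta_out <- p$a - matrix(y, 2, 1)
    delta_h <- dense_backprop_delta(delta_out, w2, h$z)
    analytic <- dense_grads(delta_h, x)$d_w
    numeric_g <- matrix(0, 2, 2)
    for (i in 1:4) {
      hi <- lo <- as.vector(w1); hi[i] <- hi[i] + 1e-6; lo[i] <- lo[i] - 1e-6
      numeric_g[i] <- (loss(hi) - loss(lo)) / 2e-6
    }
    expect_equal(analytic, numeric_g, tolerance = 1e-5)
  })
})
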