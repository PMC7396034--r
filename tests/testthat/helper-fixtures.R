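# Small in-code fixtures shared across tests.

# Tiny two-class table: n rows, p features, first feature carries the label
# signal perfectly, the rest are noise.
toy_table <- function(n = 40, p = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
    x[, 1] <- ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.1)
    feature_table(x, y)
  })
}

# Brute-force sliding-window cross-correlation oracle (channel-first
# input (c, h, w), kernel (kh, kw, c_in, c_out)); independent of the
# im2col implementation it checks.
conv_brute <- function(input, w, b, stride = 1, padding = "same") {
  d <- dim(input)
  ci <- d[1]; h <- d[2]; wd <- d[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; co <- dim(w)[4]
  if (padding == "same") {
    oh <- ceiling(h / stride); ow <- ceiling(wd / stride)
    ph <- max(0, (oh - 1) * stride + kh - h)
    pw <- max(0, (ow - 1) * stride + kw - wd)
    pt <- ph %/% 2; pl <- pw %/% 2
    padded <- array(0, c(ci, h + ph, wd + pw))
    padded[, pt + seq_len(h), pl + seq_len(wd)] <- input
  } else {
    oh <- (h - kh) %/% stride + 1; ow <- (wd - kw) %/% stride + 1
    padded <- input
  }
  z <- array(0, c(co, oh, ow))
  for (o in seq_len(co)) {
    for (i in seq_len(oh)) {
      for (j in seq_len(ow)) {
        acc <- b[o]
        for (c in seq_len(ci)) {
          for (a in seq_len(kh)) {
            for (bb in seq_len(kw)) {
              acc <- acc + padded[c, (i - 1) * stride + a, (j - 1) * stride + bb] *
                w[a, bb, c, o]
            }
          }
        }
        z[o, i, j] <- acc
      }
    }
  }
  z
}

# Brute-force max pooling oracle on a channel-first (c, h, w) array.
pool_brute <- function(input, window = c(2, 2), stride = 1) {
  d <- dim(input)
  ci <- d[1]; h <- d[2]; wd <- d[3]
  oh <- (h - window[1]) %/% stride + 1
  ow <- (wd - window[2]) %/% stride + 1
  out <- array(0, c(ci, oh, ow))
  for (c in seq_len(ci)) {
    for (i in seq_len(oh)) {
      for (j in seq_len(ow)) {
        out[c, i, j] <- max(input[c, (i - 1) * stride + seq_len(window[1]),
                                  (j - 1) * stride + seq_len(window[2])])
      }
    }
  }
  out
}
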