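# Layer primitives. Activations travel channel-first, as (C, H, W, n)
# arrays — the natural output order of the im2col matrix product, so no
# permutation is ever needed between layers. A (C, H, W, n) array is
# memory-identical to a (C*H*W) x n matrix, so "flattening" between the
# last pooling layer and the first dense layer is a free dim change.

# Geometry of a convolution on a channel-first block: output size, padding
# split, linear indices of the original cells inside the padded (c, hp, wp)
# block, and the im2col index vector. Patch elements are ordered kh-fastest,
# then kw, then channel (matching matrix(w, k) for a (kh, kw, c_in, c_out)
# kernel array); output positions are ordered out_h-fastest, then out_w.
# Memoised: geometry depends only on shapes, not data.
.geometry_cache <- new.env(parent = emptyenv())

conv_geometry <- function(h, w, c, kh, kw, stride, padding) {
  key <- paste(h, w, c, kh, kw, stride, padding, sep = "_")
  hit <- .geometry_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (padding == "same") {
    out_h <- as.integer(ceiling(h / stride))
    out_w <- as.integer(ceiling(w / stride))
    pad_h <- max(0L, (out_h - 1L) * stride + kh - h)
    pad_w <- max(0L, (out_w - 1L) * stride + kw - w)
  } else {
    if (h < kh || w < kw) {
      stop_config("input spatial dims (", h, "x", w,
                  ") smaller than kernel (", kh, "x", kw, ")")
    }
    out_h <- (h - kh) %/% stride + 1L
    out_w <- (w - kw) %/% stride + 1L
    pad_h <- pad_w <- 0L
  }
  pt <- pad_h %/% 2L; pb <- pad_h - pt
  pl <- pad_w %/% 2L; pr <- pad_w - pl
  hp <- h + pt + pb
  wp <- w + pl + pr
  # channel-first linear index in the padded block: c + (h-1)*C + (w-1)*C*hp
  lin <- function(ci, hi, wi) ci + (hi - 1L) * c + (wi - 1L) * c * hp
  inside <- as.vector(outer(seq_len(c),
                            outer((pt + seq_len(h) - 1L) * c,
                                  (pl + seq_len(w) - 1L) * c * hp, "+"), "+"))
  # patch offsets ordered (kh fastest, kw, channel), values channel-first
  offs <- as.vector(outer(outer((seq_len(kh) - 1L) * c,
                                (seq_len(kw) - 1L) * c * hp, "+"),
                          seq_len(c) - 1L, "+"))
  starts <- as.vector(outer(lin(1L, (seq_len(out_h) - 1L) * stride + 1L, 1L),
                            ((seq_len(out_w) - 1L) * stride) * c * hp, "+"))
  idx <- as.vector(outer(offs, starts, "+"))
  g <- list(out_h = out_h, out_w = out_w, hp = hp, wp = wp,
            k = kh * kw * c, inside = inside, idx = idx,
            uidx = sort(unique(idx)))
  .geometry_cache[[key]] <- g
  g
}

as_batch_array <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Convolution forward pass
#'
#' Cross-correlation of a batch of input volumes with a bank of kernels,
#' one bias per output channel, followed by elementwise ReLU. Implemented
#' by im2col patch extraction and a single matrix product. `"same"`
#' padding at stride 1 preserves the spatial size.
#'
#' Activations use the package's channel-first layout: an input volume of
#' height h, width w and c channels is a `(c, h, w)` array, batches add a
#' trailing sample dimension `(c, h, w, n)`.
#'
#' @param input Array `(c_in, h, w, n)` (or `(c_in, h, w)` for one sample).
#' @param w Kernel array `(kh, kw, c_in, c_out)`.
#' @param b Bias vector, length `c_out`.
#' @param stride Step of the sliding window (default 1).
#' @param padding `"same"` or `"valid"`.
#' @return List with `z` (pre-activation, `(c_out, out_h, out_w, n)`),
#'   `a = ReLU(z)` and `cache` (im2col matrix and geometry for the
#'   backward pass).
#' @export
conv_forward <- function(input, w, b, stride = 1L,
                         padding = c("same", "valid")) {
  padding <- match.arg(padding)
  input <- as_batch_array(input)
  d <- dim(input)                       # (c_in, h, w, n)
  dw <- dim(w)
  if (length(dw) != 4L || dw[3L] != d[1L]) {
    stop_config("conv layer: kernel channels (", dw[3L],
                ") do not match input channels (", d[1L], ")")
  }
  g <- conv_geometry(d[2L], d[3L], d[1L], dw[1L], dw[2L], stride, padding)
  n <- d[4L]
  xm <- input
  dim(xm) <- c(prod(d[1:3]), n)
  wmat <- matrix(w, nrow = g$k)
  res <- conv_forward_cpp(xm, g$inside, g$idx, g$hp * g$wp * d[1L],
                          wmat, as.numeric(b))
  z <- res$z                            # c_out x (out_h*out_w*n)
  a <- res$a
  dim(z) <- c(dw[4L], g$out_h, g$out_w, n)
  dim(a) <- dim(z)
  list(z = z, a = a, cache = list(geom = g, x_in = xm, in_dim = d))
}

#' Convolution backward pass
#'
#' Given the gradient with respect to this layer's activation, applies the
#' ReLU derivative and returns the kernel gradient (`dW`, the correlation
#' of the error with the cached input patches), the bias gradient (`db`,
#' the error summed over spatial positions per channel) and the gradient
#' with respect to the layer input. The input gradient is computed by
#' scattering `t(W) \%*\% delta` back through the im2col map — algebraically
#' identical to the classical full convolution of the error with the
#' 180-degree-rotated kernels.
#'
#' @param d_activation Gradient wrt the layer activation,
#'   `(c_out, out_h, out_w, n)`.
#' @param forward The list returned by [conv_forward()] (for `z` and cache).
#' @param w The kernel array used in the forward pass.
#' @return List with `d_input`, `d_w`, `d_b` (shapes mirror the inputs).
#' @export
conv_backward <- function(d_activation, forward, w) {
  g <- forward$cache$geom
  d <- forward$cache$in_dim
  dw_dim <- dim(w)
  n <- d[4L]
  m <- g$out_h * g$out_w
  d_act <- d_activation
  dim(d_act) <- c(dw_dim[4L], m * n)
  z <- forward$z
  dim(z) <- c(dw_dim[4L], m * n)
  wmat <- matrix(w, nrow = g$k)
  res <- conv_backward_cpp(d_act, z, forward$cache$x_in, wmat,
                           g$inside, g$idx, g$hp * g$wp * d[1L])
  d_input <- res$d_input
  dim(d_input) <- d
  list(d_input = d_input,
       d_w = array(t(res$d_wmat), dim = dw_dim),
       d_b = as.numeric(res$d_b))
}

pool_geometry <- function(h, w, c, wh, ww, stride) {
  key <- paste("pool", h, w, c, wh, ww, stride, sep = "_")
  hit <- .geometry_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (h < wh || w < ww) {
    stop_config("pooling window (", wh, "x", ww,
                ") larger than input (", h, "x", w, ")")
  }
  out_h <- (h - wh) %/% stride + 1L
  out_w <- (w - ww) %/% stride + 1L
  # window offsets in row-major scan order (across a row first), so the
  # strict '>' update keeps the first maximum of the scan on ties; output
  # cells ordered channel-first to match the activation layout
  offsets <- list()
  for (i in seq_len(wh)) {
    for (j in seq_len(ww)) {
      offsets[[length(offsets) + 1L]] <- as.vector(
        outer(seq_len(c),
              outer(((seq_len(out_h) - 1L) * stride + i - 1L) * c,
                    ((seq_len(out_w) - 1L) * stride + j - 1L) * c * h,
                    "+"), "+"))
    }
  }
  g <- list(out_h = out_h, out_w = out_w,
            offset_matrix = matrix(unlist(offsets), ncol = length(offsets)))
  .geometry_cache[[key]] <- g
  g
}

#' Max-pooling forward pass
#'
#' Valid max pooling: output size is `input - window + 1` per axis at
#' stride 1 (windows overlap). The linear index of each window's maximum
#' is recorded for the backward pass; ties go to the first position in a
#' row-major scan of the window.
#'
#' @param input Array `(c, h, w, n)` (or one sample `(c, h, w)`),
#'   channel-first.
#' @param window Pooling window `c(wh, ww)` (default 2x2).
#' @param stride Window step (default 1).
#' @return List with `a` (pooled activations `(c, out_h, out_w, n)`) and
#'   `cache` holding `argmax` (per output cell and sample, the linear index
#'   of the winning input cell within a sample's `(c, h, w)` block) plus
#'   dimensions.
#' @export
max_pool_forward <- function(input, window = c(2L, 2L), stride = 1L) {
  input <- as_batch_array(input)
  d <- dim(input)                       # (c, h, w, n)
  g <- pool_geometry(d[2L], d[3L], d[1L], window[1L], window[2L], stride)
  n <- d[4L]
  xm <- input
  dim(xm) <- c(prod(d[1:3]), n)
  m <- g$out_h * g$out_w * d[1L]
  om <- g$offset_matrix                 # m x (wh*ww)
  res <- pool_forward_cpp(xm, om)
  a <- res$a
  winner <- res$winner
  argmax <- matrix(om[as.vector(seq_len(m) + (winner - 1L) * m)], m, n)
  dim(a) <- c(d[1L], g$out_h, g$out_w, n)
  list(a = a, cache = list(argmax = argmax, winner = winner,
                           offset_matrix = om, in_dim = d,
                           out_dim = c(d[1L], g$out_h, g$out_w, n)))
}

#' Max-pooling backward pass
#'
#' Routes each incoming error value to the recorded argmax position of its
#' window; overlapping windows accumulate additively, so the total error
#' mass is conserved.
#'
#' @param d_out Gradient wrt the pooled output, `(c, out_h, out_w, n)`.
#' @param cache The cache from the matching [max_pool_forward()] call.
#' @return Gradient wrt the pooling input, `(c, h, w, n)`.
#' @export
max_pool_backward <- function(d_out, cache) {
  d <- cache$in_dim
  n <- d[4L]
  m <- prod(cache$out_dim[1:3])
  if (length(d_out) != m * n) {
    stop_config("stale pooling cache: gradient size does not match")
  }
  dim(d_out) <- c(m, n)
  d_input <- pool_backward_cpp(d_out, cache$winner, cache$offset_matrix,
                               prod(d[1:3]))
  dim(d_input) <- d
  d_input
}

#' Dense (fully connected) forward pass
#'
#' `z = W a_prev + b`, followed by ReLU (hidden layers), a numerically
#' stable max-subtracted softmax (output layer), or no nonlinearity.
#'
#' @param a_prev Activations `(inputs, n)`; higher-dimensional arrays are
#'   flattened (the conv/pool-to-dense transition).
#' @param w Weight matrix `(units, inputs)`.
#' @param b Bias vector, length `units`.
#' @param activation `"relu"`, `"softmax"` or `"linear"`.
#' @return List with `z` and `a`, both `(units, n)`.
#' @export
dense_forward <- function(a_prev, w, b,
                          activation = c("relu", "softmax", "linear")) {
  activation <- match.arg(activation)
  if (!is.null(dim(a_prev)) && length(dim(a_prev)) > 2L) {
    d <- dim(a_prev)
    dim(a_prev) <- c(prod(d[-length(d)]), d[length(d)])
  }
  if (is.null(dim(a_prev))) a_prev <- matrix(a_prev, ncol = 1L)
  if (ncol(w) != nrow(a_prev)) {
    stop_config("dense layer: weight columns (", ncol(w),
                ") do not match input size (", nrow(a_prev), ")")
  }
  z <- w %*% a_prev + b
  a <- switch(activation,
    relu = { a <- z; a[a < 0] <- 0; a },
    linear = z,
    softmax = {
      e <- exp(sweep(z, 2L, apply(z, 2L, max), "-"))
      sweep(e, 2L, colSums(e), "/")
    })
  list(z = z, a = a)
}

#' Backpropagate the error through a dense layer
#'
#' `delta_l = t(W_next) \%*\% delta_next * sigma'(z_l)`, with the ReLU
#' indicator as `sigma'`.
#'
#' @param delta_next Error term of the following layer, `(units_next, n)`.
#' @param w_next Weights of the following layer.
#' @param z Cached pre-activation of this layer.
#' @param activation `"relu"` or `"linear"`.
#' @return Error term `delta_l`, shaped like `z`.
#' @export
dense_backprop_delta <- function(delta_next, w_next, z,
                                 activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (is.null(z)) stop_config("missing forward cache for dense backward")
  delta <- crossprod(w_next, delta_next)
  if (activation == "relu") delta <- delta * (z > 0)
  delta
}

#' Parameter gradients of a dense layer
#'
#' Batch-summed gradients: `dW = delta \%*\% t(a_prev)`, `db = rowSums(delta)`.
#'
#' @param delta Error term of the layer, `(units, n)`.
#' @param a_prev Activations fed into the layer, `(inputs, n)`.
#' @return List with `d_w` and `d_b`.
#' @export
dense_grads <- function(delta, a_prev) {
  list(d_w = tcrossprod(delta, a_prev), d_b = rowSums(delta))
}
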