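#' Training configuration for the network
#'
#' @param learning_rate Step size `alpha` applied to batch-summed gradients
#'   (default 1e-4; gradients are summed, not averaged, over the batch, so
#'   sensible values are smaller than mean-gradient conventions by roughly
#'   the batch size).
#' @param max_iterations Iteration cap T; one iteration is a full pass over
#'   the training data in minibatches (default 1000).
#' @param tolerance Stopping threshold epsilon on the Frobenius norm of the
#'   concatenated parameter change over an iteration (default 1e-6, small
#'   enough that the iteration cap usually binds).
#' @param batch_size Minibatch size m (default 256, capped at n).
#' @param seed Integer seed covering initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, max_iterations = 1000L,
                         tolerance = 1e-6, batch_size = 256L, seed = 1L) {
  check_scalar(learning_rate, "learning_rate", min = 0)
  check_scalar(max_iterations, "max_iterations", min = 1, integer = TRUE)
  check_scalar(tolerance, "tolerance", min = 0, inclusive_min = FALSE,
               allow_inf = TRUE)
  check_scalar(batch_size, "batch_size", min = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# One-hot (2 x n) encoding of {0,1} labels; column order = classes (0, 1).
labels_to_onehot <- function(labels) {
  if (is.matrix(labels)) {
    if (ncol(labels) != 2L) stop_config("one-hot labels must have 2 columns")
    return(t(labels))
  }
  if (!all(labels %in% c(0, 1))) stop_config("labels must be in {0, 1}")
  unname(rbind(1 - labels, labels))
}

# Per-layer geometry plan for the compiled whole-epoch training step
# (input layer excluded; indices mirror spec$layers[-1]).
build_epoch_plan <- function(spec) {
  lapply(seq_along(spec$layers)[-1L], function(l) {
    lay <- spec$layers[[l]]
    prev <- spec$dims[[l - 1L]]
    if (lay$type == "conv") {
      g <- conv_geometry(prev[1L], prev[2L], prev[3L], lay$kernel[1L],
                         lay$kernel[2L], lay$stride, lay$padding)
      list(type = 1L, inside = g$inside, idx = g$idx,
           p_len = g$hp * g$wp * prev[3L], k = g$k)
    } else if (lay$type == "pool") {
      g <- pool_geometry(prev[1L], prev[2L], prev[3L], lay$window[1L],
                         lay$window[2L], lay$stride)
      list(type = 2L, off = g$offset_matrix, f_in = prod(prev))
    } else if (lay$type == "dense") {
      list(type = 3L)
    } else {
      list(type = 4L)
    }
  })
}

# Forward through all layers; returns activations/caches per layer plus the
# softmax probabilities (2 x n). `upto = "features"` stops at the last
# hidden dense layer (the 128-unit feature tap).
forward_network <- function(spec, params, x, upto = c("output", "features")) {
  upto <- match.arg(upto)
  layers <- spec$layers
  caches <- vector("list", length(layers))
  a <- x
  dense_idx <- which(vapply(layers, function(l) l$type == "dense", logical(1)))
  if (upto == "features" && !length(dense_idx)) {
    stop_config("network has no hidden dense layer to tap features from")
  }
  last_dense <- if (length(dense_idx)) max(dense_idx) else -1L
  for (l in seq_along(layers)[-1L]) {
    lay <- layers[[l]]
    if (lay$type == "conv") {
      fwd <- conv_forward(a, params[[l]]$w, params[[l]]$b,
                          stride = lay$stride, padding = lay$padding)
      caches[[l]] <- list(fwd = fwd, a_prev = a)
      a <- fwd$a
    } else if (lay$type == "pool") {
      fwd <- max_pool_forward(a, window = lay$window, stride = lay$stride)
      caches[[l]] <- list(cache = fwd$cache)
      a <- fwd$a
    } else {
      act <- if (lay$type == "output") "softmax" else "relu"
      a_prev <- a
      if (!is.null(dim(a_prev)) && length(dim(a_prev)) > 2L) {
        d <- dim(a_prev)
        dim(a_prev) <- c(prod(d[-length(d)]), d[length(d)])
      }
      fwd <- dense_forward(a_prev, params[[l]]$w, params[[l]]$b,
                           activation = act)
      caches[[l]] <- list(z = fwd$z, a_prev = a_prev)
      a <- fwd$a
      if (upto == "features" && l == last_dense) {
        return(list(features = a, caches = caches))
      }
    }
  }
  list(probs = a, caches = caches)
}

# Batch-summed cross-entropy loss of softmax probabilities against one-hot y.
cross_entropy <- function(probs, y) {
  p_true <- pmax(colSums(probs * y), 1e-12)
  -sum(log(p_true))
}

# Backward through all layers from delta_L = probs - y (softmax +
# cross-entropy). Returns batch-summed gradients mirroring `params`.
backward_network <- function(spec, params, fwd, y) {
  layers <- spec$layers
  caches <- fwd$caches
  grads <- vector("list", length(layers))
  nl <- length(layers)
  delta <- fwd$probs - y
  d_act <- NULL
  for (l in rev(seq_along(layers)[-1L])) {
    lay <- layers[[l]]
    if (lay$type %in% c("dense", "output")) {
      if (lay$type == "dense") {
        delta <- d_act * (caches[[l]]$z > 0)
      }
      g <- dense_grads(delta, caches[[l]]$a_prev)
      grads[[l]] <- list(d_w = g$d_w, d_b = g$d_b)
      d_act <- crossprod(params[[l]]$w, delta)
    } else if (lay$type == "pool") {
      cache <- caches[[l]]$cache
      dim(d_act) <- cache$out_dim
      d_act <- max_pool_backward(d_act, cache)
    } else if (lay$type == "conv") {
      fwd_l <- caches[[l]]$fwd
      dim(d_act) <- dim(fwd_l$z)
      bwd <- conv_backward(d_act, fwd_l, params[[l]]$w)
      grads[[l]] <- list(d_w = bwd$d_w, d_b = bwd$d_b)
      d_act <- bwd$d_input
    }
  }
  grads
}

#' Plain gradient-descent parameter update
#'
#' `W <- W - alpha * dW`, `b <- b - alpha * db`, with batch-summed
#' gradients; no momentum, no weight decay.
#'
#' @param params Per-layer parameter list (see [init_network_params()]).
#' @param grads Matching gradient list.
#' @param learning_rate Step size `alpha`.
#' @return Updated parameter list.
#' @export
update_params <- function(params, grads, learning_rate) {
  for (l in seq_along(params)) {
    if (is.null(grads[[l]])) next
    if (!all(is.finite(grads[[l]]$d_w)) || !all(is.finite(grads[[l]]$d_b))) {
      stop_config("divergence: non-finite gradients in layer ", l)
    }
    params[[l]]$w <- params[[l]]$w - learning_rate * grads[[l]]$d_w
    params[[l]]$b <- params[[l]]$b - learning_rate * grads[[l]]$d_b
  }
  params
}

params_sq_diff <- function(a, b) {
  s <- 0
  for (l in seq_along(a)) {
    if (is.null(a[[l]])) next
    s <- s + sum((a[[l]]$w - b[[l]]$w)^2) + sum((a[[l]]$b - b[[l]]$b)^2)
  }
  s
}

#' Train the network by minibatch gradient descent
#'
#' Repeats forward pass, backward pass and plain gradient-descent updates
#' (batch-summed gradients) until the Frobenius norm of the parameter change
#' over a full pass drops below `tolerance` or `max_iterations` passes are
#' done. Softmax cross-entropy loss; deterministic for a fixed seed.
#'
#' @param spec A `network_spec` (default [default_network_spec()]).
#' @param grids A `grid_batch` from [encode_grid()], or an `(h, w, c, n)`
#'   array.
#' @param labels Labels in `{0, 1}` (length n) or a one-hot n x 2 matrix.
#' @param config A [train_config()].
#' @return An object of class `cnn_network`: `spec`, `params`, `config` and
#'   `history` (data frame of per-iteration mean loss, training accuracy
#'   and parameter-change norm).
#' @export
train_network <- function(spec = default_network_spec(), grids, labels,
                          config = train_config()) {
  stopifnot(inherits(spec, "network_spec"))
  x_all <- if (inherits(grids, "grid_batch")) grid_to_input(grids) else grids
  x_all <- as_batch_array(x_all)
  n <- dim(x_all)[4L]
  y_all <- labels_to_onehot(labels)
  if (ncol(y_all) != n) stop_config("labels length does not match input rows")
  expected <- as.integer(spec$dims[[1L]][c(3L, 1L, 2L)])  # (c, h, w)
  if (!identical(dim(x_all)[1:3], expected)) {
    stop_config("input dims (", paste(dim(x_all)[1:3], collapse = "x"),
                ") do not match the network input layer (expected channel-first ",
                paste(expected, collapse = "x"), ")")
  }
  m <- min(config$batch_size, n)
  xm_all <- x_all
  dim(xm_all) <- c(prod(dim(x_all)[1:3]), n)
  in_dim <- dim(x_all)[1:3]

  plan <- build_epoch_plan(spec)
  with_seed(config$seed, {
    params <- init_network_params(spec)
    history <- vector("list", config$max_iterations)
    for (iter in seq_len(config$max_iterations)) {
      start_params <- params
      perm <- sample.int(n)
      res <- train_epoch_cpp(plan, params[-1L], xm_all, y_all, perm, m,
                             config$learning_rate)
      params[-1L] <- res$params
      loss_sum <- res$loss
      correct <- res$correct
      if (!is.finite(loss_sum) ||
          !all(vapply(params[-1L], function(p) {
            is.null(p) || (all(is.finite(p$w)) && all(is.finite(p$b)))
          }, logical(1)))) {
        stop_config("divergence: non-finite loss or parameters at iteration ",
                    iter)
      }
      dnorm <- sqrt(params_sq_diff(params, start_params))
      history[[iter]] <- c(iteration = iter, loss = loss_sum / n,
                           accuracy = correct / n, param_change = dnorm)
      if (dnorm < config$tolerance) break
    }
    history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null,
                                                            logical(1))]))
    structure(list(spec = spec, params = params, config = config,
                   history = history),
              class = "cnn_network")
  })
}

#' @export
print.cnn_network <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<cnn_network> %d iterations | final loss %.4f | train accuracy %.3f\n",
              nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

# Forward in chunks to bound the im2col memory footprint.
forward_chunked <- function(network, grids, upto, chunk = 1024L) {
  x_all <- if (inherits(grids, "grid_batch")) grid_to_input(grids) else grids
  x_all <- as_batch_array(x_all)
  n <- dim(x_all)[4L]
  in_dim <- dim(x_all)[1:3]
  xm <- x_all
  dim(xm) <- c(prod(in_dim), n)
  parts <- lapply(seq(1L, n, by = chunk), function(b0) {
    idx <- b0:min(b0 + chunk - 1L, n)
    xb <- xm[, idx, drop = FALSE]
    dim(xb) <- c(in_dim, length(idx))
    out <- forward_network(network$spec, network$params, xb, upto = upto)
    if (upto == "features") out$features else out$probs
  })
  do.call(cbind, parts)
}

#' Extract penultimate-layer features
#'
#' Returns the activations of the last dense layer before the softmax
#' output (128 units in the default architecture) — the representation the
#' bagging ensemble is trained on. Nonnegative under ReLU; deterministic.
#'
#' @param network A trained `cnn_network`.
#' @param grids A `grid_batch` or `(h, w, c, n)` array.
#' @return Numeric matrix, n rows x feature units.
#' @export
extract_features <- function(network, grids) {
  stopifnot(inherits(network, "cnn_network"))
  t(forward_chunked(network, grids, upto = "features"))
}

#' Softmax predictions of the plain network
#'
#' @param network A trained `cnn_network`.
#' @param grids A `grid_batch` or `(h, w, c, n)` array.
#' @return List with `labels` (`{0, 1}`; the argmax of the softmax, ties
#'   broken to class 0) and `probabilities` (n x 2 matrix, rows sum to 1;
#'   columns are classes 0 and 1).
#' @export
predict_softmax <- function(network, grids) {
  stopifnot(inherits(network, "cnn_network"))
  probs <- forward_chunked(network, grids, upto = "output")
  labels <- as.integer(apply(probs, 2L, which.max) - 1L)
  list(labels = labels,
       probabilities = t(probs))
}

#' Finite-difference gradient check
#'
#' Independent verification of the backward pass: compares every analytic
#' parameter gradient against central finite differences of the
#' cross-entropy loss (which exercises only the forward pass), layer by
#' layer. The reported relative error per layer is
#' `||g_a - g_n|| / max(||g_a|| + ||g_n||, 1e-12)`.
#'
#' @param spec A `network_spec` (default: a miniature 4x4 architecture
#'   small enough for exhaustive checking).
#' @param n_samples Batch size of the random probe data (default 3).
#' @param seed Integer seed for data and initialization.
#' @param step Finite-difference step h (default 1e-5).
#' @return List with `per_layer` relative errors and `max_relative_error`.
#' @export
gradient_check <- function(spec = miniature_network_spec(), n_samples = 3L,
                           seed = 1L, step = 1e-5) {
  with_seed(seed, {
    in_dim <- spec$dims[[1L]][c(3L, 1L, 2L)]  # channel-first
    x <- array(stats::rnorm(prod(in_dim) * n_samples),
               dim = c(in_dim, n_samples))
    lab <- sample(0:1, n_samples, replace = TRUE)
    if (length(unique(lab)) == 1L) lab[1L] <- 1L - lab[1L]
    y <- labels_to_onehot(lab)
    params <- init_network_params(spec)

    fwd <- forward_network(spec, params, x)
    grads <- backward_network(spec, params, fwd, y)

    loss_at <- function(p) {
      cross_entropy(forward_network(spec, p, x)$probs, y)
    }
    per_layer <- numeric(0)
    for (l in seq_along(params)) {
      if (is.null(params[[l]])) next
      for (field in c("w", "b")) {
        theta <- params[[l]][[field]]
        ga <- grads[[l]][[paste0("d_", field)]]
        gn <- array(0, dim = dim(theta) %||% length(theta))
        for (i in seq_along(theta)) {
          p_hi <- params; p_hi[[l]][[field]][i] <- theta[i] + step
          p_lo <- params; p_lo[[l]][[field]][i] <- theta[i] - step
          gn[i] <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * step)
        }
        rel <- sqrt(sum((ga - gn)^2)) /
          max(sqrt(sum(ga^2)) + sqrt(sum(gn^2)), 1e-12)
        per_layer[sprintf("layer%d_%s", l, field)] <- rel
      }
    }
    list(per_layer = per_layer, max_relative_error = max(per_layer))
  })
}
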