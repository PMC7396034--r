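#' Network layer descriptors
#'
#' Constructors for the small descriptor grammar from which a network is
#' built: an input volume, convolution layers (ReLU, cross-correlation
#' convention, one bias per output channel), max-pooling layers (valid
#' padding), ReLU dense layers, and a softmax output layer.
#'
#' @param h,w,c Input height, width and channels.
#' @param kernel Convolution kernel size, `c(kh, kw)`.
#' @param channels Number of convolution output channels.
#' @param stride Stride of the convolution or pooling window.
#' @param padding `"same"` (spatial size preserved at stride 1) or `"valid"`.
#' @param window Pooling window size, `c(wh, ww)`.
#' @param units Number of units in a dense or output layer.
#' @return A layer descriptor list.
#' @name network_layers
NULL

#' @rdname network_layers
#' @export
layer_input <- function(h, w, c) {
  list(type = "input", dim = c(as.integer(h), as.integer(w), as.integer(c)))
}

#' @rdname network_layers
#' @export
layer_conv <- function(kernel = c(3L, 3L), channels, stride = 1L,
                       padding = c("same", "valid")) {
  list(type = "conv", kernel = as.integer(kernel),
       channels = as.integer(channels), stride = as.integer(stride),
       padding = match.arg(padding))
}

#' @rdname network_layers
#' @export
layer_pool <- function(window = c(2L, 2L), stride = 1L) {
  list(type = "pool", window = as.integer(window), stride = as.integer(stride))
}

#' @rdname network_layers
#' @export
layer_dense <- function(units) list(type = "dense", units = as.integer(units))

#' @rdname network_layers
#' @export
layer_output <- function(units = 2L) {
  list(type = "output", units = as.integer(units))
}

#' Assemble and validate a network specification
#'
#' Checks the layer sequence (input first, softmax output last, no conv or
#' pool after the first dense layer), propagates shapes through every layer,
#' and stores the resulting shape trace.
#'
#' @param layers List of layer descriptors (see [network_layers]).
#' @return An object of class `network_spec` with elements `layers` and
#'   `dims` (the output shape of every layer).
#' @seealso [default_network_spec()], [shape_trace()]
#' @export
network_spec <- function(layers) {
  if (layers[[1L]]$type != "input") stop_config("first layer must be the input")
  if (layers[[length(layers)]]$type != "output") {
    stop_config("last layer must be the softmax output")
  }
  dims <- vector("list", length(layers))
  dims[[1L]] <- layers[[1L]]$dim
  seen_dense <- FALSE
  for (l in seq_along(layers)[-1L]) {
    lay <- layers[[l]]
    prev <- dims[[l - 1L]]
    if (lay$type %in% c("conv", "pool") && seen_dense) {
      stop_config("layer ", l, ": conv/pool cannot follow a dense layer")
    }
    dims[[l]] <- switch(lay$type,
      conv = {
        g <- conv_geometry(prev[1L], prev[2L], prev[3L], lay$kernel[1L],
                           lay$kernel[2L], lay$stride, lay$padding)
        c(g$out_h, g$out_w, lay$channels)
      },
      pool = {
        if (any(prev[1:2] < lay$window)) {
          stop_config("layer ", l, ": pooling window larger than its input")
        }
        c((prev[1L] - lay$window[1L]) %/% lay$stride + 1L,
          (prev[2L] - lay$window[2L]) %/% lay$stride + 1L,
          prev[3L])
      },
      dense = { seen_dense <- TRUE; lay$units },
      output = { seen_dense <- TRUE; lay$units },
      stop_config("unknown layer type '", lay$type, "'"))
  }
  structure(list(layers = layers, dims = dims), class = "network_spec")
}

#' The default 6x6 tabular-grid architecture
#'
#' Input 6x6x1; conv 3x3x32 (same, stride 1); max pool 2x2 (stride 1);
#' conv 3x3x64 (same, stride 1); max pool 2x2 (stride 1); dense 128;
#' dense 128; softmax output over 2 classes. The shape trace is
#' 6x6x1 -> 6x6x32 -> 5x5x32 -> 5x5x64 -> 4x4x64 -> 128 -> 128 -> 2.
#'
#' @return A `network_spec`.
#' @export
default_network_spec <- function() {
  network_spec(list(
    layer_input(6L, 6L, 1L),
    layer_conv(kernel = c(3L, 3L), channels = 32L, stride = 1L, padding = "same"),
    layer_pool(window = c(2L, 2L), stride = 1L),
    layer_conv(kernel = c(3L, 3L), channels = 64L, stride = 1L, padding = "same"),
    layer_pool(window = c(2L, 2L), stride = 1L),
    layer_dense(128L),
    layer_dense(128L),
    layer_output(2L)))
}

# Small network used for exhaustive finite-difference gradient checking.
miniature_network_spec <- function() {
  network_spec(list(
    layer_input(4L, 4L, 1L),
    layer_conv(kernel = c(3L, 3L), channels = 2L, stride = 1L, padding = "same"),
    layer_pool(window = c(2L, 2L), stride = 1L),
    layer_dense(8L),
    layer_output(2L)))
}

#' Shape trace of a network
#'
#' @param spec A `network_spec`.
#' @return List of per-layer output shapes: `c(h, w, c)` for spatial layers,
#'   a single integer for dense/output layers.
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$dims
}

#' @export
print.network_spec <- function(x, ...) {
  fmt <- vapply(x$dims, function(d) paste(d, collapse = "x"), character(1))
  cat("<network_spec> ", paste(fmt, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Initialize network parameters
#'
#' He-uniform weights scaled by fan-in (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`),
#' zero biases. Convolution kernels are `kh x kw x c_in x c_out` arrays;
#' dense weights are `units x inputs` matrices.
#'
#' @param spec A `network_spec`.
#' @param seed Optional integer seed (if `NULL`, uses the current RNG state).
#' @return List of per-layer parameter sets (`NULL` for input/pool layers),
#'   each with `w` and `b`.
#' @export
init_network_params <- function(spec, seed = NULL) {
  draw <- function() {
    params <- vector("list", length(spec$layers))
    for (l in seq_along(spec$layers)) {
      lay <- spec$layers[[l]]
      prev <- spec$dims[[max(l - 1L, 1L)]]
      if (lay$type == "conv") {
        fan_in <- prod(lay$kernel) * prev[3L]
        lim <- sqrt(6 / fan_in)
        params[[l]] <- list(
          w = array(stats::runif(fan_in * lay$channels, -lim, lim),
                    dim = c(lay$kernel, prev[3L], lay$channels)),
          b = numeric(lay$channels))
      } else if (lay$type %in% c("dense", "output")) {
        fan_in <- prod(prev)
        lim <- sqrt(6 / fan_in)
        params[[l]] <- list(
          w = matrix(stats::runif(lay$units * fan_in, -lim, lim),
                     lay$units, fan_in),
          b = numeric(lay$units))
      }
    }
    params
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
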