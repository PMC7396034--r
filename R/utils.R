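# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily seeded RNG
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions never perturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  code
}

# Draw k reproducible sub-seeds from a parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_config <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         integer = FALSE, inclusive_min = TRUE,
                         allow_inf = FALSE) {
  ok <- is_scalar_number(x) ||
    (allow_inf && is.numeric(x) && length(x) == 1L && is.infinite(x) && x > 0)
  if (!ok) {
    stop_config(sprintf("field '%s' must be a single finite number", name))
  }
  ok_min <- if (inclusive_min) x >= min else x > min
  if (!ok_min || x > max) {
    stop_config(sprintf("field '%s' = %s is outside its allowed range", name, format(x)))
  }
  if (integer && x != round(x)) {
    stop_config(sprintf("field '%s' must be an integer", name))
  }
  invisible(x)
}
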