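#' @keywords internal
"_PACKAGE"

#' Signal a classed package error
#'
#' All user-facing failures carry a condition class of the form
#' `perv_<stage>_error` so callers (and the CLI) can map failures to stages.
#'
#' @param message error message.
#' @param class stage class, e.g. `"perv_input_error"`.
#' @param ... fields stored on the condition.
#' @keywords internal
perv_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "perv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so simulation helpers do not disturb the
#' caller's RNG stream; identical seeds give bit-identical draws.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    perv_error("seed must be a single finite number", "perv_input_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks used by constructors
check_num <- function(x, name, len = 1L, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    perv_error(sprintf("%s must be numeric of length %d and finite", name, len),
               "perv_input_error")
  }
  if (positive && any(x <= 0)) {
    perv_error(sprintf("%s must be > 0", name), "perv_input_error")
  }
  if (nonneg && any(x < 0)) {
    perv_error(sprintf("%s must be >= 0", name), "perv_input_error")
  }
  invisible(x)
}
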