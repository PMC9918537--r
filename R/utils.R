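#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
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
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed reproduces a whole pipeline run: each stage receives
#' `(seed * 48271 + stage_index) mod (2^31 - 1)` (a Lehmer-style
#' multiplicative hash), kept within 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param stage_index integer stage offset (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage_index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage_index))
  m <- 2147483647
  prod <- ((as.numeric(seed) %% m) * 48271) %% m  # Lehmer multiplier
  as.integer((prod + stage_index) %% m)
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)
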