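#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the previous
#' global RNG state so generators are deterministic without side effects.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Clip values to an interval
#' @param x Numeric vector.
#' @param lo,hi Interval bounds.
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic expansion of one master seed into per-stage seeds, kept
#' below 2^31 so the result is a valid R integer.
#' @keywords internal
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435L + h * 97L) %% 2147483629)
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (any(!is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}
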