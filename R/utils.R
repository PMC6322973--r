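#' Guarded ceiling
#'
#' Ceiling with a relative snap tolerance: values within `eps` (relative) of
#' an integer are snapped to that integer before the ceiling is taken, so
#' floating-point residue from chained divisions cannot charge an extra unit.
#'
#' @param x numeric vector, non-negative.
#' @param eps relative snap tolerance (default `1e-9`).
#' @return integer-valued numeric vector, `ceiling(x)` after snapping.
#' @examples
#' ceil_guard(25.000000000001)  # 25, not 26
#' ceil_guard(25.001)           # 26
#' @export
ceil_guard <- function(x, eps = 1e-9) {
  near <- round(x)
  snap <- abs(x - near) <= eps * pmax(1, abs(x))
  ifelse(snap, near, ceiling(x))
}

# round to the nearest multiple of `unit`
round_to <- function(x, unit) round(x / unit) * unit

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
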