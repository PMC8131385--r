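#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's generator, evaluates `expr`, and
#' restores the previous state on exit. All stochastic code in the package
#' funnels through this helper, so identical seeds give identical results
#' without disturbing the session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic 31-bit stream split: the same master seed and index path
#' always yield the same child, and children for different paths are
#' effectively independent. Used to give every patient / repeat / candidate
#' its own reproducible seed.
#'
#' @param seed master integer seed.
#' @param ... integer path components (e.g. patient index, repeat index).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.double(seed %% 2147483647L)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(max(1, x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_bilex <- function(...) stop(..., call. = FALSE)
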