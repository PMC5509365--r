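# internal validation helpers

stop_dim <- function(axis, expected, got) {
  stop(sprintf("dimension mismatch on %s: expected %d, got %d",
               axis, expected, got), call. = FALSE)
}

check_nonneg_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("%s must be nonnegative", what), call. = FALSE)
  invisible(x)
}

# set.seed only when the caller supplies one, without clobbering the
# caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
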