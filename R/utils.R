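# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a parent seed
#'
#' Every stochastic stage of the pipeline takes an explicit integer seed.
#' Stage seeds are derived deterministically from a single global seed so a
#' whole run is reproducible from one number. The result always fits in a
#' 32-bit signed integer.
#'
#' @param seed parent integer seed.
#' @param stage stage label (character) or integer offset.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((abs(seed) * 69069 + stage * 1013904223) %% 2147483647)
}

# run code under a local RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# ceil-halving chain: spatial size after k pooling stages
ceil_halve <- function(dims, times = 1L) {
  for (i in seq_len(times)) dims <- ceiling(dims / 2)
  as.integer(dims)
}
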