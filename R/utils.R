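# Internal helpers shared across modules.

#' Derive named substream seeds from a master seed
#'
#' All stochastic stages draw their randomness from a single master seed via
#' named substreams, so that e.g. re-running the expression simulator does not
#' perturb the tissue simulator. Derived seeds stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param streams Character vector of substream names.
#' @return Named integer vector of seeds.
#' @export
derive_seeds <- function(seed, streams = c("tissue", "imaging", "expression", "trend")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(s) <- streams
  s
}

# run expr with a local RNG state seeded by `seed`, restoring global state after
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stop_if_not_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop(sprintf("`%s` must be %s", name, if (strict) "> 0" else ">= 0"), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
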