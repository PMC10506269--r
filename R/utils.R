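stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state so callers never perturb the session stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is_count(seed, min = -.Machine$integer.max)) {
    stopf("seed must be a single integer, got %s", deparse(seed))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Glorot/Xavier uniform initialisation, the Keras default for dense and
# convolution kernels; draws from the caller's RNG stream.
glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

activation_fun <- function(tag) {
  switch(tag,
    relu = relu,
    sigmoid = sigmoid,
    identity = identity,
    stopf("unknown activation '%s'", tag)
  )
}
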