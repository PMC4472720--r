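# Shared helpers: classed conditions, seeded RNG scoping, bitmask utilities.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("statbin_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io <- function(msg, ...) {
  stop(structure(
    class = c("statbin_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream seed from a master seed; stays below 2^31.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 1000003 * as.double(i)) %% 2147483629)
}

# Number of set bits in each (31-bit, non-negative) integer.
popcount <- function(x) {
  n <- 0L
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
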