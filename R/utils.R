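#' Derive a child RNG seed from a top-level seed and a stream name
#'
#' All stochastic entry points in the package draw their seed from one
#' top-level integer through named streams, so that a single \code{--seed}
#' reproduces every output while different modules see decorrelated streams.
#' The derived seed is always in \code{[0, 2^31 - 2]}.
#'
#' @param seed integer top-level seed.
#' @param stream character stream name, e.g. \code{"segregation"}.
#' @return a single integer seed.
#' @examples
#' childSeed(1L, "segregation")
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L, nzchar(stream))
  m <- 2147483647                      # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

## internal: single non-negative finite scalar check with a named error
assertScalar <- function(x, name, lower = 0, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%g, %g]",
                 name, lower, upper), call. = FALSE)
  }
  invisible(x)
}
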