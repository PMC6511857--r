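#' Construct a ripple-counter state
#'
#' @param bits 0/1 digits, units first (index 1 is the units latch).
#' @return a validated \linkS4class{CounterState}.
#' @examples
#' counterValue(counterState(c(1, 0, 1)))   # 5
#' @export
counterState <- function(bits) new("CounterState", bits = as.integer(bits))

#' @describeIn counterState the bit vector, units first
#' @param object a \linkS4class{CounterState}.
#' @export
setMethod("counterBits", "CounterState", function(object) object@bits)

#' @describeIn counterState the represented integer, sum of bits_i 2^i
#' @export
setMethod("counterValue", "CounterState", function(object)
  sum(object@bits * 2^(seq_along(object@bits) - 1L)))

#' @describeIn counterState display, most-significant bit first
#' @export
setMethod("show", "CounterState", function(object) {
  cat(sprintf("CounterState: %s (value %d)\n",
              paste(rev(object@bits), collapse = ""),
              counterValue(object)))
})

## toggle one counter and propagate carries units-first; returns new bits
rippleToggleOnce <- function(bits, p, q, carry_eff, stochastic) {
  carry <- TRUE                       # the input pulse drives the units latch
  for (i in seq_along(bits)) {
    if (!carry) break
    if (stochastic) {
      prob <- if (bits[i] == 1L) q else p
      flip <- runif(1) < prob
    } else flip <- TRUE
    emit <- FALSE
    if (flip) {
      emit <- bits[i] == 1L           # carry emitted on the 1 -> 0 transition
      bits[i] <- 1L - bits[i]
    }
    carry <- emit &&
      (!stochastic || carry_eff >= 1 || runif(1) < carry_eff) &&
      carry_eff > 0
  }
  bits
}

#' Count input pulses on a chain of N latches
#'
#' Asynchronous ripple counter: each input pulse toggles the units latch;
#' every latch passes an instantaneous carry to the next exactly when it
#' transitions from 1 to 0, processed units-first within the pulse.  In
#' ideal deterministic mode (perfect toggling, perfect carries) the counter
#' value after k pulses is exactly \code{k mod 2^N}, so three latches count
#' 0 to 7 and then roll over.
#'
#' In stochastic mode each of \code{n_cells} cells carries an independent
#' counter whose latches toggle with probabilities \code{p}/\code{q} and
#' whose carries succeed with probability \code{carry_efficiency}; the
#' result is the empirical distribution over counter values per pulse.
#'
#' @param n_latches number of latches N (>= 1).
#' @param n_pulses number of input pulses.
#' @param params a \linkS4class{ToggleParams}; ignored in deterministic
#'   mode, where toggling is perfect.
#' @param carry_efficiency probability a 1->0 transition fires the next
#'   latch (default 1).
#' @param mode \code{"deterministic"} (ideal) or \code{"stochastic"}.
#' @param n_cells cells in stochastic mode (default 1000).
#' @param seed RNG seed for stochastic mode.
#' @return deterministic mode: data.frame (pulse = 0:n_pulses, bits
#'   most-significant-first, value); stochastic mode: data.frame (pulse,
#'   value, probability).
#' @examples
#' rippleCount(3, 8)        # 0,1,...,7,0
#' @export
rippleCount <- function(n_latches, n_pulses, params = toggleParams(1, 1),
                        carry_efficiency = 1,
                        mode = c("deterministic", "stochastic"),
                        n_cells = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_latches >= 1, n_pulses >= 0)
  assertScalar(carry_efficiency, "carry_efficiency", upper = 1)
  if (mode == "deterministic") {
    bits <- integer(n_latches)
    states <- vector("list", n_pulses + 1L)
    states[[1L]] <- bits
    for (k in seq_len(n_pulses)) {
      bits <- rippleToggleOnce(bits, 1, 1, 1, stochastic = FALSE)
      states[[k + 1L]] <- bits
    }
    data.frame(
      pulse = 0:n_pulses,
      bits = vapply(states, function(b) paste(rev(b), collapse = ""), ""),
      value = vapply(states, function(b)
        sum(b * 2^(seq_along(b) - 1L)), numeric(1)))
  } else {
    stopifnot(is(params, "ToggleParams"), n_cells >= 1)
    set.seed(childSeed(seed, "ripple"))
    cells <- matrix(0L, n_cells, n_latches)
    out <- vector("list", n_pulses + 1L)
    tab <- function(k) {
      vals <- as.vector(cells %*% 2^(seq_len(n_latches) - 1L))
      tt <- table(factor(vals, levels = 0:(2^n_latches - 1L)))
      data.frame(pulse = k, value = as.integer(names(tt)),
                 probability = as.numeric(tt) / n_cells)
    }
    out[[1L]] <- tab(0L)
    for (k in seq_len(n_pulses)) {
      for (i in seq_len(n_cells))
        cells[i, ] <- rippleToggleOnce(cells[i, ], params@p, params@q,
                                       carry_efficiency, stochastic = TRUE)
      out[[k + 1L]] <- tab(k)
    }
    res <- do.call(rbind, out)
    res[res$probability > 0, , drop = FALSE]
  }
}
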