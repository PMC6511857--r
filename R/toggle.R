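#' Construct per-pulse toggle parameters
#'
#' The discrete two-state model of repeated latch operation: at each input
#' pulse a PB-state cell switches to LR with probability \code{p} and an
#' LR-state cell switches back to PB with probability \code{q} (the values
#' 0.95 and 0.85 describe the observed 70-generation operation of the
#' optimised switch).
#'
#' @param p,q transition probabilities in [0, 1].
#' @return a validated \linkS4class{ToggleParams}.
#' @export
toggleParams <- function(p = 0.95, q = 0.85) {
  new("ToggleParams", p = as.numeric(p), q = as.numeric(q))
}

#' @describeIn toggleParams display
#' @param object a \linkS4class{ToggleParams}.
#' @export
setMethod("show", "ToggleParams", function(object) {
  cat(sprintf("ToggleParams: p(PB->LR) = %.3g, q(LR->PB) = %.3g\n",
              object@p, object@q))
  if (object@p + object@q > 0)
    cat(sprintf("  stationary LR fraction %.4f\n",
                stationaryFraction(object)))
})

#' One pulse of the deterministic two-state recursion
#'
#' \code{f' = p (1 - f) + (1 - q) f}.  The map sends [0, 1] into [0, 1] and
#' contracts toward the fixed point \code{p / (p + q)} with geometric ratio
#' \code{|1 - p - q|}, giving the damped alternating convergence seen over
#' repeated pulses.
#'
#' @param f current LR fraction(s) in [0, 1] (vectorised).
#' @param params a \linkS4class{ToggleParams}.
#' @return next LR fraction(s).
#' @examples
#' stepFraction(0, toggleParams(0.95, 0.85))   # 0.95
#' @export
stepFraction <- function(f, params) {
  stopifnot(is(params, "ToggleParams"))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("'f' must lie in [0, 1]")
  params@p * (1 - f) + (1 - params@q) * f
}

#' Stationary LR fraction of the per-pulse toggle
#'
#' The unique fixed point \code{p / (p + q)} of \code{\link{stepFraction}}
#' (about 0.528 at p = 0.95, q = 0.85, i.e. the ~52\% LR / ~48\% PB steady
#' state of repeated operation).
#'
#' @param params a \linkS4class{ToggleParams} with \code{p + q > 0}.
#' @return the stationary LR fraction.
#' @export
stationaryFraction <- function(params) {
  stopifnot(is(params, "ToggleParams"))
  if (params@p + params@q <= 0)
    stop("stationary fraction undefined for p = q = 0")
  params@p / (params@p + params@q)
}

#' Fraction of cells changing state per pulse at stationarity
#'
#' At the fixed point the PB->LR and LR->PB fluxes balance:
#' \code{(1 - f*) p = f* q}, and the total switching fraction is
#' \code{2 p q / (p + q)} (about 0.90 at p = 0.95, q = 0.85: most cells
#' change state at every signal even though the population composition is
#' static).  The flux balance is certified to machine precision before
#' returning.
#'
#' @param params a \linkS4class{ToggleParams} with \code{p + q > 0}.
#' @return the per-pulse switching fraction, with attributes
#'   \code{flux_pb_to_lr} and \code{flux_lr_to_pb}.
#' @export
switchFractionAtStationarity <- function(params) {
  fstar <- stationaryFraction(params)
  up <- (1 - fstar) * params@p
  down <- fstar * params@q
  if (abs(up - down) > 1e-12)
    stop("flux balance violated at the fixed point")   # cannot happen
  structure(up + down, flux_pb_to_lr = up, flux_lr_to_pb = down)
}

#' Stochastic per-cell toggling over repeated pulses
#'
#' Each of \code{n_cells} cells carries one latch; at every pulse it toggles
#' independently with probability \code{p} or \code{q} according to its
#' state.  The mean trajectory converges to the deterministic
#' \code{\link{stepFraction}} recursion as \code{n_cells} grows, with
#' binomial Monte-Carlo error.
#'
#' @param n_cells number of cells (>= 1).
#' @param params a \linkS4class{ToggleParams}.
#' @param n_pulses number of pulses.
#' @param seed RNG seed.
#' @param init_lr logical vector (recycled) of initial LR states; default
#'   all PB.
#' @return data.frame (pulse = 0:n_pulses, fraction_lr).
#' @export
simulateToggleCells <- function(n_cells, params, n_pulses, seed = 1L,
                                init_lr = FALSE) {
  stopifnot(is(params, "ToggleParams"), n_cells >= 1, n_pulses >= 0)
  set.seed(childSeed(seed, "toggle"))
  state <- rep_len(as.logical(init_lr), n_cells)
  frac <- numeric(n_pulses + 1L)
  frac[1L] <- mean(state)
  for (k in seq_len(n_pulses)) {
    u <- runif(n_cells)
    state <- ifelse(state, u >= params@q, u < params@p)
    frac[k + 1L] <- mean(state)
  }
  data.frame(pulse = 0:n_pulses, fraction_lr = frac)
}
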