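#' Pre-pulse steady-state initial condition
#'
#' Analytic steady state of the latch held in a pure DNA state with no
#' arabinose.  In a pure state the expression subsystem is linear (the DNA
#' inputs are constant and there is no integrase), so the steady state is
#' exact when \code{leak_bad = 0}; with a leaky P_BAD an optional relaxation
#' integration refines it.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param state \code{"PB"} or \code{"LR"}: which pure DNA state to hold.
#' @param relax_h hours of no-pulse integration to relax the analytic state
#'   (only needed when \code{leak_bad > 0}); default 0.
#' @return named numeric vector over \code{speciesNames(network)}.
#' @examples
#' init <- steadyInit(buildNetwork(latchParams()), "PB")
#' @export
steadyInit <- function(network, state = c("PB", "LR"), relax_h = 0) {
  stopifnot(is(network, "ReactionNetwork"))
  state <- match.arg(state)
  p <- network@params
  x <- setNames(numeric(length(network@species)), network@species)
  dm <- p@d_mrna + p@mu
  if (state == "PB") {
    x["dna_pb"] <- 1
    if (p@tetr_circuit_enabled) {
      x["m_tet"] <- p@k_tx_tetr * p@c_switch / dm
      x["tetr"] <- p@k_tl_tetr * x["m_tet"] / (p@d_tetr + p@mu)
    }
  } else {
    x["dna_lr"] <- 1
    # TetR absent in LR, so the RDF promoter is fully active
    x["m_rdf"] <- p@k_tx_rdf * p@c_switch / dm
    x["rdf"] <- p@k_tl_rdf * x["m_rdf"] / (p@d_rdf + p@mu)
  }
  if (relax_h > 0) {
    quiet <- pulseProtocol(numeric(0), numeric(0), horizon = relax_h)
    tr <- simulateLatch(network, quiet, init = x,
                        times = c(0, relax_h / 2, relax_h))
    x <- tr@states[nrow(tr@states), ]
  }
  x
}

## derivative of the network state: stoichiometry %*% reaction rates
networkDeriv <- function(network, t, x, ara) {
  drop(network@stoich %*% network@rateFun(t, x, ara))
}

#' Integrate the latch ODE model
#'
#' Integrates the network with the stiff solver of \pkg{deSolve}
#' (\code{lsoda}), piecewise between pulse boundaries so that the square
#' arabinose input is constant within every integration segment.  The
#' trajectory is checked for non-negativity (to solver tolerance) and
#' conservation of total switch DNA; integrator failure raises an error with
#' diagnostics rather than returning a truncated result.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param init named initial state; defaults to the all-PB steady state.
#'   Must be non-negative with positive total switch DNA.
#' @param times output time grid (h) within \code{[0, horizon]}; default a
#'   481-point grid plus all pulse boundaries.
#' @param rtol,atol relative/absolute solver tolerances (defaults 1e-8,
#'   1e-10).
#' @return a \linkS4class{LatchTrajectory}.
#' @examples
#' net <- buildNetwork(latchParams())
#' traj <- simulateLatch(net, pulseProtocol(0.5, 0.2, horizon = 12))
#' tail(fractionLR(traj), 1)   # LR fraction at 12 h
#' @export
simulateLatch <- function(network, protocol, init = NULL, times = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(network, "ReactionNetwork"), is(protocol, "PulseProtocol"))
  if (is.null(init)) init <- steadyInit(network, "PB")
  if (!all(network@species %in% names(init)))
    stop("init must name every network species")
  init <- init[network@species]
  if (any(init < 0)) stop("init must be non-negative")
  dna0 <- sum(init[dnaSpecies(network)])
  if (dna0 <= 0) stop("init must contain switch DNA")

  hz <- protocol@horizon
  if (is.null(times)) times <- seq(0, hz, length.out = 481L)
  if (any(times < 0 | times > hz)) stop("times must lie in [0, horizon]")
  pulses <- protocol@pulses[protocol@pulses$inducer == "ara", , drop = FALSE]
  bounds <- sort(unique(pmin(pmax(
    c(0, hz, pulses$start, pulses$start + pulses$duration), 0), hz)))
  # merge output times with pulse boundaries, collapsing float near-duplicates
  # onto the boundary value so every segment has well-separated mesh points
  grid <- sort(c(times, bounds))
  near <- vapply(grid, function(g) {
    j <- which(abs(bounds - g) < 1e-9)
    if (length(j)) bounds[j[1L]] else g
  }, numeric(1))
  grid <- unique(near)
  times <- unique(vapply(times, function(g) {
    j <- which(abs(bounds - g) < 1e-9)
    if (length(j)) bounds[j[1L]] else g
  }, numeric(1)))

  state <- init
  outT <- numeric(0); outX <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    seg <- grid[grid >= t0 & grid <= t1]
    if (seg[1L] > t0) seg <- c(t0, seg)
    if (seg[length(seg)] < t1) seg <- c(seg, t1)
    ara <- arabinoseInput((t0 + t1) / 2, protocol)
    sol <- deSolve::ode(
      y = state, times = seg,
      func = function(t, y, parms) list(networkDeriv(network, t, y, ara)),
      method = "lsoda", rtol = rtol, atol = atol)
    if (anyNA(sol) || abs(sol[nrow(sol), "time"] - t1) > 1e-10)
      stop(sprintf(
        "ODE solver failed in segment [%.4g, %.4g] h (ara = %g); %s",
        t0, t1, ara, "try looser tolerances or revised parameters"))
    m <- sol[, -1L, drop = FALSE]
    keep <- seg %in% times & (if (k > 1L) seg > t0 else TRUE)
    outT <- c(outT, seg[keep])
    outX <- rbind(outX, m[keep, , drop = FALSE])
    state <- m[nrow(m), ]
  }
  colnames(outX) <- network@species
  # negatives within solver tolerance are integration noise: clamp to zero;
  # anything larger is a genuine failure
  neg_tol <- max(1e-9, 100 * atol)
  if (min(outX) < -neg_tol)
    stop("trajectory violates non-negativity beyond solver tolerance")
  outX[outX < 0] <- 0
  dna <- rowSums(outX[, dnaSpecies(network), drop = FALSE])
  if (max(abs(dna - dna0)) > 1e-6 * dna0)
    stop("trajectory violates switch-DNA conservation beyond tolerance")
  new("LatchTrajectory", times = outT, states = outX,
      network = network, protocol = protocol)
}

#' @describeIn simulateLatch time grid of a trajectory
#' @param object a \linkS4class{LatchTrajectory}.
#' @export
setMethod("trajectoryTimes", "LatchTrajectory", function(object) object@times)

#' @describeIn simulateLatch state matrix (time x species) of a trajectory
#' @export
setMethod("stateMatrix", "LatchTrajectory", function(object) object@states)

#' @describeIn simulateLatch species registry of the underlying network
#' @export
setMethod("speciesNames", "LatchTrajectory",
          function(object) object@network@species)

#' @describeIn simulateLatch display a trajectory
#' @export
setMethod("show", "LatchTrajectory", function(object) {
  f <- fractionLR(object)
  cat(sprintf(
    "LatchTrajectory: %d points over [0, %.3g] h; final LR fraction %.3f\n",
    length(object@times), max(object@times), f[length(f)]))
})

#' Fraction of switch DNA in the LR configuration
#'
#' Summarises the DNA species into the \%LR readout quantified on gels:
#' (LR + LR-configured synaptic complexes) / total switch DNA.  Synaptic
#' complexes count for the configuration they currently hold (the PB->LR
#' synapse still holds PB).
#'
#' @param traj a \linkS4class{LatchTrajectory}.
#' @param t optional time(s) (h) at which to evaluate by linear
#'   interpolation; out-of-range times are an error.  Default: the whole
#'   trajectory grid.
#' @param ... unused.
#' @return numeric vector of fractions in [0, 1].
#' @export
setMethod("fractionLR", "LatchTrajectory", function(traj, t = NULL, ...) {
  st <- traj@states
  lr <- rowSums(st[, lrSpecies(traj@network), drop = FALSE])
  tot <- rowSums(st[, dnaSpecies(traj@network), drop = FALSE])
  f <- lr / tot
  if (is.null(t)) return(f)
  if (any(t < min(traj@times) | t > max(traj@times)))
    stop("requested time outside the trajectory range")
  approx(traj@times, f, xout = t)$y
})

#' Multi-cycle operation of the latch
#'
#' Applies \code{n_pulses} identical arabinose pulses separated by
#' \code{spacing} hours (first pulse at \code{t0}), integrating continuously
#' across cycles with no state reset, and reports the LR fraction at the end
#' of each inter-pulse interval (just before the next pulse, and at the
#' horizon for the last).
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param n_pulses number of pulses (>= 1).
#' @param pulse_len pulse length (h).
#' @param spacing pulse period (h); must exceed \code{pulse_len}.
#' @param init initial state; default all-PB steady state.
#' @param t0 time of the first pulse (h), default 0.5.
#' @param ... passed to \code{\link{simulateLatch}}.
#' @return list with \code{cycles} (data.frame pulse, t_end, fraction_lr)
#'   and \code{trajectory}.
#' @export
runCycles <- function(network, n_pulses, pulse_len, spacing, init = NULL,
                      t0 = 0.5, ...) {
  stopifnot(n_pulses >= 1, spacing > pulse_len, pulse_len > 0)
  starts <- t0 + spacing * (seq_len(n_pulses) - 1)
  horizon <- t0 + spacing * n_pulses
  prot <- pulseProtocol(starts, pulse_len, horizon = horizon)
  tEnd <- starts + spacing
  grid <- sort(unique(c(seq(0, horizon, length.out = 241L), tEnd)))
  traj <- simulateLatch(network, prot, init = init, times = grid, ...)
  list(cycles = data.frame(pulse = seq_len(n_pulses), t_end = tEnd,
                           fraction_lr = fractionLR(traj, tEnd)),
       trajectory = traj)
}

#' Terminal LR fraction as a function of pulse length
#'
#' For each pulse length, applies a single pulse (at \code{t0}) from the
#' pure-state steady state of the requested direction and evaluates the LR
#' fraction after a fixed post-pulse relaxation interval.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param pulse_lengths vector of pulse lengths (h), all > 0.
#' @param direction \code{"PBtoLR"} (start all-PB) or \code{"LRtoPB"}
#'   (start all-LR).
#' @param relax_h post-pulse relaxation before reading out (h), default 6.
#' @param t0 pulse start (h), default 0.5.
#' @param ... passed to \code{\link{simulateLatch}}.
#' @return data.frame (pulse_len, fraction_lr).
#' @export
pulseScan <- function(network, pulse_lengths, direction = c("PBtoLR", "LRtoPB"),
                      relax_h = 6, t0 = 0.5, ...) {
  direction <- match.arg(direction)
  stopifnot(all(pulse_lengths > 0))
  init <- steadyInit(network, if (direction == "PBtoLR") "PB" else "LR")
  out <- vapply(pulse_lengths, function(L) {
    hz <- t0 + L + relax_h
    prot <- pulseProtocol(t0, L, horizon = hz)
    traj <- simulateLatch(network, prot, init = init,
                          times = seq(0, hz, length.out = 201L), ...)
    fractionLR(traj, hz)
  }, numeric(1))
  data.frame(pulse_len = pulse_lengths, fraction_lr = out)
}
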