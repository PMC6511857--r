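# Shared fixtures: networks and protocols reused across test files.

defaultNet <- function(...) buildNetwork(latchParams(...))

# the single 12-min arabinose pulse at 0.5 h used throughout the examples
pulse12min <- function(horizon = 24) pulseProtocol(0.5, 0.2, horizon = horizon)

# inert parameter set: no production, no decay, no growth — only the
# recombination machinery (useful for conservation checks)
inertParams <- function(...) {
  latchParams(k_tx_int = 0, k_tx_rdf = 0, k_tx_tetr = 0,
              k_tl_int = 0, k_tl_rdf = 0, k_tl_tetr = 0,
              d_mrna = 0, d_int = 0, d_rdf = 0, d_tetr = 0, mu = 0, ...)
}

# named state vector over a network's species with selected values set
stateWith <- function(net, ...) {
  x <- stats::setNames(numeric(length(speciesNames(net))), speciesNames(net))
  vals <- list(...)
  x[names(vals)] <- unlist(vals)
  x
}
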