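#' Construct a pulse protocol
#'
#' @param starts numeric vector of pulse start times (h).
#' @param durations pulse durations (h); recycled to the length of
#'   \code{starts}.
#' @param horizon total simulated time (h); must contain all pulses.
#' @param inducer inducer identity, default \code{"ara"}.
#' @return a validated \linkS4class{PulseProtocol}.
#' @examples
#' # the single 12-min arabinose pulse at 0.5 h used throughout
#' pulseProtocol(0.5, 0.2, horizon = 24)
#' # daily pulses
#' pulseProtocol(0.5 + 24 * (0:5), 0.2, horizon = 24 * 6 + 0.5)
#' @export
pulseProtocol <- function(starts, durations, horizon, inducer = "ara") {
  stopifnot(is.numeric(starts), is.numeric(durations), length(starts) >= 0)
  durations <- rep_len(durations, length(starts))
  inducer <- rep_len(as.character(inducer), length(starts))
  new("PulseProtocol",
      pulses = data.frame(start = as.numeric(starts),
                          duration = as.numeric(durations),
                          inducer = inducer, stringsAsFactors = FALSE),
      horizon = as.numeric(horizon))
}

#' Inducer activity at a given time
#'
#' Square-pulse convention: activity is 1 inside a pulse (closed at the start,
#' open at the end) and 0 outside.  Instantaneous switch-off models the
#' 1:1000 dilution into glucose that terminates induction experimentally.
#'
#' @param t time(s) in hours; every value must lie in \code{[0, horizon]}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param inducer which inducer to evaluate (default \code{"ara"}).
#' @return numeric vector of 0/1 activities, same length as \code{t}.
#' @examples
#' pp <- pulseProtocol(0.5, 0.2, horizon = 24)
#' arabinoseInput(c(0.4, 0.6), pp)   # 0, then 1
#' @export
arabinoseInput <- function(t, protocol, inducer = "ara") {
  stopifnot(is(protocol, "PulseProtocol"), is.numeric(t))
  if (any(t < 0 | t > protocol@horizon))
    stop("time outside [0, horizon] of the protocol")
  p <- protocol@pulses[protocol@pulses$inducer == inducer, , drop = FALSE]
  out <- numeric(length(t))
  for (i in seq_len(nrow(p)))
    out <- out | (t >= p$start[i] & t < p$start[i] + p$duration[i])
  as.numeric(out)
}

#' @describeIn pulseProtocol display a protocol
#' @param object a \linkS4class{PulseProtocol}.
#' @export
setMethod("show", "PulseProtocol", function(object) {
  cat(sprintf("PulseProtocol: %d pulse(s), horizon %.3g h\n",
              nrow(object@pulses), object@horizon))
  if (nrow(object@pulses)) {
    p <- object@pulses
    cat(sprintf("  %s at %.3g h for %.3g h\n", p$inducer, p$start, p$duration),
        sep = "")
  }
})
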