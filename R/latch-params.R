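#' Construct latch model parameters
#'
#' Returns a \linkS4class{LatchParams} object with the package's calibrated
#' defaults, overriding any field passed by name.  The defaults are chosen so
#' that, with the TetR delay circuit, PB->LR recombination is detectable
#' within ~10 min of induction and near complete by ~60 min, a single 12-min
#' arabinose pulse completes either transition, and daily pulses toggle the
#' latch repeatedly (see the package vignette for the calibration targets).
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return a validated \linkS4class{LatchParams}.
#' @examples
#' p <- latchParams()
#' p2 <- latchParams(k_tx_rdf = 10 * p@k_tx_rdf)   # RDF overexpression
#' @export
latchParams <- function(...) {
  defaults <- list(
    k_tx_int = 0.12, k_tx_rdf = 0.05, k_tx_tetr = 0.05,
    k_tl_int = 60, k_tl_rdf = 30, k_tl_tetr = 15,
    d_mrna = 8,
    d_int = 0.8, d_rdf = 0.2, d_tetr = 0,
    mu = 0.7,
    K_tet = 0.1, n_tet = 3, leak_tet = 0.02, leak_bad = 0,
    k_dim = 50, k_undim = 1,
    k_rdf_on = 100, K_rdf = 0.1,
    k_syn_on = 200, k_syn_off = 1, k_cat_f = 20, k_cat_r = 20,
    c_switch = 20, c_int = 10, dna_um = 0.03,
    tetr_circuit_enabled = TRUE, dead_end_pb = FALSE,
    k_dead_on = 50, k_dead_off = 1)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown LatchParams field(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  do.call(new, c(list(Class = "LatchParams"), defaults))
}

#' Lumped production rates of a parameter set
#'
#' The fraction-LR readout cannot separate transcription from translation, so
#' fitting works on the lumped production rate per protein, the product
#' k_tx * k_tl (µM protein per hour per plasmid copy at full promoter
#' activity).
#'
#' @param params a \linkS4class{LatchParams}.
#' @return named numeric vector \code{c(int=, rdf=, tetr=)}.
#' @seealso \code{\link{applyProductionRates}}, \code{\link{fitProductionRates}}
#' @export
lumpedProductionRates <- function(params) {
  stopifnot(is(params, "LatchParams"))
  c(int  = params@k_tx_int  * params@k_tl_int,
    rdf  = params@k_tx_rdf  * params@k_tl_rdf,
    tetr = params@k_tx_tetr * params@k_tl_tetr)
}

#' Impose lumped production rates on a parameter set
#'
#' Rescales the translation rates so that k_tx * k_tl equals the requested
#' lumped rate for each named protein, leaving all other parameters alone.
#'
#' @param params a \linkS4class{LatchParams}.
#' @param rates named numeric vector with any of \code{int}, \code{rdf},
#'   \code{tetr}.
#' @return a modified \linkS4class{LatchParams}.
#' @export
applyProductionRates <- function(params, rates) {
  stopifnot(is(params, "LatchParams"), is.numeric(rates),
            !is.null(names(rates)))
  bad <- setdiff(names(rates), c("int", "rdf", "tetr"))
  if (length(bad))
    stop("unknown production rate name(s): ", paste(bad, collapse = ", "))
  if (any(rates < 0)) stop("production rates must be >= 0")
  if ("int" %in% names(rates))  params@k_tl_int  <- rates[["int"]]  / params@k_tx_int
  if ("rdf" %in% names(rates))  params@k_tl_rdf  <- rates[["rdf"]]  / params@k_tx_rdf
  if ("tetr" %in% names(rates)) params@k_tl_tetr <- rates[["tetr"]] / params@k_tx_tetr
  validObject(params)
  params
}

#' @describeIn latchParams compact display of a parameter set
#' @param object a \linkS4class{LatchParams}.
#' @export
setMethod("show", "LatchParams", function(object) {
  cat("LatchParams (", if (object@tetr_circuit_enabled)
    "TetR delay circuit" else "no TetR circuit", ")\n", sep = "")
  lump <- lumpedProductionRates(object)
  cat(sprintf("  lumped production (uM/h/copy): int %.3g, rdf %.3g, tetr %.3g\n",
              lump["int"], lump["rdf"], lump["tetr"]))
  cat(sprintf("  dilution mu = %.3g/h; copy numbers: switch %g, int %g\n",
              object@mu, object@c_switch, object@c_int))
})
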