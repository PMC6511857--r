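## S4 class definitions and validity methods for all latchSim containers.
## Constructors, accessors and show() methods live with their module files.

#' LatchParams: rate constants and copy numbers of the latch ODE model
#'
#' Holds every parameter of the deterministic latch model.  Units: rates in
#' 1/h, concentrations in µM, switch DNA in arbitrary units normalised to a
#' total of 1 (one AU corresponds to \code{dna_um} µM of plasmid, default
#' 0.03 µM for ~20 copies/cell).  Transcription rates are per plasmid copy;
#' the copy numbers \code{c_switch}/\code{c_int} multiply them.
#'
#' @slot k_tx_int,k_tx_rdf,k_tx_tetr transcription rates (µM mRNA/h per copy);
#'   integrase from the arabinose-induced promoter, RDF per accessible
#'   LR-state copy, TetR per PB-state copy.
#' @slot k_tl_int,k_tl_rdf,k_tl_tetr translation rates (protein per mRNA/h).
#' @slot d_mrna mRNA degradation rate (1/h).
#' @slot d_int,d_rdf,d_tetr protein degradation rates (1/h).
#' @slot mu growth/dilution rate (1/h), applied to all mRNA/protein species.
#' @slot K_tet TetR repression half-maximal concentration (µM).
#' @slot n_tet Hill coefficient (>= 1).
#' @slot leak_tet residual P_LtetO-1 activity at saturating TetR (fraction).
#' @slot leak_bad residual P_BAD activity without arabinose (fraction).
#' @slot k_dim,k_undim integrase dimerisation/dissociation rates.
#' @slot k_rdf_on association rate of the integrase-dimer:RDF complex
#'   (1/(µM·h)); dissociation rate is \code{k_rdf_on * K_rdf}.
#' @slot K_rdf dissociation constant of the dimer:RDF complex (µM).
#' @slot k_syn_on,k_syn_off synapse assembly (1/(µM^2·h)) / disassembly (1/h).
#' @slot k_cat_f,k_cat_r PB->LR and LR->PB catalytic conversion rates (1/h).
#' @slot c_switch,c_int switch- and integrase-plasmid copy numbers.
#' @slot dna_um µM of plasmid DNA corresponding to 1 AU of switch DNA.
#' @slot tetr_circuit_enabled logical; TRUE selects the TetR delay circuit,
#'   FALSE the circuit with constitutive (unrepressed) RDF expression from LR
#'   and no TetR production.
#' @slot dead_end_pb logical; optional inhibitory binding of the dimer:RDF
#'   complex to PB DNA (default OFF).
#' @slot k_dead_on,k_dead_off rates of the optional dead-end binding.
#' @seealso \code{\link{latchParams}}
#' @export
setClass("LatchParams", representation(
  k_tx_int = "numeric", k_tx_rdf = "numeric", k_tx_tetr = "numeric",
  k_tl_int = "numeric", k_tl_rdf = "numeric", k_tl_tetr = "numeric",
  d_mrna = "numeric",
  d_int = "numeric", d_rdf = "numeric", d_tetr = "numeric",
  mu = "numeric",
  K_tet = "numeric", n_tet = "numeric", leak_tet = "numeric",
  leak_bad = "numeric",
  k_dim = "numeric", k_undim = "numeric",
  k_rdf_on = "numeric", K_rdf = "numeric",
  k_syn_on = "numeric", k_syn_off = "numeric",
  k_cat_f = "numeric", k_cat_r = "numeric",
  c_switch = "numeric", c_int = "numeric", dna_um = "numeric",
  tetr_circuit_enabled = "logical", dead_end_pb = "logical",
  k_dead_on = "numeric", k_dead_off = "numeric"))

setValidity("LatchParams", function(object) {
  msgs <- character()
  num <- setdiff(slotNames(object), c("tetr_circuit_enabled", "dead_end_pb"))
  for (s in num) {
    v <- slot(object, s)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single finite value >= 0", s))
  }
  if (length(msgs)) return(msgs)
  if (object@n_tet < 1) msgs <- c(msgs, "'n_tet' must be >= 1")
  for (s in c("leak_tet", "leak_bad"))
    if (slot(object, s) > 1) msgs <- c(msgs, sprintf("'%s' must be in [0, 1]", s))
  for (s in c("c_switch", "c_int", "dna_um", "K_tet", "K_rdf"))
    if (slot(object, s) <= 0) msgs <- c(msgs, sprintf("'%s' must be > 0", s))
  for (s in c("tetr_circuit_enabled", "dead_end_pb"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msgs <- c(msgs, sprintf("'%s' must be TRUE or FALSE", s))
  if (length(msgs)) msgs else TRUE
})

#' PulseProtocol: timed square pulses of inducer
#'
#' @slot pulses data.frame with columns \code{start}, \code{duration} (hours)
#'   and \code{inducer} (character).  Pulses of the same inducer must not
#'   overlap and must end before \code{horizon}.
#' @slot horizon total simulated time (h).
#' @seealso \code{\link{pulseProtocol}}, \code{\link{arabinoseInput}}
#' @export
setClass("PulseProtocol",
         representation(pulses = "data.frame", horizon = "numeric"))

setValidity("PulseProtocol", function(object) {
  p <- object@pulses
  if (!all(c("start", "duration", "inducer") %in% names(p)))
    return("pulses must have columns start, duration, inducer")
  if (length(object@horizon) != 1L || !is.finite(object@horizon) ||
      object@horizon <= 0)
    return("horizon must be a single positive number")
  if (nrow(p)) {
    if (any(p$start < 0)) return("pulse start times must be >= 0")
    if (any(p$duration <= 0)) return("pulse durations must be > 0")
    if (any(p$start + p$duration > object@horizon))
      return("all pulses must end before the horizon")
    for (ind in unique(p$inducer)) {
      q <- p[p$inducer == ind, , drop = FALSE]
      q <- q[order(q$start), , drop = FALSE]
      if (nrow(q) > 1L &&
          any(q$start[-1L] < (q$start + q$duration)[-nrow(q)]))
        return(sprintf("pulses overlap for inducer '%s'", ind))
    }
  }
  TRUE
})

#' ReactionNetwork: species, stoichiometry and rate laws of the latch model
#'
#' @slot species character vector of species names (mRNAs; integrase monomer,
#'   dimer and dimer:RDF complex; free RDF; TetR; switch DNA in PB, LR and the
#'   two synaptic-complex configurations).
#' @slot stoich species x reaction stoichiometry matrix.  DNA rows are
#'   integer; protein rows of the synapse reactions are scaled by
#'   \code{dna_um} because DNA is in AU while proteins are in µM.
#' @slot reactions character vector of reaction names (matrix columns).
#' @slot rateFun function(t, state, ara) returning the vector of reaction
#'   rates, all >= 0 for non-negative states.
#' @slot params the \linkS4class{LatchParams} the network was built from.
#' @seealso \code{\link{buildNetwork}}
#' @export
setClass("ReactionNetwork", representation(
  species = "character", stoich = "matrix", reactions = "character",
  rateFun = "function", params = "LatchParams"))

setValidity("ReactionNetwork", function(object) {
  if (!identical(rownames(object@stoich), object@species))
    return("stoichiometry rows must be named by species")
  if (!identical(colnames(object@stoich), object@reactions))
    return("stoichiometry columns must be named by reactions")
  dna <- dnaSpecies(object)
  if (!all(dna %in% object@species))
    return("network lacks the switch DNA species")
  cons <- as.numeric(object@species %in% dna)
  if (max(abs(drop(cons %*% object@stoich))) > 1e-12)
    return("total switch DNA is not conserved by the stoichiometry")
  TRUE
})

#' LatchTrajectory: an integrated time course of the latch model
#'
#' @slot times strictly increasing time grid (h).
#' @slot states matrix (time x species); proteins/mRNA in µM, DNA in AU.
#' @slot network the \linkS4class{ReactionNetwork} integrated.
#' @slot protocol the \linkS4class{PulseProtocol} applied.
#' @seealso \code{\link{simulateLatch}}, \code{\link{fractionLR}}
#' @export
setClass("LatchTrajectory", representation(
  times = "numeric", states = "matrix",
  network = "ReactionNetwork", protocol = "PulseProtocol"))

setValidity("LatchTrajectory", function(object) {
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    return("states must have one row per time point")
  if (min(object@states) < -1e-9)
    return("states fall below the non-negativity tolerance")
  TRUE
})

#' ToggleParams: per-pulse transition probabilities of the two-state model
#'
#' @slot p probability that a PB-state cell switches to LR at a pulse.
#' @slot q probability that an LR-state cell switches to PB at a pulse.
#' @seealso \code{\link{toggleParams}}, \code{\link{stepFraction}}
#' @export
setClass("ToggleParams", representation(p = "numeric", q = "numeric"))

setValidity("ToggleParams", function(object) {
  for (s in c("p", "q")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      return(sprintf("'%s' must be a probability in [0, 1]", s))
  }
  TRUE
})

#' CounterState: the bit vector of an N-latch ripple counter
#'
#' Bits are stored units-first (index 1 = the units latch); the represented
#' value is \code{sum(bits * 2^(0:(N-1)))}.
#'
#' @slot bits integer vector of 0/1 digits, units first.
#' @seealso \code{\link{counterState}}, \code{\link{rippleCount}}
#' @export
setClass("CounterState", representation(bits = "integer"))

setValidity("CounterState", function(object) {
  if (!length(object@bits)) return("counter needs at least one latch")
  if (anyNA(object@bits) || !all(object@bits %in% c(0L, 1L)))
    return("bits must all be 0 or 1")
  TRUE
})

#' CellPopulation: per-cell plasmid composition and GFP content
#'
#' @slot cells data.frame with integer columns \code{n_pb}, \code{n_lr} and
#'   numeric \code{gfp}; every cell carries \code{n_pb + n_lr} equal to the
#'   configured plasmid copy number.
#' @slot generation non-negative integer generation index.
#' @slot copy_number plasmid copies per cell (default 20).
#' @seealso \code{\link{cellPopulation}}, \code{\link{simulatePopulation}}
#' @export
setClass("CellPopulation", representation(
  cells = "data.frame", generation = "integer", copy_number = "integer"))

setValidity("CellPopulation", function(object) {
  c0 <- object@cells
  if (!nrow(c0)) return("population must be non-empty")
  if (!all(c("n_pb", "n_lr", "gfp") %in% names(c0)))
    return("cells must have columns n_pb, n_lr, gfp")
  if (any(c0$n_pb < 0) || any(c0$n_lr < 0) || any(c0$gfp < 0))
    return("cell contents must be non-negative")
  if (any(c0$n_pb + c0$n_lr != object@copy_number))
    return("every cell must carry exactly copy_number plasmids")
  if (object@generation < 0L) return("generation must be >= 0")
  TRUE
})

#' SegregationConfig: settings of the stochastic segregation simulation
#'
#' @slot n_cells population size (default 3000).
#' @slot copy_number plasmid copies per cell (default 20).
#' @slot init_lr LR copies per cell at generation 0.
#' @slot generations number of division rounds to simulate.
#' @slot gfp_rate GFP produced per LR copy per generation; the default
#'   1/(2*copy_number) normalises a pure-LR lineage's steady state to 1.
#' @slot partition \code{"hypergeometric"} (duplicate to 2n, draw exactly n
#'   without replacement; copy number fixed), or the \code{"binomial"} and
#'   \code{"random_replication"} variants for sensitivity analysis (see
#'   \code{\link{divideCell}}).
#' @slot seed RNG seed recorded with all outputs.
#' @seealso \code{\link{segregationConfig}}
#' @export
setClass("SegregationConfig", representation(
  n_cells = "integer", copy_number = "integer", init_lr = "integer",
  generations = "integer", gfp_rate = "numeric", partition = "character",
  seed = "integer"))

setValidity("SegregationConfig", function(object) {
  if (object@n_cells < 1L) return("n_cells must be >= 1")
  if (object@copy_number < 1L) return("copy_number must be >= 1")
  if (object@init_lr < 0L || object@init_lr > object@copy_number)
    return("init_lr must be between 0 and copy_number")
  if (object@generations < 0L) return("generations must be >= 0")
  if (object@gfp_rate < 0) return("gfp_rate must be >= 0")
  if (!object@partition %in%
        c("hypergeometric", "binomial", "random_replication"))
    return("partition must be 'hypergeometric', 'binomial' or 'random_replication'")
  TRUE
})

#' SegregationRun: generation-indexed output of the segregation model
#'
#' @slot config the \linkS4class{SegregationConfig} used.
#' @slot summary data.frame (generation, frac_pb_only, frac_mixed,
#'   frac_lr_only, mean_lr_fraction, mean_gfp).
#' @slot n_lr_history integer matrix (generation+1 x n_cells) of LR copies.
#' @slot gfp_history numeric matrix of per-cell GFP, same shape.
#' @seealso \code{\link{simulatePopulation}}, \code{\link{populationAt}}
#' @export
setClass("SegregationRun", representation(
  config = "SegregationConfig", summary = "data.frame",
  n_lr_history = "matrix", gfp_history = "matrix"))

#' TimeCourseData: observed fraction-LR versus time
#'
#' @slot times strictly increasing sampling times (h).
#' @slot fraction_lr observed LR fractions in [0, 1].
#' @slot protocol the \linkS4class{PulseProtocol} under which the course was
#'   (or is assumed to have been) acquired.
#' @slot init_state \code{"PB"} or \code{"LR"}: the pre-pulse steady state.
#' @slot noise_sd assumed observation noise (fraction units).
#' @slot meta list of provenance (true parameters, seed) for synthetic data.
#' @seealso \code{\link{timeCourseData}}, \code{\link{genTimecourse}}
#' @export
setClass("TimeCourseData", representation(
  times = "numeric", fraction_lr = "numeric", protocol = "PulseProtocol",
  init_state = "character", noise_sd = "numeric", meta = "list"))

setValidity("TimeCourseData", function(object) {
  if (length(object@times) != length(object@fraction_lr))
    return("times and fraction_lr must have equal length")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (any(object@fraction_lr < 0) || any(object@fraction_lr > 1))
    return("fraction_lr must lie in [0, 1]")
  if (!object@init_state %in% c("PB", "LR"))
    return("init_state must be 'PB' or 'LR'")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  TRUE
})

#' FitResult: fitted production rates with diagnostics
#'
#' @slot estimates named numeric vector of fitted lumped production rates.
#' @slot loss final sum of squared residuals.
#' @slot n_iter total objective evaluations across restarts.
#' @slot converged logical; at least one restart converged.
#' @slot seed integer seed the multi-start draw used.
#' @slot starts data.frame of per-restart results (start, loss, convergence).
#' @seealso \code{\link{fitProductionRates}}
#' @export
setClass("FitResult", representation(
  estimates = "numeric", loss = "numeric", n_iter = "integer",
  converged = "logical", seed = "integer", starts = "data.frame"))

setValidity("FitResult", function(object) {
  if (object@loss < 0) return("loss must be >= 0")
  if (is.null(names(object@estimates))) return("estimates must be named")
  TRUE
})

#' NoiseModel: observation-noise settings for the synthetic generators
#'
#' @slot timecourse_sd Gaussian sd on fraction-LR observations, truncated to
#'   [0, 1] (default 0.03).
#' @slot cytometry_cv per-event multiplicative log-normal coefficient of
#'   variation (default 0.25), mean-corrected to 1.
#' @slot baseline autofluorescence added to each cell's GFP before the
#'   multiplicative noise (arbitrary units, default 0.01).
#' @seealso \code{\link{noiseModel}}
#' @export
setClass("NoiseModel", representation(
  timecourse_sd = "numeric", cytometry_cv = "numeric", baseline = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@timecourse_sd < 0) return("timecourse_sd must be >= 0")
  if (object@cytometry_cv < 0) return("cytometry_cv must be >= 0")
  if (object@baseline < 0) return("baseline must be >= 0")
  TRUE
})
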