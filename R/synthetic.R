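## Synthetic observation generators.  These stand in for the wet-lab
## readouts the models were developed against: gel-quantified %LR time
## courses, and 30 000-event flow-cytometry GFP acquisitions.  All are pure
## functions of (inputs, seed).

#' Construct an observation-noise model
#'
#' @param timecourse_sd Gaussian sd on fraction-LR observations (default
#'   0.03, approximating gel densitometry variation), truncated to [0, 1].
#' @param cytometry_cv per-event multiplicative log-normal CV (default 0.25,
#'   chosen so pure-state gates are well separated), mean-corrected to 1.
#' @param baseline cell autofluorescence (AU, default 0.01).
#' @return a validated \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(timecourse_sd = 0.03, cytometry_cv = 0.25,
                       baseline = 0.01) {
  new("NoiseModel", timecourse_sd = as.numeric(timecourse_sd),
      cytometry_cv = as.numeric(cytometry_cv),
      baseline = as.numeric(baseline))
}

#' @describeIn noiseModel display
#' @param object a \linkS4class{NoiseModel}.
#' @export
setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: timecourse sd %.3g, cytometry cv %.3g, baseline %.3g\n",
    object@timecourse_sd, object@cytometry_cv, object@baseline))
})

#' Generate a noisy fraction-LR time course from the ODE model
#'
#' Simulates the latch under the given protocol, samples the model LR
#' fraction at the requested times and adds truncated Gaussian observation
#' noise.  The true parameters and seed are recorded in the metadata.
#'
#' @param base a \linkS4class{LatchParams} (the generating truth).
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param times sampling times within the protocol horizon.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed RNG seed.
#' @param init_state \code{"PB"} or \code{"LR"} pre-pulse state.
#' @return a \linkS4class{TimeCourseData}.
#' @examples
#' tc <- genTimecourse(latchParams(), pulseProtocol(0.5, 0.2, horizon = 6),
#'                     times = 1:5, noise = noiseModel(0), seed = 1)
#' @export
genTimecourse <- function(base, protocol, times, noise = noiseModel(),
                          seed = 1L, init_state = "PB") {
  stopifnot(is(base, "LatchParams"), is(protocol, "PulseProtocol"),
            is(noise, "NoiseModel"))
  d0 <- timeCourseData(times, rep(0, length(times)), protocol,
                       init_state = init_state,
                       noise_sd = noise@timecourse_sd)
  truth <- predictFractionLR(base, d0, rtol = 1e-8, atol = 1e-10)
  set.seed(childSeed(seed, "timecourse"))
  obs <- truth + rnorm(length(truth), 0, noise@timecourse_sd)
  obs <- pmin(pmax(obs, 0), 1)
  timeCourseData(times, obs, protocol, init_state = init_state,
                 noise_sd = noise@timecourse_sd,
                 meta = list(true_fraction_lr = truth,
                             true_rates = lumpedProductionRates(base),
                             seed = seed))
}

#' Generate flow-cytometry-like fluorescence events from a population
#'
#' Samples \code{n_events} cells with replacement and multiplies each cell's
#' GFP (plus the autofluorescence baseline) by mean-1 log-normal measurement
#' noise, emulating a cytometer acquisition (default 30 000 events).
#' Population mean fluorescence is preserved in expectation for any CV.
#'
#' @param pop a non-empty \linkS4class{CellPopulation}.
#' @param n_events number of events (default 30000).
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed RNG seed.
#' @return numeric vector of event fluorescences.
#' @export
genFlowEvents <- function(pop, n_events = 30000L, noise = noiseModel(),
                          seed = 1L) {
  stopifnot(is(pop, "CellPopulation"), is(noise, "NoiseModel"))
  if (n_events < 1) stop("n_events must be >= 1")
  if (!nrow(pop@cells)) stop("population is empty")
  set.seed(childSeed(seed, "cytometry"))
  idx <- sample.int(nrow(pop@cells), n_events, replace = TRUE)
  g <- pop@cells$gfp[idx] + noise@baseline
  if (noise@cytometry_cv > 0) {
    sdlog <- sqrt(log1p(noise@cytometry_cv^2))
    g <- g * rlnorm(n_events, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  g
}

#' Discrete-molecule gel readout of a true LR fraction
#'
#' Binomial counterpart of band quantification: draws the number of LR
#' molecules among \code{n_molecules} at the true fraction and reports the
#' observed proportion, an unbiased estimator supported on
#' \code{{0, 1/n, ..., 1}}.
#'
#' @param true_fraction_lr true fraction in [0, 1].
#' @param n_molecules molecules quantified (>= 1).
#' @param seed RNG seed.
#' @return observed fraction.
#' @examples
#' genGelReadout(0.8, 20, seed = 1)
#' @export
genGelReadout <- function(true_fraction_lr, n_molecules, seed = 1L) {
  assertScalar(true_fraction_lr, "true_fraction_lr", upper = 1)
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  set.seed(childSeed(seed, "gel"))
  rbinom(1L, size = as.integer(n_molecules),
         prob = true_fraction_lr) / n_molecules
}
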