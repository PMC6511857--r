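## Stochastic plasmid segregation: plasmids replicate (counts double), then
## each daughter draws exactly copy_number copies without replacement
## (hypergeometric partition), so the copy number stays fixed.  One random
## daughter per cell is tracked, keeping the population size constant; the
## marginal law of a random daughter equals the population law, so all
## reported fractions are unbiased.

#' Construct a cell population
#'
#' @param n_cells number of cells.
#' @param n_lr LR plasmid copies per cell (scalar or length \code{n_cells}).
#' @param copy_number total plasmid copies per cell (default 20, the
#'   maintained copy number of the switch plasmid in fast-growing cells).
#' @param gfp initial GFP content per cell (default 0).
#' @param generation generation index (default 0).
#' @return a validated \linkS4class{CellPopulation}.
#' @examples
#' cellPopulation(3000, n_lr = 4)   # 16 PB + 4 LR copies each
#' @export
cellPopulation <- function(n_cells, n_lr, copy_number = 20L, gfp = 0,
                           generation = 0L) {
  n_lr <- as.integer(rep_len(n_lr, n_cells))
  gfp <- rep_len(as.numeric(gfp), n_cells)
  new("CellPopulation",
      cells = data.frame(n_pb = as.integer(copy_number) - n_lr,
                         n_lr = n_lr, gfp = gfp),
      generation = as.integer(generation),
      copy_number = as.integer(copy_number))
}

#' @describeIn cellPopulation the per-cell data.frame
#' @param object a \linkS4class{CellPopulation}.
#' @export
setMethod("populationCells", "CellPopulation", function(object) object@cells)

#' @describeIn cellPopulation display a population
#' @export
setMethod("show", "CellPopulation", function(object) {
  fx <- fixationSummary(object)
  cat(sprintf(paste0(
    "CellPopulation: %d cells, %d plasmid copies each, generation %d\n",
    "  PB-only %.1f%%, mixed %.1f%%, LR-only %.1f%%; mean LR fraction %.3f\n"),
    nrow(object@cells), object@copy_number, object@generation,
    100 * fx[["frac_pb_only"]], 100 * fx[["frac_mixed"]],
    100 * fx[["frac_lr_only"]],
    mean(object@cells$n_lr) / object@copy_number))
})

#' Deterministic recombination of a cell's plasmid copies
#'
#' Worked-arithmetic helper: converts a fraction of a cell's plasmids to the
#' other state, rounding to whole copies (80\% recombination of a 20-copy
#' cell in the LR state yields 16 PB and 4 LR copies).
#'
#' @param copy_number total plasmid copies (default 20).
#' @param fraction fraction recombined, in [0, 1].
#' @param from state the copies recombine away from, \code{"LR"} or
#'   \code{"PB"}.
#' @return named integer vector \code{c(n_pb=, n_lr=)}.
#' @examples
#' recombineCopies(20, 0.8, from = "LR")   # 16 PB, 4 LR
#' @export
recombineCopies <- function(copy_number = 20L, fraction, from = c("LR", "PB")) {
  from <- match.arg(from)
  assertScalar(fraction, "fraction", upper = 1)
  moved <- as.integer(round(copy_number * fraction))
  if (from == "LR") c(n_pb = moved, n_lr = as.integer(copy_number) - moved)
  else c(n_pb = as.integer(copy_number) - moved, n_lr = moved)
}

#' One cell division: replicate, partition, halve GFP
#'
#' Every plasmid is duplicated, then the tracked daughter draws exactly
#' \code{copy_number} copies without replacement from the \code{2 *
#' copy_number} pool (hypergeometric partition; a binomial variant is
#' available for sensitivity analysis).  The daughter inherits half the GFP
#' content of its mother.  Vectorised over cells.
#'
#' @param n_lr integer vector of LR copies per mother cell.
#' @param gfp numeric vector of mother GFP contents.
#' @param copy_number plasmid copies per cell.
#' @param partition \code{"hypergeometric"} (the default replication rule:
#'   every plasmid duplicated exactly once), \code{"binomial"} (independent
#'   coin-flip partition, truncated to the copy number), or
#'   \code{"random_replication"} (copy_number sequential duplications each
#'   picking a plasmid uniformly from the growing pool — the classical
#'   higher-variance model of relaxed plasmid replication — followed by the
#'   hypergeometric partition).
#' @return list with \code{n_lr} and \code{gfp} of the daughters (GFP before
#'   any new production; see \code{\link{gfpStep}}).
#' @examples
#' set.seed(1)
#' divideCell(n_lr = 4, gfp = 10, copy_number = 20)
#' @export
divideCell <- function(n_lr, gfp = 0, copy_number = 20L,
                       partition = "hypergeometric") {
  n <- length(n_lr)
  stopifnot(all(n_lr >= 0), all(n_lr <= copy_number))
  gfp <- rep_len(gfp, n)
  cn <- as.integer(copy_number)
  d_lr <- switch(partition,
    hypergeometric = rhyper(n, m = 2L * n_lr,
                            n = 2L * (cn - n_lr), k = cn),
    binomial = pmin(rbinom(n, size = 2L * n_lr, prob = 0.5), cn),
    random_replication = {
      lr <- as.integer(n_lr); tot <- rep.int(cn, n)
      for (k in seq_len(cn)) {          # pool grows cn -> 2*cn
        dup <- runif(n) < lr / tot
        lr <- lr + dup; tot <- tot + 1L
      }
      rhyper(n, m = lr, n = 2L * cn - lr, k = cn)
    },
    stop("partition must be 'hypergeometric', 'binomial' or ",
         "'random_replication'"))
  list(n_lr = as.integer(d_lr), gfp = gfp / 2)
}

#' GFP production over one generation
#'
#' Each cell produces GFP at a rate proportional to its LR copy number:
#' \code{gfp + gfp_rate * n_lr} after one generation.  Under the halving at
#' division, a pure-LR lineage converges to the geometric-series fixed point
#' \code{2 * copy_number * gfp_rate}.
#'
#' @param n_lr LR copies per cell.
#' @param gfp current GFP content.
#' @param gfp_rate GFP per LR copy per generation (>= 0).
#' @return updated GFP vector.
#' @export
gfpStep <- function(n_lr, gfp, gfp_rate) {
  if (any(gfp_rate < 0)) stop("gfp_rate must be >= 0")
  gfp + gfp_rate * n_lr
}

#' Construct a segregation-simulation configuration
#'
#' Defaults mirror the study conditions: 3000 cells, 20 plasmid copies per
#' cell, 4 of them LR (the composition left by an 80\% LR->PB conversion),
#' 70 generations, hypergeometric partition, and a GFP rate normalising the
#' pure-LR steady state to 1.
#'
#' @param n_cells,copy_number,init_lr,generations,gfp_rate,partition,seed
#'   see \linkS4class{SegregationConfig}.
#' @return a validated \linkS4class{SegregationConfig}.
#' @export
segregationConfig <- function(n_cells = 3000L, copy_number = 20L,
                              init_lr = 4L, generations = 70L,
                              gfp_rate = 1 / (2 * copy_number),
                              partition = "hypergeometric", seed = 1L) {
  new("SegregationConfig", n_cells = as.integer(n_cells),
      copy_number = as.integer(copy_number), init_lr = as.integer(init_lr),
      generations = as.integer(generations), gfp_rate = as.numeric(gfp_rate),
      partition = partition, seed = as.integer(seed))
}

#' Simulate plasmid segregation over many generations
#'
#' Runs the division/partition/GFP model for \code{generations} rounds from
#' a homogeneous starting population, tracking one random daughter per cell
#' (constant population size).  Fully reproducible from the configured seed.
#'
#' @param config a \linkS4class{SegregationConfig}.
#' @return a \linkS4class{SegregationRun}.
#' @examples
#' run <- simulatePopulation(segregationConfig(n_cells = 300,
#'                                             generations = 10))
#' tail(run@summary)
#' @export
simulatePopulation <- function(config) {
  stopifnot(is(config, "SegregationConfig"))
  validObject(config)
  set.seed(config@seed)
  cn <- config@copy_number
  nG <- config@generations
  n_lr <- rep.int(as.integer(config@init_lr), config@n_cells)
  # start at the GFP level a steady mixed lineage would carry
  gfp <- rep.int(2 * config@gfp_rate * config@init_lr, config@n_cells)
  lrH <- matrix(0L, nG + 1L, config@n_cells)
  gfH <- matrix(0, nG + 1L, config@n_cells)
  lrH[1L, ] <- n_lr; gfH[1L, ] <- gfp
  for (g in seq_len(nG)) {
    d <- divideCell(n_lr, gfp, cn, config@partition)
    n_lr <- d$n_lr
    gfp <- gfpStep(n_lr, d$gfp, config@gfp_rate)
    lrH[g + 1L, ] <- n_lr
    gfH[g + 1L, ] <- gfp
  }
  summ <- data.frame(
    generation = 0:nG,
    frac_pb_only = rowMeans(lrH == 0L),
    frac_mixed = rowMeans(lrH > 0L & lrH < cn),
    frac_lr_only = rowMeans(lrH == cn),
    mean_lr_fraction = rowMeans(lrH) / cn,
    mean_gfp = rowMeans(gfH))
  new("SegregationRun", config = config, summary = summ,
      n_lr_history = lrH, gfp_history = gfH)
}

#' Extract the population at a given generation of a run
#'
#' @param run a \linkS4class{SegregationRun}.
#' @param generation generation index in \code{0:generations}.
#' @return a \linkS4class{CellPopulation}.
#' @export
populationAt <- function(run, generation) {
  stopifnot(is(run, "SegregationRun"))
  g <- as.integer(generation)
  if (g < 0L || g > run@config@generations)
    stop("generation outside the simulated range")
  cellPopulation(run@config@n_cells, run@n_lr_history[g + 1L, ],
                 copy_number = run@config@copy_number,
                 gfp = run@gfp_history[g + 1L, ], generation = g)
}

#' @describeIn simulatePopulation display a run
#' @param object a \linkS4class{SegregationRun}.
#' @export
setMethod("show", "SegregationRun", function(object) {
  s <- object@summary
  last <- s[nrow(s), ]
  cat(sprintf(paste0(
    "SegregationRun: %d cells, %d generations (seed %d, %s partition)\n",
    "  final: PB-only %.1f%%, mixed %.1f%%, LR-only %.1f%%\n"),
    object@config@n_cells, object@config@generations, object@config@seed,
    object@config@partition, 100 * last$frac_pb_only,
    100 * last$frac_mixed, 100 * last$frac_lr_only))
})

#' Fractions of pure and mixed cells in a population
#'
#' @param pop a \linkS4class{CellPopulation}.
#' @return named numeric vector (frac_pb_only, frac_mixed, frac_lr_only)
#'   summing to 1; a cell is PB-only iff it has zero LR copies and LR-only
#'   iff it has zero PB copies.
#' @export
fixationSummary <- function(pop) {
  stopifnot(is(pop, "CellPopulation"))
  n_lr <- pop@cells$n_lr
  cn <- pop@copy_number
  c(frac_pb_only = mean(n_lr == 0L),
    frac_mixed = mean(n_lr > 0L & n_lr < cn),
    frac_lr_only = mean(n_lr == cn))
}

#' Gate fluorescence events into low/intermediate/high bins
#'
#' Partitions events by two strictly increasing cutoffs using half-open
#' intervals \code{[lo, hi)}: an event exactly at a cutoff is assigned to
#' the upper bin.
#'
#' @param events numeric vector of fluorescence values.
#' @param thresholds two strictly increasing cutoffs.
#' @return named fractions (low, intermediate, high) summing to 1.
#' @examples
#' gateFluorescence(c(0.01, 0.2, 0.9), thresholds = c(0.05, 0.5))
#' @export
gateFluorescence <- function(events, thresholds) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two strictly increasing cutoffs")
  if (!length(events)) stop("no events to gate")
  bin <- findInterval(events, thresholds)   # [lo, hi) bins
  c(low = mean(bin == 0L), intermediate = mean(bin == 1L),
    high = mean(bin == 2L))
}

#' Default gating thresholds from pure-state controls
#'
#' The low/intermediate cutoff is the 99.9th percentile of a pure-PB
#' population's event distribution and the intermediate/high cutoff the
#' 0.1st percentile of a pure-LR population's, both computed in closed form
#' from the log-normal event model of \code{\link{genFlowEvents}} (pure-PB
#' cells carry only the autofluorescence baseline; pure-LR cells sit at the
#' GFP steady state \code{2 * copy_number * gfp_rate}).
#'
#' @param config a \linkS4class{SegregationConfig} (for the GFP steady state).
#' @param noise a \linkS4class{NoiseModel}.
#' @return two increasing thresholds.
#' @export
defaultGates <- function(config = segregationConfig(),
                         noise = noiseModel()) {
  stopifnot(is(config, "SegregationConfig"), is(noise, "NoiseModel"))
  sdlog <- sqrt(log1p(noise@cytometry_cv^2))
  mulog <- -sdlog^2 / 2
  gfp_lr <- 2 * config@copy_number * config@gfp_rate
  lo <- noise@baseline * qlnorm(0.999, mulog, sdlog)
  hi <- (gfp_lr + noise@baseline) * qlnorm(0.001, mulog, sdlog)
  if (hi <= lo)
    stop("pure-state controls do not separate; increase gfp_rate or reduce cv")
  c(lo, hi)
}
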