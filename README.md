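# latchSim

Models of a single-input **binary latch** built from phiC31 integrase and its
recombination directionality factor (RDF), for synthetic biologists studying
recombinase memory and counting circuits.

An invertible DNA segment flanked by integrase attachment sites stores one
bit: orientation **PB** (attP/attB, read as 0) or **LR** (attL/attR, read
as 1). Integrase alone converts PB→LR; integrase plus stoichiometric RDF
converts LR→PB. Wiring RDF expression to the LR state — behind a TetR delay
circuit expressed only in the PB state — makes a single repeated input
toggle the bit, and N such latches chained by 1→0 carries form a binary
ripple counter that counts to 2^N − 1.

The package implements, as tested S4 classes and functions:

* **`buildNetwork()` / `simulateLatch()`** — deterministic mass-action ODEs
  of pulsed integrase expression, state-dependent RDF expression under TetR
  repression, dimerisation, dimer:RDF complexation and directional
  synapsis/recombination (stiff `lsoda` integration, exact DNA
  conservation); `runCycles()` and `pulseScan()` for repeated operation.
* **`simulatePopulation()`** — stochastic plasmid replication and random
  partition at division (20 copies/cell), GFP production/dilution, and
  flow-cytometry-style gating (`genFlowEvents()`, `gateFluorescence()`).
* **`stepFraction()` / `stationaryFraction()` /
  `switchFractionAtStationarity()` / `rippleCount()`** — the per-pulse
  two-state model `f' = p(1−f) + (1−q)f` and the N-latch ripple counter.
* **`fitProductionRates()`** — multi-start, bounded, derivative-free
  least-squares recovery of the lumped integrase/RDF/TetR production rates
  from fraction-LR time courses.
* **`genTimecourse()` / `genGelReadout()` / `noiseModel()`** — synthetic
  observation generators with seeded, reproducible noise.

A thin command-line wrapper over these functions ships in
`inst/scripts/latchsim.R` (subcommands `ode`, `segregate`, `toggle`,
`ripple`, `fit`, `synth`); YAML configuration parsing (`parseLatchConfig()`)
is fail-closed. The methods vignette
(`vignettes/latch-modelling.Rmd`) documents the model equations, parameter
calibration and design choices.

## Worked example

```r
library(latchSim)

## a single 12-min arabinose pulse at 0.5 h flips the latch from PB to LR
net  <- buildNetwork(latchParams())
traj <- simulateLatch(net, pulseProtocol(0.5, 0.2, horizon = 24))
traj
#> LatchTrajectory: 481 points over [0, 24] h; final LR fraction 0.953

## daily pulses toggle it back and forth
rc <- runCycles(net, n_pulses = 4, pulse_len = 0.2, spacing = 24)
round(rc$cycles$fraction_lr, 3)
#> [1] 0.953 0.085 0.950 0.111

## the per-pulse two-state model at the observed efficiencies
tp <- toggleParams(p = 0.95, q = 0.85)
stationaryFraction(tp)                          # steady state ~52.8% LR
#> [1] 0.5277778
100 * as.numeric(switchFractionAtStationarity(tp))   # ~90% flip per pulse
#> [1] 89.72222

## plasmid segregation from 16 PB + 4 LR copies per cell
run <- simulatePopulation(segregationConfig(seed = 1))
run
#> SegregationRun: 3000 cells, 70 generations (seed 1, hypergeometric partition)
#>   final: PB-only 72.3%, mixed 14.8%, LR-only 12.9%
```

The first block shows the delay circuit doing its job: one short pulse
converts >95% of the DNA, and repeated pulses alternate between
mostly-LR and mostly-PB states. The toggle numbers say that at
stationarity the population composition is static (~53% LR) while ~90% of
individual cells change state at every signal. The segregation run shows
mixed-state cells resolving toward the pure absorbing states at the
no-selection (martingale) ratio set by the initial 20% LR fraction.

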