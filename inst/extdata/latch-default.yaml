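# Default latch configuration: calibrated parameters, a single 12-min
# arabinose pulse at 0.5 h, and the stiff-solver tolerances.
params:
  k_tx_int: 0.12
  k_tx_rdf: 0.05
  k_tx_tetr: 0.05
  tetr_circuit_enabled: true
protocol:
  starts: [0.5]
  durations: [0.2]
  horizon: 24.0
  inducer: ara
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
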