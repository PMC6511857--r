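test_that("with no dynamics the all-PB state is constant", {
  net <- buildNetwork(inertParams(k_syn_on = 0, k_dim = 0))
  init <- stateWith(net, dna_pb = 1)
  tr <- simulateLatch(net, pulse12min(horizon = 10),
                      times = seq(0, 10, by = 0.5), init = init)
  expect_equal(max(abs(stateMatrix(tr)[, "dna_pb"] - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fractionLR(tr))), 0, tolerance = 1e-9)
})

test_that("trajectories conserve DNA and stay non-negative in both directions", {
  net <- defaultNet()
  for (state in c("PB", "LR")) {
    tr <- simulateLatch(net, pulse12min(), init = steadyInit(net, state))
    st <- stateMatrix(tr)
    dna <- rowSums(st[, dnaSpecies(net)])
    expect_lt(max(abs(dna - 1)), 1e-6)
    expect_gt(min(st), -1e-9)
    f <- fractionLR(tr)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("a 12-min pulse with the TetR delay flips PB to LR; without TetR it stalls", {
  netT <- defaultNet()
  netN <- defaultNet(tetr_circuit_enabled = FALSE)
  trT <- simulateLatch(netT, pulse12min(), init = steadyInit(netT, "PB"))
  trN <- simulateLatch(netN, pulse12min(), init = steadyInit(netN, "PB"))
  fT <- fractionLR(trT, 24)
  fN <- fractionLR(trN, 24)
  expect_gt(fT, fN)          # the delay circuit rescues the transition
  expect_gt(fT, 0.9)
  expect_lt(fN, 0.5)         # RDF negative feedback stalls conversion
  # TetR decays after switching while RDF rises late (delay-circuit shape)
  st <- stateMatrix(trT); tt <- trajectoryTimes(trT)
  tet_peak <- max(st[, "tetr"])
  expect_lt(st[nrow(st), "tetr"], 0.1 * tet_peak)
  expect_gt(st[nrow(st), "rdf"], st[which.min(abs(tt - 1)), "rdf"])
})

test_that("RDF persists through the LR->PB pulse and decays afterwards", {
  net <- defaultNet()
  tr <- simulateLatch(net, pulse12min(), init = steadyInit(net, "LR"))
  st <- stateMatrix(tr); tt <- trajectoryTimes(tr)
  rdf_pulse_end <- approx(tt, st[, "rdf"], 0.7)$y
  rdf_final <- st[nrow(st), "rdf"]
  expect_gt(rdf_pulse_end, 10 * rdf_final)
  expect_lt(fractionLR(tr, 24), 0.1)   # the transition completes
})

test_that("the stiff integrator matches fixed-step RK4 on a reduced linear network", {
  # reduced 3-species system: arabinose-driven integrase mRNA -> monomer,
  # all recombination and dimerisation off; independent RK4 oracle on a
  # hand-written right-hand side at small fixed step
  p <- latchParams(k_dim = 0, k_syn_on = 0, k_rdf_on = 0,
                   k_tx_rdf = 0, k_tx_tetr = 0)
  net <- buildNetwork(p)
  pp <- pulseProtocol(0, 2, horizon = 2)
  tr <- simulateLatch(net, pp, init = stateWith(net, dna_pb = 1),
                      times = seq(0, 2, by = 0.25))

  a <- p@k_tx_int * p@c_int; b <- p@d_mrna + p@mu
  kt <- p@k_tl_int; d <- p@d_int + p@mu
  rhs <- function(y) c(a - b * y[1], kt * y[1] - d * y[2])
  y <- c(0, 0); h <- 1e-4
  keep <- seq(0, 2, by = 0.25); out <- matrix(NA_real_, length(keep), 2)
  out[1, ] <- y; ti <- 0
  for (i in seq_len(2 / h)) {
    k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ti <- ti + h
    j <- which(abs(keep - ti) < h / 2)
    if (length(j)) out[j, ] <- y
  }
  got <- stateMatrix(tr)[, c("m_int", "int_mono")]
  expect_lt(max(abs(got[-1, ] - out[-1, ]) / pmax(out[-1, ], 1e-12)), 1e-5)
})

test_that("fractionLR reads pure states and respects the trajectory range", {
  net <- defaultNet()
  quiet <- pulseProtocol(numeric(0), numeric(0), horizon = 1)
  trP <- simulateLatch(net, quiet, init = steadyInit(net, "PB"),
                       times = c(0, 0.5, 1))
  trL <- simulateLatch(net, quiet, init = steadyInit(net, "LR"),
                       times = c(0, 0.5, 1))
  expect_equal(fractionLR(trP, 0), 0)
  expect_equal(fractionLR(trL, 0), 1)
  expect_error(fractionLR(trP, 2), "range")
})

test_that("multi-cycle runs integrate continuously and alternate states", {
  net <- defaultNet()
  rc <- runCycles(net, n_pulses = 4, pulse_len = 0.2, spacing = 24)
  f <- rc$cycles$fraction_lr
  expect_length(f, 4)
  expect_true(all(f[c(1, 3)] > 0.85))   # LR after odd pulses
  expect_true(all(f[c(2, 4)] < 0.2))    # PB after even pulses
  expect_error(runCycles(net, 2, pulse_len = 2, spacing = 1), "spacing")
})

test_that("overexpression of either arm traps the multi-cycle switch", {
  rcR <- runCycles(defaultNet(k_tx_rdf = 0.5), 6, 0.2, 24)   # 10x RDF
  rcT <- runCycles(defaultNet(k_tx_tetr = 0.5), 6, 0.2, 24)  # 10x TetR
  lastR <- tail(rcR$cycles$fraction_lr, 3)
  lastT <- tail(rcT$cycles$fraction_lr, 3)
  expect_lt(mean(lastR), 0.5)   # stuck mostly PB
  expect_gt(mean(lastT), 0.5)   # trapped in LR
})

test_that("pulse-length scans rise to a working plateau and show LR->PB reversal", {
  net <- defaultNet()
  lens <- c(0.005, 0.05, 0.1, 0.5, 2)
  fwd <- pulseScan(net, lens, "PBtoLR")$fraction_lr
  expect_lt(fwd[1], 0.05)                 # vanishing pulse: no recombination
  expect_true(all(diff(fwd[1:3]) > 0))    # rising to the plateau
  expect_gt(min(fwd[3:4]), 0.85)          # working range
  rev <- 1 - pulseScan(net, lens, "LRtoPB")$fraction_lr
  expect_lt(rev[1], 0.05)
  expect_gt(max(rev), 0.95)
  # completion collapses for pulses much longer than the RDF lifetime
  expect_lt(rev[5], rev[4] - 0.2)
})
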