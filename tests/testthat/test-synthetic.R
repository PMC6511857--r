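test_that("noise-free time courses reproduce the model exactly and round-trip to zero loss", {
  base <- latchParams()
  pp <- pulse12min(horizon = 6)
  tc <- genTimecourse(base, pp, times = c(1, 2, 4, 6), noise = noiseModel(0),
                      seed = 1)
  expect_equal(tc@fraction_lr, tc@meta$true_fraction_lr)
  expect_lt(timeCourseLoss(lumpedProductionRates(base), tc, base), 1e-8)
})

test_that("time-course noise is truncated to [0,1] and reproducible from the seed", {
  base <- latchParams()
  pp <- pulse12min(horizon = 6)
  tms <- seq(0.5, 6, by = 0.5)
  tc1 <- genTimecourse(base, pp, tms, noiseModel(timecourse_sd = 0.5), seed = 3)
  expect_true(all(tc1@fraction_lr >= 0 & tc1@fraction_lr <= 1))
  tc2 <- genTimecourse(base, pp, tms, noiseModel(timecourse_sd = 0.5), seed = 3)
  expect_identical(tc1@fraction_lr, tc2@fraction_lr)
  tc3 <- genTimecourse(base, pp, tms, noiseModel(timecourse_sd = 0.5), seed = 4)
  expect_false(identical(tc1@fraction_lr, tc3@fraction_lr))
})

test_that("flow events reduce to cell fluorescence at zero CV", {
  pop <- cellPopulation(1, n_lr = 20, gfp = 0.8)
  ev <- genFlowEvents(pop, 100, noiseModel(cytometry_cv = 0, baseline = 0.01))
  expect_true(all(ev == 0.81))
})

test_that("mean-1 log-normal noise preserves population mean fluorescence", {
  set.seed(1)
  pop <- cellPopulation(500, n_lr = rep(c(0L, 20L), 250),
                        gfp = rep(c(0, 1), 250))
  nm <- noiseModel(cytometry_cv = 0.4, baseline = 0.01)
  ev <- genFlowEvents(pop, 2e5, nm, seed = 6)
  truth <- mean(pop@cells$gfp) + nm@baseline
  expect_lt(abs(mean(ev) - truth) / truth, 0.02)
})

test_that("a fixated mixed population gates bimodally with an empty middle", {
  run <- simulatePopulation(segregationConfig(n_cells = 1500L,
                                              generations = 70L, seed = 2L))
  ev <- genFlowEvents(populationAt(run, 70), n_events = 30000, seed = 7)
  g <- gateFluorescence(ev, defaultGates())
  expect_lt(g[["intermediate"]], 0.12)
  expect_gt(g[["low"]], 0.5)
  expect_gt(g[["high"]], 0.05)
})

test_that("gel readouts are unbiased binomial draws on the molecule lattice", {
  expect_identical(genGelReadout(0, 20, seed = 1), 0)
  expect_identical(genGelReadout(1, 20, seed = 1), 1)
  obs <- vapply(1:200, function(s) genGelReadout(0.8, 20, seed = s),
                numeric(1))
  expect_true(all(obs %in% ((0:20) / 20)))
  se <- sqrt(0.8 * 0.2 / 20 / 200)
  expect_lt(abs(mean(obs) - 0.8), 3 * se)
})
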