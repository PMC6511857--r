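test_that("pure-PB mothers always yield pure-PB daughters", {
  set.seed(1)
  d <- divideCell(rep(0L, 500), gfp = 2, copy_number = 20)
  expect_true(all(d$n_lr == 0L))
  expect_equal(d$gfp, rep(1, 500))   # GFP halves at division
})

test_that("the hypergeometric partition matches a brute-force enumeration oracle", {
  # daughter LR copies from a (16 PB, 4 LR) mother: duplicate to (32, 8),
  # draw 20 of 40.  Oracle pmf from first-principles combinatorics.
  j <- 0:8
  pmf <- choose(8, j) * choose(32, 20 - j) / choose(40, 20)
  expect_equal(sum(pmf), 1)
  expect_equal(sum(j * pmf), 4)              # hypergeometric mean
  set.seed(99)
  draws <- divideCell(rep(4L, 40000), copy_number = 20)$n_lr
  expect_true(all(draws %in% 0:8))
  emp <- tabulate(draws + 1L, nbins = 9L) / 40000
  expect_lt(max(abs(emp - pmf)), 0.01)
  expect_lt(abs(mean(draws) - 4), 3 * sqrt(sum(j^2 * pmf) - 16) / sqrt(40000))
})

test_that("GFP production is proportional to LR copies with the geometric fixed point", {
  expect_equal(gfpStep(0, 5, 0.025), 5)
  expect_equal(gfpStep(20, 1, 0.025), 1.5)
  # pure-LR lineage: halve then produce -> fixed point 2 * 20 * rate
  g <- 0
  for (i in 1:60) g <- gfpStep(20, g / 2, 0.025)
  expect_equal(g, 2 * 20 * 0.025, tolerance = 1e-9)
})

test_that("worked arithmetic: 80% recombination of 20 copies leaves 16 PB / 4 LR", {
  expect_identical(recombineCopies(20, 0.8, from = "LR"),
                   c(n_pb = 16L, n_lr = 4L))
  expect_identical(recombineCopies(20, 0.8, from = "PB"),
                   c(n_pb = 4L, n_lr = 16L))
})

test_that("simulated populations keep copy number, absorb pure states, and reproduce from seed", {
  cfg <- segregationConfig(n_cells = 400L, generations = 30L, seed = 5L)
  run <- simulatePopulation(cfg)
  H <- run@n_lr_history
  expect_true(all(H >= 0L & H <= 20L))
  # absorbing states: a lineage at 0 (or 20) LR copies never leaves it
  for (cell in seq_len(ncol(H))) {
    z <- which(H[, cell] == 0L)
    if (length(z)) expect_true(all(H[z[1]:nrow(H), cell] == 0L))
    f <- which(H[, cell] == 20L)
    if (length(f)) expect_true(all(H[f[1]:nrow(H), cell] == 20L))
  }
  run2 <- simulatePopulation(cfg)
  expect_identical(run@n_lr_history, run2@n_lr_history)
  expect_identical(run@summary, run2@summary)
  # population containers agree with the run summary
  pop <- populationAt(run, 30)
  expect_equal(unname(fixationSummary(pop)["frac_pb_only"]),
               run@summary$frac_pb_only[31])
})

test_that("the population mean LR fraction is a martingale across seeds", {
  means <- vapply(1:10, function(s) {
    run <- simulatePopulation(segregationConfig(n_cells = 1000L,
                                                generations = 25L, seed = s))
    run@summary$mean_lr_fraction[26]
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.2), 3 * max(se, 1e-4))
})

test_that("asymptotic fixation fractions reflect the initial LR fraction", {
  # deep enough that essentially every lineage has fixed
  for (init in c(4L, 10L, 16L)) {
    lr_only <- vapply(1:5, function(s) {
      run <- simulatePopulation(segregationConfig(
        n_cells = 800L, init_lr = init, generations = 200L, seed = 10 + s))
      su <- run@summary[nrow(run@summary), ]
      expect_lt(su$frac_mixed, 0.03)
      su$frac_lr_only
    }, numeric(1))
    expect_lt(abs(mean(lr_only) - init / 20), 0.03)
  }
})

test_that("symmetric starts fix symmetrically", {
  res <- vapply(1:8, function(s) {
    run <- simulatePopulation(segregationConfig(
      n_cells = 1000L, init_lr = 10L, generations = 120L, seed = 100 + s))
    su <- run@summary[nrow(run@summary), ]
    c(su$frac_pb_only, su$frac_lr_only)
  }, numeric(2))
  diffs <- res[1, ] - res[2, ]
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 0.01)
})

test_that("partition variants stay on the copy-number lattice", {
  set.seed(3)
  for (part in c("binomial", "random_replication")) {
    d <- divideCell(rep(c(0L, 4L, 20L), each = 200), copy_number = 20,
                    partition = part)
    expect_true(all(d$n_lr >= 0L & d$n_lr <= 20L))
    # pure PB remains pure under every variant
    expect_true(all(d$n_lr[1:200] == 0L))
  }
})

test_that("fluorescence gating uses half-open bins and sums to one", {
  g <- gateFluorescence(c(0.01, 0.02, 0.3, 0.9), thresholds = c(0.05, 0.5))
  expect_equal(unname(g), c(0.5, 0.25, 0.25))
  expect_equal(sum(g), 1)
  # events exactly at a cutoff land in the upper bin
  g2 <- gateFluorescence(c(0.05, 0.5), thresholds = c(0.05, 0.5))
  expect_equal(unname(g2), c(0, 0.5, 0.5))
  expect_equal(unname(gateFluorescence(rep(0.001, 5), c(0.05, 0.5))),
               c(1, 0, 0))
  expect_error(gateFluorescence(1, thresholds = c(0.5, 0.5)), "increasing")
})

test_that("default gates separate the pure-state control populations", {
  th <- defaultGates()
  expect_lt(th[1], th[2])
  pb <- cellPopulation(200, n_lr = 0, gfp = 0)
  ev <- genFlowEvents(pb, n_events = 5000, seed = 2)
  g <- gateFluorescence(ev, th)
  expect_gt(g[["low"]], 0.995)
  lr <- cellPopulation(200, n_lr = 20, gfp = 1)
  g2 <- gateFluorescence(genFlowEvents(lr, 5000, seed = 3), th)
  expect_gt(g2[["high"]], 0.995)
})
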