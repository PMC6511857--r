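# paired induction time courses used throughout: a 2-h pulse from PB (long
# enough that the TetR delay and late RDF escape shape the curve) and a
# 30-min pulse from LR, sampled at 12 points each
fitFixture <- function(noise_sd = 0, seeds = c(11, 12)) {
  base <- latchParams()
  tms <- c(0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 6, 8)
  list(base = base,
       data = list(
         genTimecourse(base, pulseProtocol(0.5, 2, horizon = 8), tms,
                       noiseModel(timecourse_sd = noise_sd),
                       seed = seeds[1], init_state = "PB"),
         genTimecourse(base, pulseProtocol(0.5, 0.5, horizon = 8), tms,
                       noiseModel(timecourse_sd = noise_sd),
                       seed = seeds[2], init_state = "LR")))
}

test_that("the loss vanishes at the generating parameters on noise-free data", {
  fx <- fitFixture(0)
  expect_lt(timeCourseLoss(lumpedProductionRates(fx$base), fx$data, fx$base),
            1e-8)
})

test_that("with observation noise the loss at truth sits at the expected residual sum", {
  fx <- fitFixture(0.03)
  loss <- timeCourseLoss(lumpedProductionRates(fx$base), fx$data, fx$base)
  expected <- 24 * 0.03^2   # n_points * sd^2, chi-square spread around it
  expect_gt(loss / expected, 0.4)
  expect_lt(loss / expected, 2.2)
})

test_that("perturbing any one production rate strictly increases the loss", {
  fx <- fitFixture(0)
  truth <- lumpedProductionRates(fx$base)
  l0 <- timeCourseLoss(truth, fx$data, fx$base)
  for (nm in names(truth)) for (fac in c(0.5, 2)) {
    th <- truth; th[nm] <- th[nm] * fac
    expect_gt(timeCourseLoss(th, fx$data, fx$base), l0 + 1e-3)
  }
})

test_that("the loss is additive over time points (order-independent)", {
  fx <- fitFixture(0.03)
  d <- fx$data[[1]]
  th <- lumpedProductionRates(fx$base) * c(1.3, 0.8, 1.1)
  whole <- timeCourseLoss(th, d, fx$base)
  parts <- lapply(seq_along(d@times), function(i)
    timeCourseData(d@times[i], d@fraction_lr[i], d@protocol,
                   init_state = d@init_state, noise_sd = d@noise_sd))
  expect_equal(whole, timeCourseLoss(th, parts, fx$base), tolerance = 1e-7)
})

test_that("bounds excluding the truth leave a visibly bad constrained optimum", {
  fx <- fitFixture(0)
  # integrase production forced far below its true value of 7.2
  loss <- timeCourseLoss(c(int = 0.5), fx$data, fx$base)
  expect_gt(loss, 100 * 24 * 0.03^2)
})

test_that("RDF production is flagged weakly identified from a lone short PB->LR course", {
  base <- latchParams()
  # course truncated before the RDF escape window: RDF leaves no signature
  short <- genTimecourse(base, pulseProtocol(0.5, 0.5, horizon = 2),
                         times = seq(0.5, 1.5, by = 0.25),
                         noise = noiseModel(0), seed = 1, init_state = "PB")
  truth <- lumpedProductionRates(base)
  pr_rdf <- profileLoss(truth, short, base, "rdf", factors = c(0.5, 1, 2))
  pr_int <- profileLoss(truth, short, base, "int", factors = c(0.5, 1, 2))
  # flat within 1% across a 2x range for RDF, while integrase is sharp
  expect_lt(max(abs(pr_rdf$loss - min(pr_rdf$loss))), 0.01 * max(pr_int$loss))
  expect_gt(max(pr_int$loss), 0.05)
})

test_that("multi-start fitting is reproducible bit-for-bit from the seed", {
  fx <- fitFixture(0.03)
  f1 <- fitProductionRates(fx$data, fx$base, free = c("int", "rdf"),
                           lower = 0.2, upper = 30, n_starts = 2,
                           seed = 21, maxit = 40)
  f2 <- fitProductionRates(fx$data, fx$base, free = c("int", "rdf"),
                           lower = 0.2, upper = 30, n_starts = 2,
                           seed = 21, maxit = 40)
  expect_identical(estimates(f1), estimates(f2))
  expect_identical(f1@loss, f2@loss)
  expect_identical(f1@starts, f2@starts)
  expect_s4_class(f1, "FitResult")
  expect_gte(nrow(f1@starts), 2)
})

test_that("noise-free self-generated data is recovered to under 1%", {
  fx <- fitFixture(0)
  truth <- lumpedProductionRates(fx$base)
  fit <- fitProductionRates(fx$data, fx$base, lower = 0.05, upper = 100,
                            n_starts = 3, seed = 5)
  expect_true(fit@converged)
  expect_lt(max(abs(estimates(fit) / truth - 1)), 0.01)
  expect_lt(fit@loss, 1e-6)
})
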