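# Yeast glycolysis oscillator benchmark.

test_that("default parameters are the published constants", {
  v <- glycolysisValues(GlycolysisParameters())
  expect_equal(v[["J0"]], 2.5)
  expect_equal(v[["k1"]], 100)
  expect_equal(v[["k5"]], 1.28)
  expect_equal(v[["kappa"]], 13)
  expect_equal(v[["K1"]], 0.52)
  expect_equal(v[["psi"]], 0.1)
  expect_equal(v[["N_conc"]], 1)
  expect_equal(v[["A_conc"]], 4)
  expect_error(GlycolysisParameters(bogus = 1), "unknown")
})

test_that("rate laws match an independently coded oracle", {
  oracle <- function(S) {
    # second, independent transcription of the seven rate laws
    J0 <- 2.5; k1 <- 100; k2 <- 6; k3 <- 16; k4 <- 100; k5 <- 1.28
    k6 <- 12; kk <- 1.8; kap <- 13; q <- 4; K1 <- 0.52; psi <- 0.1
    Nc <- 1; Ac <- 4
    inhib <- 1 + (S[6] / K1)^q
    c(J0 - k1 * S[1] * S[6] / inhib,
      2 * k1 * S[1] * S[6] / inhib - k2 * S[2] * (Nc - S[5]) -
        k6 * S[2] * S[5],
      k2 * S[2] * (Nc - S[5]) - k3 * S[3] * (Ac - S[6]),
      k3 * S[3] * (Ac - S[6]) - k4 * S[4] * S[5] - kap * (S[4] - S[7]),
      k2 * S[2] * (Nc - S[5]) - k4 * S[4] * S[5] - k6 * S[2] * S[5],
      -2 * k1 * S[1] * S[6] / inhib + 2 * k3 * S[3] * (Ac - S[6]) -
        k5 * S[6],
      psi * kap * (S[4] - S[7]) - kk * S[7])
  }
  for (seed in 1:20) {
    S <- withSeed(seed, runif(7, 0.05, 2.5))
    expect_equal(glycolysisRates(S), oracle(S), tolerance = 1e-12)
  }
  # shared-zero identity: with S4 = S7 = 0 the external species is static
  S <- c(0.5, 0.5, 0.1, 0, 0.2, 0.5, 0)
  expect_equal(glycolysisRates(S)[7], 0)
})

test_that("trajectory integration is consistent and positive", {
  ic <- rowMeans(glycolysisICRanges())
  # zero-length horizon returns the initial condition
  expect_equal(unname(simulateTrajectory(ic, 0)[1, -1]), unname(ic))
  traj <- simulateTrajectory(ic, seq(0, 2, by = 0.05), rtol = 1e-9,
                             atol = 1e-11)
  expect_true(all(traj[, -1] > 0))
  # halving the tolerances barely moves the states
  t2 <- simulateTrajectory(ic, seq(0, 2, by = 0.05), rtol = 5e-10,
                           atol = 5e-12)
  expect_lt(max(abs(traj[, -1] - t2[, -1])), 1e-6)
})

test_that("the attractor is a limit cycle with a roughly one-minute period", {
  p1 <- estimatePeriod()
  expect_gt(p1, 0.8); expect_lt(p1, 1.2)
  p2 <- estimatePeriod(ic = glycolysisICRanges()[, "low"])
  expect_lt(abs(p1 - p2) / p1, 0.01)
})

test_that("long-time rate variability is attractor-determined", {
  s1 <- glycoRateStd()
  s2 <- longTimeRateStd(ic = glycolysisICRanges()[, "high"] * 0.9)
  expect_lt(max(abs(s1 - s2) / s1), 0.01)
  # stable under a denser sampling resolution and longer window
  s3 <- longTimeRateStd(nPoints = 12000L, window = 45)
  expect_lt(max(abs(s1 - s3) / s1), 0.005)
  expect_equal(unname(benchmarkSigmaTable()), unname(0.5 * s1))
})

test_that("training sets follow the sampling protocol", {
  std <- glycoRateStd()
  cfg <- BenchConfig(nSamples = 200L, tTrain = 0, seed = 5L)
  d <- generateTrainingSet(cfg, rateStd = std)
  r <- glycolysisICRanges()
  # T = 0: concentrations are exactly the initial conditions, inside ranges
  x <- concentrations(d)
  for (j in 1:7) {
    expect_true(all(x[, j] >= r[j, 1] & x[, j] <= r[j, 2]))
  }
  # sigma' column equals half the long-time rate sd
  expect_equal(rateSD(d)[1, ], unname(0.5 * std))
  # reproducibility: identical seed, identical data; new seed differs
  d2 <- generateTrainingSet(cfg, rateStd = std)
  expect_identical(concentrations(d), concentrations(d2))
  expect_identical(measuredRates(d), measuredRates(d2))
  d3 <- generateTrainingSet(BenchConfig(nSamples = 200L, tTrain = 0,
                                        seed = 6L), rateStd = std)
  expect_false(identical(measuredRates(d), measuredRates(d3)))
})

test_that("rate noise has the configured magnitude", {
  std <- glycoRateStd()
  cfg <- BenchConfig(nSamples = 10000L, tTrain = 0, seed = 9L)
  d <- generateTrainingSet(cfg, rateStd = std)
  trueRates <- t(apply(concentrations(d), 1, glycolysisRates))
  resid <- measuredRates(d) - trueRates
  empir <- apply(resid, 2, sd)
  expect_lt(max(abs(empir - 0.5 * std) / (0.5 * std)), 0.03)
  expect_lt(max(abs(colMeans(resid)) / (0.5 * std)), 0.05)
})

test_that("test sets extrapolate into ranges widened by exactly 25%", {
  wide <- glycolysisICRanges(0.25)
  base <- glycolysisICRanges()
  expect_equal(wide[1, "high"], 1.9625)
  expect_equal(unname((wide[, 2] - wide[, 1]) / (base[, 2] - base[, 1])),
               rep(1.25, 7))
  std <- glycoRateStd()
  cfg <- BenchConfig(nSamples = 500L, tTrain = 5, tTest = 0, seed = 13L)
  d <- generateTestSet(cfg, rateStd = std)
  x <- concentrations(d)
  for (j in 1:7)
    expect_true(all(x[, j] >= wide[j, 1] & x[, j] <= wide[j, 2]))
  # some draws genuinely exceed the training ranges
  expect_true(any(x > matrix(base[, 2], 500, 7, byrow = TRUE)))
})
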