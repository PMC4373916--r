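# Shared generators for synthetic models and datasets.

randomSSystem <- function(J, seed, scale = 0.4, mask = ParameterMask(J, free = "all")) {
  withSeed(seed, {
    m <- SSystemModel(
      J,
      logAlpha = rnorm(J, 0, scale) * mask@thetaG[1L, ],
      logBeta = rnorm(J, 0, scale) * mask@thetaH[1L, ],
      g = t(matrix(rnorm(J * J, 0, scale), J, J) * mask@thetaG[-1L, ]),
      h = t(matrix(rnorm(J * J, 0, scale), J, J) * mask@thetaH[-1L, ]),
      mask = mask)
    m
  })
}

randomStates <- function(n, J, seed, lo = -1, hi = 1) {
  withSeed(seed, matrix(exp(runif(n * J, lo, hi)), n, J))
}

datasetFromModel <- function(model, n, seed, sd = 0.05, noisy = FALSE) {
  x <- randomStates(n, nSpecies(model), seed)
  r <- predictRates(model, x)
  if (noisy) r <- r + withSeed(seed + 1L, matrix(rnorm(length(r), 0, sd), nrow(r)))
  RateDataset(x, r, sd = sd)
}

# cache the (expensive-ish) attractor rate sd and one benchmark dataset pair
.fixtureEnv <- new.env(parent = emptyenv())

glycoRateStd <- function() {
  if (is.null(.fixtureEnv$std)) .fixtureEnv$std <- longTimeRateStd()
  .fixtureEnv$std
}

glycoData <- function(n = 100L, tTrain = 5, seed = 11L, test = FALSE) {
  key <- sprintf("d_%d_%g_%d_%d", n, tTrain, seed, test)
  if (is.null(.fixtureEnv[[key]])) {
    cfg <- BenchConfig(nSamples = n, tTrain = tTrain, seed = seed)
    .fixtureEnv[[key]] <- if (test)
      generateTestSet(cfg, rateStd = glycoRateStd())
    else generateTrainingSet(cfg, rateStd = glycoRateStd())
  }
  .fixtureEnv[[key]]
}
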