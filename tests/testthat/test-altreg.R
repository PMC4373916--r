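# Alternating log-space ridge regression.

test_that("regression targets follow the production/degradation split", {
  J <- 2
  d <- RateDataset(matrix(1, 3, J), matrix(2, 3, J), sd = 1)
  def <- SSystemModel(J, mask = ParameterMask(J))

  # H = 1 (default), x' = 2: Y(G) = log 3
  tg <- computeTargets(def, d, "production")
  expect_true(all(tg$valid))
  expect_equal(tg$Y, matrix(log(3), 3, J))

  # G = 1 (default), x' = 2: log argument -1, flagged invalid
  th <- computeTargets(def, d, "degradation")
  expect_false(any(th$valid))
  expect_true(all(is.na(th$Y)))
})

test_that("targets match a termwise oracle on random models", {
  for (seed in 1:25) {
    J <- 2L + (seed %% 3L)
    m <- randomSSystem(J, seed)
    d <- datasetFromModel(randomSSystem(J, seed + 7), 15, seed + 13,
                          sd = 0.2, noisy = TRUE)
    tg <- computeTargets(m, d, "production")
    x <- concentrations(d)
    for (i in c(1L, 8L)) for (mu in seq_len(J)) {
      arg <- evaluateDegradation(m, x[i, ])[mu] + measuredRates(d)[i, mu]
      if (arg > 0) {
        expect_true(tg$valid[i, mu])
        expect_equal(tg$Y[i, mu], log(arg), tolerance = 1e-12)
      } else {
        expect_false(tg$valid[i, mu])
      }
    }
  }
})

test_that("weights are exp(Y)/sigma where valid and zero where not", {
  Y <- matrix(c(0, 1, NA, 2), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  sg <- matrix(2, 2, 2)
  W <- computeWeights(Y, sg, valid)
  expect_equal(W[1, 1], 0.5)
  expect_equal(W[2, 1], exp(1) / 2)
  expect_identical(W[1, 2], 0)
  expect_equal(W[2, 2], exp(2) / 2)
})

test_that("masked ridge solution honors the mask and the closed forms", {
  set.seed(31)
  N <- 40; J <- 3
  D <- cbind(1, matrix(rnorm(N * J), N, J))
  y <- rnorm(N); w <- runif(N, 0.2, 3)

  # no free parameters: zero vector
  expect_identical(maskedRidgeSolve(D, y, w, rep(0, J + 1), 0.1),
                   rep(0, J + 1))

  # all-free solution equals the unmasked ridge normal equations
  theta <- rep(1, J + 1)
  Dc <- D * w
  pRef <- solve(crossprod(Dc) + diag(1 / 0.1^2, J + 1), crossprod(Dc, w * y))
  expect_equal(maskedRidgeSolve(D, y, w, theta, 0.1), as.vector(pRef),
               tolerance = 1e-10)

  # fixed entries are exactly zero for random masks
  for (seed in 1:15) {
    th <- withSeed(seed, rbinom(J + 1, 1, 0.5))
    p <- maskedRidgeSolve(D, y, w, th, 0.5)
    expect_identical(p[th == 0], rep(0, sum(th == 0)))
  }
})

test_that("masked ridge solve minimizes the weighted penalized objective", {
  # brute-force oracle: generic optimizer on the half-step objective
  set.seed(77)
  N <- 30; J <- 2
  D <- cbind(1, matrix(rnorm(N * J), N, J))
  y <- rnorm(N); w <- c(runif(N - 3, 0.1, 2), 0, 0, 0)
  theta <- c(1, 1, 0)
  sp <- 0.3
  obj <- function(pFree) {
    p <- c(pFree, 0)
    r <- w * (y - as.vector(D %*% p))
    sum(r^2) + sum(p[theta == 1]^2) / sp^2
  }
  grad <- function(pFree) {
    p <- c(pFree, 0)
    r <- w * (y - as.vector(D %*% p))
    (-2 * as.vector(crossprod(D * w, r)) + 2 * p / sp^2)[1:2]
  }
  o <- optim(c(0, 0), obj, grad, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 1000))
  p <- maskedRidgeSolve(D, y, w, theta, sp)
  expect_equal(p[1:2], o$par, tolerance = 1e-8)
})

test_that("with a huge prior and unit weights the solve reduces to OLS", {
  set.seed(5)
  N <- 50; J <- 3
  D <- cbind(1, matrix(rnorm(N * J), N, J))
  y <- rnorm(N)
  p <- maskedRidgeSolve(D, y, rep(1, N), rep(1, J + 1), 1e8)
  expect_equal(p, as.vector(qr.solve(D, y)), tolerance = 1e-6)
})

test_that("alternating regression recovers an identifiable generating model", {
  # truth drawn inside the simplest-structure mask: free log beta and the
  # diagonal production exponents; noiseless rates
  J <- 3
  tg <- rbind(rep(0, J), diag(J))
  th <- rbind(rep(1, J), matrix(0, J, J))
  mask <- ParameterMask(J, thetaG = tg, thetaH = th)
  truth <- SSystemModel(J, logBeta = c(-0.2, 0.2, -0.1),
                        g = diag(c(0.3, -0.2, 0.25)), mask = mask)
  x <- withSeed(7, matrix(exp(runif(200 * J, -1.5, 1.5)), 200, J))
  d <- RateDataset(x, predictRates(truth, x), sd = 0.01)
  fit <- alternateFit(d, mask, FitSettings(relTol = 1e-8, maxIter = 500))
  expect_true(fit$converged)
  relErr <- abs(packParameters(fit$model) - packParameters(truth)) /
    abs(packParameters(truth))
  expect_lt(max(relErr), 1e-2)
})

test_that("an all-fixed mask returns the default model in one sweep", {
  d <- datasetFromModel(randomSSystem(2, 1), 10, 2)
  fit <- alternateFit(d, ParameterMask(2, free = "none"))
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
  expect_equal(packParameters(fit$model), numeric(0))
})

test_that("the fully connected fit converges on benchmark data", {
  train <- glycoData(n = 100L, tTrain = 5, seed = 11L)
  fit <- suppressWarnings(
    alternateFit(train, ParameterMask(7, free = "all"), FitSettings()))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 100L)
  expect_length(fit$failedSpecies, 0L)
  # the fit must be a real improvement over the zero-rate default model
  def <- SSystemModel(7, mask = ParameterMask(7))
  expect_lt(chiSquaredTilde(fit$model, train, 0.1),
            0.7 * chiSquaredTilde(def, train, 0.1))
})

test_that("invalidated-datapoint fraction shrinks over early sweeps", {
  # tracked per sweep; statistically non-increasing across seeds
  ok <- 0L
  nSeeds <- 10L
  for (seed in seq_len(nSeeds)) {
    cfg <- BenchConfig(nSamples = 50L, tTrain = 5, seed = 600L + seed)
    train <- generateTrainingSet(cfg, rateStd = glycoRateStd())
    fit <- suppressWarnings(
      alternateFit(train, ParameterMask(7, free = "all"), FitSettings()))
    dg <- fit$diagnostics
    first <- dg$invalidFracG[1L] + dg$invalidFracH[1L]
    later <- if (nrow(dg) >= 3L) dg$invalidFracG[3L] + dg$invalidFracH[3L]
             else dg$invalidFracG[nrow(dg)] + dg$invalidFracH[nrow(dg)]
    if (later <= first + 1e-12) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * nSeeds))
})

test_that("parameter masks are never violated by the fitted model", {
  for (seed in 1:5) {
    J <- 3
    tg <- withSeed(seed, matrix(rbinom((J + 1) * J, 1, 0.5), J + 1, J))
    th <- withSeed(seed + 9, matrix(rbinom((J + 1) * J, 1, 0.5), J + 1, J))
    mask <- ParameterMask(J, thetaG = tg, thetaH = th)
    d <- datasetFromModel(randomSSystem(J, seed + 20), 40, seed + 30,
                          sd = 0.1, noisy = TRUE)
    fit <- suppressWarnings(alternateFit(d, mask, FitSettings(maxIter = 20)))
    PG <- rbind(fit$model@logAlpha, t(fit$model@g))
    PH <- rbind(fit$model@logBeta, t(fit$model@h))
    expect_true(all(PG[tg == 0] == 0))
    expect_true(all(PH[th == 0] == 0))
  }
})
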