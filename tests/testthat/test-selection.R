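# Hierarchy construction, posterior scoring, model selection.

test_that("nearest-neighbor hierarchy has the documented structure", {
  h <- buildHierarchy(7)
  ms <- hierarchyMasks(h)
  expect_length(ms, 15L)
  counts <- vapply(ms, countFreeParameters, integer(1))
  expect_identical(counts, as.integer(seq(14, 112, by = 7)))

  # first mask frees exactly log beta and the diagonal g exponents
  m1 <- ms[[1]]
  expect_equal(m1@thetaH[1, ], rep(1, 7))
  expect_equal(sum(m1@thetaH), 7)
  expect_equal(m1@thetaG[1, ], rep(0, 7))
  expect_equal(m1@thetaG[-1, ], diag(7))

  # level 2 adds the h diagonal, level 3 the log alpha row
  expect_equal(ms[[2]]@thetaH[-1, ], diag(7))
  expect_equal(ms[[3]]@thetaG[1, ], rep(1, 7))

  # level 4 adds the distance-1 production ring: g[mu, mu-1 mod J]
  added <- ms[[4]]@thetaG - ms[[3]]@thetaG
  for (mu in 1:7) {
    nu <- ((mu - 1 - 1) %% 7) + 1
    expect_equal(added[1 + nu, mu], 1)
  }
  expect_equal(sum(added), 7)
})

test_that("a single-species hierarchy has free counts 2, 3, 4", {
  ms <- hierarchyMasks(buildHierarchy(1))
  expect_identical(vapply(ms, countFreeParameters, integer(1)), c(2L, 3L, 4L))
})

test_that("hierarchies are strictly nested for both orderings", {
  for (h in list(buildHierarchy(5), buildHierarchy(5, "random", seed = 3),
                 buildHierarchy(7, "random", seed = 42))) {
    ms <- hierarchyMasks(h)
    J <- nSpecies(h)
    expect_identical(countFreeParameters(ms[[length(ms)]]),
                     as.integer(2 * J * (J + 1)))
    for (k in 2:length(ms)) {
      expect_true(all(ms[[k - 1]]@thetaG <= ms[[k]]@thetaG))
      expect_true(all(ms[[k - 1]]@thetaH <= ms[[k]]@thetaH))
      expect_gt(countFreeParameters(ms[[k]]),
                countFreeParameters(ms[[k - 1]]))
    }
  }
})

test_that("random hierarchies keep the mandatory first level and reshuffle the rest", {
  nn <- buildHierarchy(4)
  r1 <- buildHierarchy(4, "random", seed = 1)
  r2 <- buildHierarchy(4, "random", seed = 2)
  expect_equal(hierarchyMasks(r1)[[1]]@thetaG, hierarchyMasks(nn)[[1]]@thetaG)
  expect_equal(hierarchyMasks(r1)[[1]]@thetaH, hierarchyMasks(nn)[[1]]@thetaH)
  expect_length(hierarchyMasks(r1), length(hierarchyMasks(nn)))
  # same seed reproduces, different seeds differ somewhere
  r1b <- buildHierarchy(4, "random", seed = 1)
  expect_equal(hierarchyMasks(r1)[[3]]@thetaG, hierarchyMasks(r1b)[[3]]@thetaG)
  differs <- any(vapply(2:9, function(k)
    !identical(hierarchyMasks(r1)[[k]]@thetaG,
               hierarchyMasks(r2)[[k]]@thetaG), logical(1)))
  expect_true(differs)
})

test_that("chi-squared matches its definition", {
  m <- SSystemModel(2, mask = ParameterMask(2))  # predicts zero rates
  d1 <- RateDataset(matrix(1, 1, 2), matrix(c(0, 0), 1, 2), sd = 1)
  expect_equal(chiSquared(m, d1), 0)

  # one datapoint with residual equal to sigma
  d2 <- RateDataset(matrix(1, 1, 1), matrix(0.7, 1, 1), sd = 0.7)
  expect_equal(chiSquared(SSystemModel(1, mask = ParameterMask(1)), d2), 1)

  # random model and data against a termwise oracle
  for (seed in 1:10) {
    mm <- randomSSystem(3, seed)
    dd <- datasetFromModel(randomSSystem(3, seed + 4), 12, seed + 8,
                           sd = 0.3, noisy = TRUE)
    acc <- 0
    for (i in 1:12) for (mu in 1:3) {
      pred <- evaluateRate(mm, concentrations(dd)[i, ])[mu]
      acc <- acc + ((measuredRates(dd)[i, mu] - pred) / rateSD(dd)[i, mu])^2
    }
    expect_equal(chiSquared(mm, dd), acc, tolerance = 1e-10)
    p <- packParameters(mm)
    expect_equal(chiSquaredTilde(mm, dd, 0.4), acc + sum(p^2) / 0.16,
                 tolerance = 1e-10)
  }
})

test_that("posterior Hessian eigenvalues match analytic curvature", {
  # analytic oracle: for rates r = G - H, the Hessian of 0.5 * chi2-tilde is
  # sum_i [ (dr/dp)(dr/dp)' + (r - x') d2r/dp2 ] / sigma^2 + I / prior^2,
  # assembled here independently by explicit differentiation of the
  # power-law terms
  analyticHessian <- function(m, d, pw) {
    x <- concentrations(d); xp <- measuredRates(d); sg <- rateSD(d)
    J <- nSpecies(m); D <- cbind(1, log(x))
    mask <- modelMask(m)
    flags <- rbind(cbind(1, which(t(mask@thetaG) == 1, arr.ind = TRUE)),
                   cbind(2, which(t(mask@thetaH) == 1, arr.ind = TRUE)))
    # flags columns: term, position in t(P) = (mu, kappa) index pairs
    tpos <- function(idx) {
      # linear index in t(P) (J x (1+J)) -> (mu = row, kappa = col)
      mu <- (idx - 1) %% J + 1
      kap <- (idx - 1) %/% J + 1
      c(mu, kap)
    }
    ordG <- which(t(mask@thetaG) == 1)
    ordH <- which(t(mask@thetaH) == 1)
    K <- length(ordG) + length(ordH)
    G <- exp(D %*% rbind(m@logAlpha, t(m@g)))
    H <- exp(D %*% rbind(m@logBeta, t(m@h)))
    r <- G - H - xp
    Hm <- diag(1 / pw^2, K)
    info <- list()
    for (k in seq_len(K)) {
      if (k <= length(ordG)) {
        mk <- tpos(ordG[k]); sk <- 1
      } else {
        mk <- tpos(ordH[k - length(ordG)]); sk <- -1
      }
      info[[k]] <- list(mu = mk[1], kap = mk[2], s = sk)
    }
    for (k in seq_len(K)) for (l in k:K) {
      a <- info[[k]]; b <- info[[l]]
      if (a$mu != b$mu) next
      mu <- a$mu
      termA <- if (a$s == 1) G[, mu] else H[, mu]
      termB <- if (b$s == 1) G[, mu] else H[, mu]
      dk <- a$s * termA * D[, a$kap]
      dl <- b$s * termB * D[, b$kap]
      # second derivative nonzero only within the same exponential term
      d2 <- if (a$s == b$s) a$s * termA * D[, a$kap] * D[, b$kap] else 0
      v <- sum((dk * dl + r[, mu] * d2) / sg[, mu]^2)
      Hm[k, l] <- Hm[k, l] + v
      if (l > k) Hm[l, k] <- Hm[l, k] + v
    }
    Hm
  }

  for (seed in c(2, 9)) {
    J <- 2
    mask <- ParameterMask(J, free = "all")
    m <- randomSSystem(J, seed, scale = 0.3, mask = mask)
    d <- datasetFromModel(randomSSystem(J, seed + 3, scale = 0.3), 25,
                          seed + 6, sd = 0.4, noisy = TRUE)
    Hfd <- posteriorHessian(m, d, priorWidth = 2)
    Han <- analyticHessian(m, d, 2)
    expect_equal(Hfd, Han, tolerance = 1e-4)
    lam <- hessianEigenvalues(m, d, priorWidth = 2)
    expect_equal(lam, sort(eigen(Han, symmetric = TRUE)$values,
                           decreasing = TRUE), tolerance = 1e-4)
  }
})

test_that("pure-prior limit gives eigenvalues at the prior curvature", {
  # enormous rate uncertainties: the data carry no information
  m <- randomSSystem(2, 4)
  x <- randomStates(10, 2, 5)
  d <- RateDataset(x, predictRates(m, x), sd = 1e8)
  lam <- hessianEigenvalues(m, d, priorWidth = 5)
  expect_equal(lam, rep(1 / 25, countFreeParameters(m)), tolerance = 1e-4)
  # and the score then reduces to -chi2-tilde / 2 exactly
  L <- logPosterior(m, d, priorWidth = 5, eigenvalues = lam)
  expect_equal(as.numeric(L), -0.5 * chiSquaredTilde(m, d, 5),
               tolerance = 1e-2)
})

test_that("zero-free-parameter models score -chi2-tilde/2 with no volume term", {
  m <- SSystemModel(3, mask = ParameterMask(3, free = "none"))
  d <- datasetFromModel(randomSSystem(3, 11), 8, 12, sd = 0.5, noisy = TRUE)
  expect_length(hessianEigenvalues(m, d, 10), 0L)
  expect_equal(as.numeric(logPosterior(m, d, 10)),
               -0.5 * chiSquaredTilde(m, d, 10))
})

test_that("the score matches a quadrature log-evidence on a 1-parameter model", {
  # J = 1, only log alpha free: posterior is nearly Gaussian for tight data,
  # and the score should match log integral exp(-chi2/2) N(p; 0, prior^2) dp
  mask <- ParameterMask(1, thetaG = matrix(c(1, 0), 2, 1),
                        thetaH = matrix(0, 2, 1))
  x <- matrix(withSeed(3, runif(30, 0.5, 2)), 30, 1)
  truth <- unpackParameters(0.4, mask)
  d <- RateDataset(x, predictRates(truth, x) +
                     withSeed(4, matrix(rnorm(30, 0, 0.05), 30, 1)),
                   sd = 0.05)
  fit <- polishFit(unpackParameters(0, mask), d, priorWidth = 10)
  L <- as.numeric(logPosterior(fit, d, priorWidth = 10))
  chi2 <- function(p) {
    mm <- unpackParameters(p, mask)
    chiSquared(mm, d)
  }
  integrand <- Vectorize(function(p)
    exp(-0.5 * chi2(p)) * stats::dnorm(p, 0, 10))
  Z <- stats::integrate(integrand, 0.4 - 1, 0.4 + 1, rel.tol = 1e-10)$value
  expect_equal(L, log(Z), tolerance = 1e-2)
})

test_that("effective parameters are the eigenvalues above one", {
  expect_identical(effectiveNumParameters(c(0.5, 0.99)), 0L)
  expect_identical(effectiveNumParameters(c(2, 100, 0.1)), 2L)
  expect_identical(effectiveNumParameters(c(1, 1 + 1e-9, 1 - 1e-9)), 1L)
  expect_identical(effectiveNumParameters(numeric(0)), 0L)
})

test_that("selection recovers a simple generating structure", {
  # data generated noiselessly from a level-1 model: the level-1 mask wins
  J <- 3
  h <- buildHierarchy(J)
  lvl1 <- hierarchyMasks(h)[[1]]
  truth <- SSystemModel(J, logBeta = c(0.3, -0.2, 0.1),
                        g = diag(c(0.4, 0.3, -0.2)), mask = lvl1)
  x <- withSeed(21, matrix(exp(runif(150 * J, -1, 1)), 150, J))
  d <- RateDataset(x, predictRates(truth, x), sd = 0.02)
  sel <- selectModel(d, h)
  expect_identical(winnerIndex(sel), 1L)
  rec <- selectionRecords(sel)[[1]]
  expect_lte(rec$effectiveParams, rec$nominalParams)
  # recovered parameters close to truth
  expect_lt(max(abs(packParameters(rec$model) - packParameters(truth))), 0.05)
})

test_that("a single-mask hierarchy trivially wins and invariants hold", {
  J <- 2
  mask <- hierarchyMasks(buildHierarchy(J))[[1]]
  h1 <- new("ModelHierarchy", masks = list(mask),
            orderingKind = "nearest_neighbor", seed = NA_integer_)
  d <- datasetFromModel(randomSSystem(J, 31), 30, 32, sd = 0.2, noisy = TRUE)
  sel <- selectModel(d, h1)
  expect_identical(winnerIndex(sel), 1L)
  for (r in selectionRecords(sel))
    expect_lte(r$effectiveParams, r$nominalParams)
})
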