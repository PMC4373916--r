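#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Yeast glycolysis oscillator benchmark
## ---------------------------------------------------------------------------

#' Parameters of the yeast glycolysis oscillator
#'
#' The 7-species model of glycolytic oscillations used as the inference
#' benchmark. Defaults are the standard published constants: J0 = 2.5
#' mM/min; k1 = 100, k2 = 6, k3 = 16, k4 = 100, k6 = 12 (1/mM/min);
#' k5 = 1.28, k = 1.8, kappa = 13 (1/min); q = 4; K1 = 0.52 mM;
#' psi = 0.1; and total cofactor pools N = 1 mM, A = 4 mM (named `N_conc`
#' and `A_conc` to avoid clashing with the sample count N and the linear
#' interaction matrix A).
#'
#' @slot values named numeric vector of the 14 constants.
#' @export
setClass("GlycolysisParameters", representation(values = "numeric"))

.glycoParamNames <- c("J0", "k1", "k2", "k3", "k4", "k5", "k6", "k",
                      "kappa", "q", "K1", "psi", "N_conc", "A_conc")

setValidity("GlycolysisParameters", function(object) {
  v <- object@values
  if (!identical(sort(names(v)), sort(.glycoParamNames)))
    return("values must be named exactly by the 14 model constants")
  if (any(!is.finite(v)) || any(v <= 0))
    return("all parameters must be positive and finite")
  TRUE
})

#' @rdname GlycolysisParameters-class
#' @param ... named overrides of individual constants (e.g. `k5 = 1.5`).
#' @return a `GlycolysisParameters` object.
#' @examples
#' glycolysisValues(GlycolysisParameters())[["k5"]]  # 1.28
#' @export
GlycolysisParameters <- function(...) {
  v <- c(J0 = 2.5, k1 = 100, k2 = 6, k3 = 16, k4 = 100, k5 = 1.28,
         k6 = 12, k = 1.8, kappa = 13, q = 4, K1 = 0.52, psi = 0.1,
         N_conc = 1, A_conc = 4)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(v))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(ov)] <- unlist(ov)
  }
  new("GlycolysisParameters", values = v)
}

#' @rdname GlycolysisParameters-class
#' @param x a `GlycolysisParameters` object.
#' @export
glycolysisValues <- function(x) x@values

setMethod("show", "GlycolysisParameters", function(object) {
  cat("GlycolysisParameters:\n")
  print(object@values)
})

#' Initial-condition ranges for the benchmark protocol
#'
#' The 7 x 2 matrix of per-species low/high bounds (mM) from which training
#' initial conditions are drawn uniformly. For test data the high end of each
#' range is raised so that the range is 25% wider, forcing extrapolation.
#'
#' @param widenFactor nonnegative fractional increase of each range's size,
#'   applied to the high end only. Default 0 (training ranges).
#' @return 7 x 2 matrix with columns `low`, `high`.
#' @examples
#' glycolysisICRanges()[1, ]            # S1: 0.15 to 1.60
#' glycolysisICRanges(0.25)[1, "high"]  # 1.9625
#' @export
glycolysisICRanges <- function(widenFactor = 0) {
  r <- matrix(c(0.15, 1.60,
                0.19, 2.16,
                0.04, 0.20,
                0.10, 0.35,
                0.08, 0.30,
                0.14, 2.67,
                0.05, 0.10),
              ncol = 2L, byrow = TRUE,
              dimnames = list(paste0("S", 1:7), c("low", "high")))
  r[, "high"] <- r[, "low"] + (1 + widenFactor) * (r[, "high"] - r[, "low"])
  r
}

#' Right-hand side of the glycolysis ODEs
#'
#' Evaluates the seven coupled rate laws of the oscillator: glucose input
#' J0 into S1, the allosterically inhibited PFK step
#' \eqn{v_1 = k_1 S_1 S_6 / (1 + (S_6/K_1)^q)}, downstream mass-action
#' steps, membrane exchange \eqn{\kappa(S_4 - S_7)} scaled by psi in the
#' external compartment, and first-order losses.
#'
#' @param S strictly positive numeric vector of 7 concentrations (mM).
#' @param params a \linkS4class{GlycolysisParameters} object.
#' @return numeric vector of 7 rates (mM/min).
#' @export
glycolysisRates <- function(S, params = GlycolysisParameters()) {
  if (length(S) != 7L) stop("S must have length 7")
  p <- as.list(glycolysisValues(params))
  v1 <- p$k1 * S[1] * S[6] / (1 + (S[6] / p$K1)^p$q)
  v2 <- p$k2 * S[2] * (p$N_conc - S[5])
  v3 <- p$k3 * S[3] * (p$A_conc - S[6])
  v4 <- p$k4 * S[4] * S[5]
  v6 <- p$k6 * S[2] * S[5]
  ex <- p$kappa * (S[4] - S[7])
  c(p$J0 - v1,
    2 * v1 - v2 - v6,
    v2 - v3,
    v3 - v4 - ex,
    v2 - v4 - v6,
    -2 * v1 + 2 * v3 - p$k5 * S[6],
    p$psi * ex - p$k * S[7])
}

## Vectorized rate evaluation: S is an N x 7 matrix of states.
.glycolysisRatesMatrix <- function(S, params) {
  p <- as.list(glycolysisValues(params))
  v1 <- p$k1 * S[, 1] * S[, 6] / (1 + (S[, 6] / p$K1)^p$q)
  v2 <- p$k2 * S[, 2] * (p$N_conc - S[, 5])
  v3 <- p$k3 * S[, 3] * (p$A_conc - S[, 6])
  v4 <- p$k4 * S[, 4] * S[, 5]
  v6 <- p$k6 * S[, 2] * S[, 5]
  ex <- p$kappa * (S[, 4] - S[, 7])
  cbind(p$J0 - v1, 2 * v1 - v2 - v6, v2 - v3, v3 - v4 - ex,
        v2 - v4 - v6, -2 * v1 + 2 * v3 - p$k5 * S[, 6],
        p$psi * ex - p$k * S[, 7])
}

## Integrate many independent copies of the model at once (one stacked ODE
## system with a vectorized right-hand side) and return each copy's state at
## its own end time. Mathematically identical to per-sample integration --
## the copies do not interact -- but orders of magnitude faster in R.
.batchStatesAtTimes <- function(ics, ts, params, rtol = 1e-8, atol = 1e-10) {
  n <- nrow(ics)
  out <- ics
  todo <- which(ts > 0)
  if (!length(todo)) return(out)
  times <- sort(unique(c(0, ts[todo])))
  rhs <- function(t, y, parms)
    list(as.vector(.glycolysisRatesMatrix(matrix(y, ncol = 7L), params)))
  sol <- deSolve::lsoda(y = as.vector(ics[todo, , drop = FALSE]),
                        times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 100000L)
  if (attr(sol, "istate")[1L] < 0)
    stop("batched integration of the benchmark model failed")
  rows <- match(ts[todo], times)
  for (k in seq_along(todo)) {
    y <- matrix(sol[rows[k], -1L], ncol = 7L)
    out[todo[k], ] <- y[k, ]
  }
  out
}

#' Integrate the glycolysis model
#'
#' Stiff-capable integration (deSolve's `lsoda`) at tight tolerances.
#'
#' @param ic strictly positive numeric vector of 7 initial concentrations.
#' @param times numeric vector of output times (min), starting at the
#'   initial time.
#' @param params a \linkS4class{GlycolysisParameters} object.
#' @param rtol,atol integrator tolerances (defaults 1e-8, 1e-10).
#' @return matrix with a `time` column and columns S1..S7.
#' @export
simulateTrajectory <- function(ic, times, params = GlycolysisParameters(),
                               rtol = 1e-8, atol = 1e-10) {
  if (length(ic) != 7L || any(ic <= 0))
    stop("ic must be 7 positive concentrations")
  if (length(times) == 1L) {
    out <- cbind(time = times, matrix(ic, 1L, 7L,
                                      dimnames = list(NULL, paste0("S", 1:7))))
    return(out)
  }
  rhs <- function(t, y, parms) list(glycolysisRates(y, params))
  out <- deSolve::lsoda(y = setNames(ic, paste0("S", 1:7)), times = times,
                        func = rhs, parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000L)
  if (attr(out, "istate")[1L] < 0)
    stop(sprintf("integration failed from IC (%s) near t = %.3f",
                 paste(signif(ic, 4), collapse = ", "),
                 max(out[, "time"])))
  unclass(out)
}

#' Long-time standard deviation of each species' rate
#'
#' Integrates the oscillator onto its limit cycle, discards a transient
#' (default 10 min), samples the state at `nPoints` uniformly spaced times
#' over the following `window` minutes, evaluates the rate vector at each
#' sampled state, and returns the per-species standard deviation of the
#' rates. This is the scale used to set the benchmark's measurement noise.
#'
#' @param params a \linkS4class{GlycolysisParameters} object.
#' @param ic starting concentrations; defaults to the midpoints of the
#'   training initial-condition ranges. The result is attractor-determined
#'   and insensitive to this choice.
#' @param transient minutes discarded before sampling (default 30; from
#'   initial conditions near the edges of the published ranges the approach
#'   to the limit cycle can take tens of minutes).
#' @param window sampling window length in minutes (default 30).
#' @param nPoints number of uniform sample times (default 6000).
#' @return named numeric vector of 7 rate standard deviations (mM/min).
#' @export
longTimeRateStd <- function(params = GlycolysisParameters(),
                            ic = rowMeans(glycolysisICRanges()),
                            transient = 30, window = 30, nPoints = 6000L) {
  times <- c(0, transient + seq(0, window, length.out = nPoints))
  traj <- simulateTrajectory(ic, times, params)
  states <- traj[-1L, -1L, drop = FALSE]
  ## trim to whole oscillation cycles (first to last S1 maximum), so the
  ## estimate carries no partial-cycle phase bias
  s1 <- states[, 1L]
  n <- length(s1)
  pk <- which(s1[2:(n - 1L)] > s1[1:(n - 2L)] & s1[2:(n - 1L)] >= s1[3:n]) + 1L
  pk <- pk[s1[pk] > mean(range(s1))]
  if (length(pk) >= 2L)
    states <- states[pk[1L]:(pk[length(pk)] - 1L), , drop = FALSE]
  rates <- .glycolysisRatesMatrix(states, params)
  setNames(apply(rates, 2L, sd), paste0("S", 1:7))
}

#' Published noise scale of the benchmark
#'
#' The benchmark corrupts each rate with zero-mean Gaussian noise whose
#' standard deviation is half the long-time rate standard deviation of the
#' species; this half-sd vector is also the per-species scale used to
#' standardize squared prediction errors. Computed as
#' `0.5 * longTimeRateStd(params)`.
#'
#' @inheritParams longTimeRateStd
#' @return named numeric vector of 7 noise standard deviations (mM/min).
#' @export
benchmarkSigmaTable <- function(params = GlycolysisParameters(), ...) {
  0.5 * longTimeRateStd(params, ...)
}

#' Estimate the oscillation period from successive maxima
#'
#' Integrates past the transient, locates the interior local maxima of S1 on
#' a dense time grid, and returns the mean spacing between successive
#' maxima.
#'
#' @inheritParams longTimeRateStd
#' @param transient minutes discarded before peak-finding (default 30).
#' @param window observation window in minutes (default 10).
#' @return numeric scalar, the period in minutes.
#' @export
estimatePeriod <- function(params = GlycolysisParameters(),
                           ic = rowMeans(glycolysisICRanges()),
                           transient = 30, window = 10) {
  times <- c(0, transient + seq(0, window, length.out = 4001L))
  s1 <- simulateTrajectory(ic, times, params)[-1L, "S1"]
  n <- length(s1)
  peaks <- which(s1[2:(n - 1)] > s1[1:(n - 2)] & s1[2:(n - 1)] >= s1[3:n]) + 1L
  ## ignore ripples: only maxima in the upper part of the waveform count
  peaks <- peaks[s1[peaks] > mean(range(s1))]
  if (length(peaks) < 2L) stop("found fewer than two oscillation maxima")
  dt <- window / 4000
  stats::median(diff(peaks)) * dt
}

## ---------------------------------------------------------------------------
## Benchmark dataset generation
## ---------------------------------------------------------------------------

#' Benchmark data-generation protocol
#'
#' Bundles the knobs of the training/test protocol: `nSamples` initial
#' conditions are drawn uniformly from the training ranges, each integrated
#' to an independent time uniform on `[0, tTrain]`, and the state and rate
#' at that time become one sample. Rates are corrupted with zero-mean
#' Gaussian noise of standard deviation `noiseFactor` times the long-time
#' rate standard deviation of each species; concentrations are noise-free.
#' Test data use times uniform on `[0, tTest]` and ranges whose size is
#' increased by `widenFactor` (high end only), forcing extrapolation.
#'
#' @slot nSamples integer N.
#' @slot tTrain nonnegative training time horizon (min).
#' @slot tTest test time horizon (min), default 5.
#' @slot icRanges 7 x 2 matrix of training initial-condition bounds.
#' @slot widenFactor test-range size increase, default 0.25.
#' @slot noiseFactor rate-noise scale in units of the long-time rate
#'   standard deviation, default 0.5.
#' @slot seed integer RNG seed.
#' @export
setClass("BenchConfig",
         representation(nSamples = "integer", tTrain = "numeric",
                        tTest = "numeric", icRanges = "matrix",
                        widenFactor = "numeric", noiseFactor = "numeric",
                        seed = "integer"))

setValidity("BenchConfig", function(object) {
  if (object@nSamples < 1L) return("nSamples must be positive")
  if (object@tTrain < 0) return("tTrain must be nonnegative")
  if (!identical(dim(object@icRanges), c(7L, 2L)))
    return("icRanges must be a 7 x 2 matrix")
  if (any(object@icRanges <= 0) ||
      any(object@icRanges[, 2L] <= object@icRanges[, 1L]))
    return("icRanges rows must satisfy 0 < low < high")
  TRUE
})

#' @rdname BenchConfig-class
#' @param nSamples,tTrain,tTest,icRanges,widenFactor,noiseFactor,seed see
#'   slot documentation.
#' @export
BenchConfig <- function(nSamples = 100L, tTrain = 5, tTest = 5,
                        icRanges = glycolysisICRanges(),
                        widenFactor = 0.25, noiseFactor = 0.5, seed = 0L) {
  new("BenchConfig", nSamples = as.integer(nSamples), tTrain = tTrain,
      tTest = tTest, icRanges = icRanges, widenFactor = widenFactor,
      noiseFactor = noiseFactor, seed = as.integer(seed))
}

.sampleRateData <- function(nSamples, tMax, ranges, noiseSD, seed, params,
                            noisy = TRUE) {
  J <- 7L
  withSeed(seed, {
    ics <- matrix(runif(nSamples * J, rep(ranges[, 1L], each = nSamples),
                        rep(ranges[, 2L], each = nSamples)), nSamples, J)
    ts <- if (tMax > 0) runif(nSamples, 0, tMax) else numeric(nSamples)
    x <- .batchStatesAtTimes(ics, ts, params)
    trueRates <- .glycolysisRatesMatrix(x, params)
    noise <- if (noisy)
      matrix(rnorm(nSamples * J, sd = rep(noiseSD, each = nSamples)),
             nSamples, J)
    else matrix(0, nSamples, J)
    RateDataset(conc = x, rate = trueRates + noise,
                sd = matrix(noiseSD, nSamples, J, byrow = TRUE))
  })
}

#' Generate a benchmark training set
#'
#' @param config a \linkS4class{BenchConfig}.
#' @param params a \linkS4class{GlycolysisParameters} object.
#' @param rateStd optional precomputed [longTimeRateStd()] vector, to avoid
#'   re-integrating the attractor on every call.
#' @return a \linkS4class{RateDataset} with `config@nSamples` rows.
#' @export
generateTrainingSet <- function(config = BenchConfig(),
                                params = GlycolysisParameters(),
                                rateStd = NULL) {
  if (is.null(rateStd)) rateStd <- longTimeRateStd(params)
  .sampleRateData(config@nSamples, config@tTrain, config@icRanges,
                  config@noiseFactor * rateStd, config@seed, params)
}

#' Generate a benchmark test set
#'
#' Same protocol as [generateTrainingSet()] but with times drawn from
#' `[0, tTest]` and initial-condition ranges widened by `widenFactor`. Test
#' rates are noise-corrupted by default ("created using the same method");
#' set `noisy = FALSE` for noise-free diagnostics.
#'
#' @inheritParams generateTrainingSet
#' @param noisy logical, corrupt the test rates with the same noise model.
#' @export
generateTestSet <- function(config = BenchConfig(),
                            params = GlycolysisParameters(),
                            rateStd = NULL, noisy = TRUE) {
  if (is.null(rateStd)) rateStd <- longTimeRateStd(params)
  ranges <- config@icRanges
  ranges[, 2L] <- ranges[, 1L] +
    (1 + config@widenFactor) * (ranges[, 2L] - ranges[, 1L])
  .sampleRateData(config@nSamples, config@tTest, ranges,
                  config@noiseFactor * rateStd, config@seed + 1000003L,
                  params, noisy = noisy)
}
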