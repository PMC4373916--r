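#' @include AllClasses.R
NULL

## Parameter-matrix layout: P is (1+J) x J with one column per species mu;
## row 1 holds the log prefactor, row 1+nu the exponent of species nu.

.pgMatrix <- function(model) rbind(model@logAlpha, t(model@g))

.phMatrix <- function(model) rbind(model@logBeta, t(model@h))

.modelFromP <- function(PG, PH, mask) {
  J <- ncol(PG)
  new("SSystemModel", J = as.integer(J),
      logAlpha = unname(PG[1L, ]), logBeta = unname(PH[1L, ]),
      g = t(PG[-1L, , drop = FALSE]), h = t(PH[-1L, , drop = FALSE]),
      mask = mask)
}

## Row-major flattening of a (1+J) x J matrix (prefactor row first).
.rowMajor <- function(M) as.vector(t(M))

.rowMajorAssign <- function(J, values, flags) {
  M <- matrix(0, J, J + 1L)          # transposed layout
  M[flags == 1] <- values
  t(M)
}

#' @export
setMethod("packParameters", "SSystemModel", function(model) {
  mk <- model@mask
  c(.rowMajor(.pgMatrix(model))[.rowMajor(mk@thetaG) == 1],
    .rowMajor(.phMatrix(model))[.rowMajor(mk@thetaH) == 1])
})

#' Rebuild a model from a packed free-parameter vector
#'
#' Inverse of [packParameters()]: `theta` holds the free entries of the
#' production parameter matrix in row-major order followed by those of the
#' degradation matrix; fixed parameters are restored to their default 0.
#'
#' @param theta numeric vector of length `countFreeParameters(mask)`.
#' @param mask a \linkS4class{ParameterMask}.
#' @return an \linkS4class{SSystemModel}.
#' @export
unpackParameters <- function(theta, mask) {
  J <- nSpecies(mask)
  nG <- sum(mask@thetaG)
  if (length(theta) != nG + sum(mask@thetaH))
    stop("theta length does not match the number of free parameters")
  PG <- .rowMajorAssign(J, theta[seq_len(nG)], .rowMajor2(mask@thetaG))
  PH <- .rowMajorAssign(J, theta[nG + seq_len(sum(mask@thetaH))],
                        .rowMajor2(mask@thetaH))
  .modelFromP(PG, PH, mask)
}

## flags in the transposed (row-major fill) layout
.rowMajor2 <- function(M) t(M)

.checkPositiveState <- function(x, J) {
  if (length(x) != J)
    stop(sprintf("state vector has length %d, expected %d", length(x), J))
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop(sprintf("concentrations must be strictly positive; offending species index: %s",
                 paste(bad, collapse = ", ")))
  invisible(x)
}

#' @export
setMethod("evaluateProduction", "SSystemModel", function(model, x) {
  .checkPositiveState(x, model@J)
  as.vector(exp(model@logAlpha + model@g %*% log(x)))
})

#' @export
setMethod("evaluateDegradation", "SSystemModel", function(model, x) {
  .checkPositiveState(x, model@J)
  as.vector(exp(model@logBeta + model@h %*% log(x)))
})

#' @export
setMethod("evaluateRate", "SSystemModel", function(model, x) {
  evaluateProduction(model, x) - evaluateDegradation(model, x)
})

#' @export
setMethod("predictRates", "SSystemModel", function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@J) stop("state matrix must have J columns")
  if (any(!is.finite(x) | x <= 0))
    stop("concentrations must be strictly positive")
  D <- cbind(1, log(x))
  exp(D %*% .pgMatrix(model)) - exp(D %*% .phMatrix(model))
})

#' @export
setMethod("predictRates", "LinearModel", function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nSpecies(model)) stop("state matrix must have J columns")
  sweep(x %*% t(model@A), 2L, model@intercept, "+")
})

#' Predict the rate vector of a linear model at one state
#'
#' @param model a \linkS4class{LinearModel}.
#' @param x numeric length-J state vector.
#' @return numeric length-J rate vector \eqn{A x} (+ intercept if fitted).
#' @export
predictLinear <- function(model, x) {
  as.vector(model@A %*% x) + model@intercept
}
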