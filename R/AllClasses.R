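#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ParameterMask
## ---------------------------------------------------------------------------

#' Binary free-parameter mask for an S-system
#'
#' An S-system over J species has two parameter matrices of shape (1+J) x J:
#' one for the production term (row 1 holds the log prefactors
#' \eqn{\log\alpha_\mu}, rows 2..J+1 the exponents \eqn{g_{\mu\nu}}, one column
#' per species \eqn{\mu}) and one for the degradation term
#' (\eqn{\log\beta_\mu}, \eqn{h_{\mu\nu}}). A `ParameterMask` carries a 0/1
#' flag for every entry: 1 means the parameter is inferred from data, 0 means
#' it is held at its default value 0 (prefactor 1, exponent 0).
#'
#' @slot thetaG (1+J) x J binary matrix of free-flags for the production
#'   parameters.
#' @slot thetaH same shape, for the degradation parameters.
#' @export
setClass("ParameterMask",
         representation(thetaG = "matrix", thetaH = "matrix"))

setValidity("ParameterMask", function(object) {
  tg <- object@thetaG; th <- object@thetaH
  if (!is.numeric(tg) || !is.numeric(th))
    return("mask matrices must be numeric 0/1 matrices")
  if (!identical(dim(tg), dim(th)))
    return("thetaG and thetaH must have identical dimensions")
  if (nrow(tg) != ncol(tg) + 1L)
    return("mask matrices must have shape (1+J) x J")
  if (!all(tg %in% c(0, 1)) || !all(th %in% c(0, 1)))
    return("mask entries must be 0 or 1")
  TRUE
})

#' Construct a parameter mask
#'
#' @param J positive integer, number of species. Ignored when `thetaG` is
#'   given.
#' @param free one of `"none"` (all parameters fixed), `"all"` (all
#'   2J(J+1) parameters free); ignored when `thetaG`/`thetaH` are supplied.
#' @param thetaG,thetaH optional (1+J) x J binary matrices.
#' @return a \linkS4class{ParameterMask}.
#' @examples
#' countFreeParameters(ParameterMask(7, free = "all"))  # 112
#' @export
ParameterMask <- function(J, free = c("none", "all"),
                          thetaG = NULL, thetaH = NULL) {
  if (is.null(thetaG) != is.null(thetaH))
    stop("supply both thetaG and thetaH or neither")
  if (is.null(thetaG)) {
    free <- match.arg(free)
    fill <- if (free == "all") 1 else 0
    thetaG <- matrix(fill, J + 1L, J)
    thetaH <- matrix(fill, J + 1L, J)
  }
  storage.mode(thetaG) <- "double"
  storage.mode(thetaH) <- "double"
  new("ParameterMask", thetaG = unname(thetaG), thetaH = unname(thetaH))
}

#' @describeIn ParameterMask number of species J.
#' @param x a `ParameterMask`.
#' @export
setMethod("nSpecies", "ParameterMask", function(x) ncol(x@thetaG))

#' @export
setMethod("countFreeParameters", "ParameterMask", function(x)
  as.integer(sum(x@thetaG) + sum(x@thetaH)))

setMethod("show", "ParameterMask", function(object) {
  J <- nSpecies(object)
  cat(sprintf("ParameterMask: J = %d, %d of %d parameters free\n",
              J, countFreeParameters(object), 2L * J * (J + 1L)))
})

## ---------------------------------------------------------------------------
## SSystemModel
## ---------------------------------------------------------------------------

#' S-system rate model
#'
#' Represents the power-law rate function
#' \deqn{\frac{dx_\mu}{dt} = G_\mu(x) - H_\mu(x), \qquad
#'   G_\mu(x) = \alpha_\mu \prod_\nu x_\nu^{g_{\mu\nu}}, \quad
#'   H_\mu(x) = \beta_\mu \prod_\nu x_\nu^{h_{\mu\nu}}.}
#' Prefactors are stored in log space, so \eqn{\alpha_\mu,\beta_\mu > 0} by
#' construction. Every parameter whose mask entry is fixed holds the default
#' value 0 (prefactor 1, exponent 0); the validity method enforces this.
#'
#' @slot J integer, number of species.
#' @slot logAlpha,logBeta length-J numeric, log production/degradation
#'   prefactors.
#' @slot g,h J x J numeric exponent matrices (`g[mu, nu]` is the exponent of
#'   species nu in the production of species mu).
#' @slot mask a \linkS4class{ParameterMask}.
#' @export
setClass("SSystemModel",
         representation(J = "integer", logAlpha = "numeric",
                        logBeta = "numeric", g = "matrix", h = "matrix",
                        mask = "ParameterMask"))

setValidity("SSystemModel", function(object) {
  J <- object@J
  if (length(J) != 1L || J < 1L) return("J must be a positive integer")
  if (length(object@logAlpha) != J || length(object@logBeta) != J)
    return("logAlpha and logBeta must have length J")
  if (!identical(dim(object@g), c(J, J)) ||
      !identical(dim(object@h), c(J, J)))
    return("g and h must be J x J matrices")
  if (nSpecies(object@mask) != J)
    return("mask dimension does not match J")
  PG <- rbind(object@logAlpha, t(object@g))
  PH <- rbind(object@logBeta, t(object@h))
  if (any(PG[object@mask@thetaG == 0] != 0) ||
      any(PH[object@mask@thetaH == 0] != 0))
    return("parameters fixed by the mask must equal the default value 0")
  TRUE
})

#' Construct an S-system model
#'
#' With only `J` (and optionally `mask`) supplied, returns the default model:
#' every parameter at 0, i.e. all prefactors 1, all exponents 0, so the rate
#' is identically zero.
#'
#' @param J positive integer, number of species.
#' @param logAlpha,logBeta length-J log prefactors.
#' @param g,h J x J exponent matrices.
#' @param mask a \linkS4class{ParameterMask}; defaults to all-free.
#' @return an \linkS4class{SSystemModel}.
#' @examples
#' m <- SSystemModel(2, logAlpha = c(log(5), 0),
#'                   g = matrix(c(1, 0, -1, 0), 2, 2))
#' evaluateProduction(m, c(2, 4))  # c(2.5, 1)
#' @export
SSystemModel <- function(J, logAlpha = numeric(J), logBeta = numeric(J),
                         g = matrix(0, J, J), h = matrix(0, J, J),
                         mask = ParameterMask(J, free = "all")) {
  new("SSystemModel", J = as.integer(J), logAlpha = as.numeric(logAlpha),
      logBeta = as.numeric(logBeta), g = g, h = h, mask = mask)
}

#' @export
setMethod("nSpecies", "SSystemModel", function(x) x@J)

#' @export
setMethod("countFreeParameters", "SSystemModel", function(x)
  countFreeParameters(x@mask))

setMethod("show", "SSystemModel", function(object) {
  cat(sprintf("SSystemModel: J = %d species, %d free parameters\n",
              object@J, countFreeParameters(object)))
  cat("  alpha:", format(exp(object@logAlpha), digits = 4), "\n")
  cat("  beta: ", format(exp(object@logBeta), digits = 4), "\n")
})

#' Extract the free-parameter mask of a model
#'
#' @param model an \linkS4class{SSystemModel}.
#' @return the model's \linkS4class{ParameterMask}.
#' @export
modelMask <- function(model) model@mask

## ---------------------------------------------------------------------------
## RateDataset
## ---------------------------------------------------------------------------

#' Dataset of concentrations, rates and rate uncertainties
#'
#' The sole input of the fitters: N samples of J species, each sample holding
#' a strictly positive concentration vector x (assumed measured without
#' error), a measured rate vector x' and a strictly positive rate uncertainty
#' vector sigma'. In the benchmark the units are mM and mM/min.
#'
#' @slot conc N x J matrix of concentrations, strictly positive.
#' @slot rate N x J matrix of measured rates of change.
#' @slot sd N x J matrix of rate standard errors, strictly positive.
#' @export
setClass("RateDataset",
         representation(conc = "matrix", rate = "matrix", sd = "matrix"))

setValidity("RateDataset", function(object) {
  if (!identical(dim(object@conc), dim(object@rate)) ||
      !identical(dim(object@conc), dim(object@sd)))
    return("conc, rate and sd must share dimensions")
  if (any(!is.finite(object@conc)) || any(object@conc <= 0))
    return("concentrations must be finite and strictly positive")
  if (any(!is.finite(object@rate)))
    return("rates must be finite")
  if (any(!is.finite(object@sd)) || any(object@sd <= 0))
    return("rate uncertainties must be finite and strictly positive")
  TRUE
})

#' Construct a rate dataset
#'
#' @param conc,rate,sd numeric N x J matrices of concentrations, measured
#'   rates and rate standard errors. A strictly positive scalar or length-J
#'   `sd` is recycled across samples.
#' @return a \linkS4class{RateDataset}.
#' @export
RateDataset <- function(conc, rate, sd) {
  conc <- as.matrix(conc); rate <- as.matrix(rate)
  if (!is.matrix(sd))
    sd <- matrix(sd, nrow(conc), ncol(conc), byrow = length(sd) > 1L)
  new("RateDataset", conc = conc, rate = rate, sd = sd)
}

#' @export
setMethod("nSpecies", "RateDataset", function(x) ncol(x@conc))

#' @export
setMethod("nSamples", "RateDataset", function(x) nrow(x@conc))

#' @export
setMethod("concentrations", "RateDataset", function(x) x@conc)

#' @export
setMethod("measuredRates", "RateDataset", function(x) x@rate)

#' @export
setMethod("rateSD", "RateDataset", function(x) x@sd)

setMethod("show", "RateDataset", function(object) {
  cat(sprintf("RateDataset: %d samples x %d species\n",
              nSamples(object), nSpecies(object)))
})

#' Subset a rate dataset by sample index
#'
#' @param x a \linkS4class{RateDataset}.
#' @param i sample (row) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "RateDataset", function(x, i, j, ..., drop = FALSE) {
  RateDataset(x@conc[i, , drop = FALSE], x@rate[i, , drop = FALSE],
              x@sd[i, , drop = FALSE])
})

## ---------------------------------------------------------------------------
## LinearModel
## ---------------------------------------------------------------------------

#' Linear rate model
#'
#' The baseline approximation \eqn{dx_\mu/dt = \sum_\nu A_{\mu\nu} x_\nu}
#' (optionally plus an intercept \eqn{b_\mu}).
#'
#' @slot A J x J numeric interaction matrix.
#' @slot intercept length-J numeric; all zero unless fitted with an intercept.
#' @export
setClass("LinearModel",
         representation(A = "matrix", intercept = "numeric"))

setValidity("LinearModel", function(object) {
  if (nrow(object@A) != ncol(object@A)) return("A must be square")
  if (any(!is.finite(object@A))) return("A must be finite")
  if (length(object@intercept) != nrow(object@A))
    return("intercept must have length J")
  TRUE
})

#' @rdname LinearModel-class
#' @param A J x J numeric matrix.
#' @param intercept optional length-J numeric, default zero.
#' @export
LinearModel <- function(A, intercept = numeric(nrow(A))) {
  new("LinearModel", A = as.matrix(A), intercept = as.numeric(intercept))
}

#' @export
setMethod("nSpecies", "LinearModel", function(x) nrow(x@A))

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: J = %d species\n", nSpecies(object)))
})

## ---------------------------------------------------------------------------
## FitSettings
## ---------------------------------------------------------------------------

#' Settings for the alternating-regression fitter
#'
#' @slot priorWidth positive scalar: standard deviation \eqn{\varsigma_p} of
#'   the zero-mean Gaussian prior applied to every free parameter in the
#'   log-space ridge regressions. Default 0.1.
#' @slot relTol positive scalar: convergence threshold on the relative change
#'   of the (linear-space) penalized chi-squared between successive full
#'   production+degradation sweeps. Default 1e-2.
#' @slot maxIter positive integer: maximum number of sweeps. Default 100.
#' @export
setClass("FitSettings",
         representation(priorWidth = "numeric", relTol = "numeric",
                        maxIter = "integer"))

setValidity("FitSettings", function(object) {
  if (object@priorWidth <= 0) return("priorWidth must be positive")
  if (object@relTol <= 0) return("relTol must be positive")
  if (object@maxIter < 1L) return("maxIter must be at least 1")
  TRUE
})

#' @rdname FitSettings-class
#' @param priorWidth,relTol,maxIter see slot documentation.
#' @export
FitSettings <- function(priorWidth = 0.1, relTol = 1e-2, maxIter = 100L) {
  new("FitSettings", priorWidth = priorWidth, relTol = relTol,
      maxIter = as.integer(maxIter))
}

## ---------------------------------------------------------------------------
## ModelHierarchy
## ---------------------------------------------------------------------------

#' Nested hierarchy of S-system complexity
#'
#' An ordered list of strictly nested \linkS4class{ParameterMask}s: each
#' mask's free set contains the previous one's. The first mask frees exactly
#' the degradation prefactors and the diagonal production exponents (2J
#' parameters); the last frees all 2J(J+1).
#'
#' @slot masks list of \linkS4class{ParameterMask}.
#' @slot orderingKind `"nearest_neighbor"` or `"random"`.
#' @slot seed integer seed used for random orderings (NA otherwise).
#' @seealso [buildHierarchy()]
#' @export
setClass("ModelHierarchy",
         representation(masks = "list", orderingKind = "character",
                        seed = "integer"))

setValidity("ModelHierarchy", function(object) {
  ms <- object@masks
  if (length(ms) < 1L) return("hierarchy must contain at least one mask")
  for (k in seq_along(ms)) {
    if (!is(ms[[k]], "ParameterMask")) return("masks must be ParameterMask")
    if (k > 1L) {
      prev <- ms[[k - 1L]]; cur <- ms[[k]]
      if (any(prev@thetaG > cur@thetaG) || any(prev@thetaH > cur@thetaH))
        return(sprintf("mask %d is not a superset of mask %d", k, k - 1L))
      if (countFreeParameters(cur) <= countFreeParameters(prev))
        return("free-parameter counts must strictly increase")
    }
  }
  TRUE
})

#' @describeIn ModelHierarchy the list of masks, simplest first.
#' @param x a `ModelHierarchy`.
#' @export
hierarchyMasks <- function(x) x@masks

#' @export
setMethod("nSpecies", "ModelHierarchy", function(x) nSpecies(x@masks[[1L]]))

setMethod("show", "ModelHierarchy", function(object) {
  counts <- vapply(object@masks, countFreeParameters, integer(1))
  cat(sprintf("ModelHierarchy (%s): %d levels, free counts %s\n",
              object@orderingKind, length(object@masks),
              paste(counts, collapse = " ")))
})

## ---------------------------------------------------------------------------
## SelectionResult
## ---------------------------------------------------------------------------

#' Result of Bayesian model selection over a hierarchy
#'
#' Holds one record per candidate mask -- the fitted model, its penalized
#' chi-squared, the posterior-Hessian eigenvalues, the log-posterior score,
#' and the nominal and effective parameter counts -- plus the index of the
#' winning candidate (the score maximizer; ties go to fewer nominal
#' parameters).
#'
#' @slot records list of per-candidate lists with elements `mask`, `model`,
#'   `chi2Tilde`, `eigenvalues`, `logPosterior`, `nominalParams`,
#'   `effectiveParams`, `converged`, `failedSpecies`.
#' @slot winner integer index into `records`.
#' @export
setClass("SelectionResult",
         representation(records = "list", winner = "integer"))

#' @describeIn SelectionResult index of the winning candidate.
#' @param x a `SelectionResult`.
#' @export
winnerIndex <- function(x) x@winner

#' @describeIn SelectionResult the winning fitted \linkS4class{SSystemModel}.
#' @export
winningModel <- function(x) x@records[[x@winner]]$model

#' @describeIn SelectionResult per-candidate records (list).
#' @export
selectionRecords <- function(x) x@records

#' @describeIn SelectionResult one-row-per-candidate summary `data.frame`
#'   with columns `level`, `nominalParams`, `effectiveParams`, `chi2Tilde`,
#'   `logPosterior`, `converged`, `winner`.
#' @export
candidateSummary <- function(x) {
  recs <- x@records
  data.frame(
    level = seq_along(recs),
    nominalParams = vapply(recs, function(r) r$nominalParams, integer(1)),
    effectiveParams = vapply(recs, function(r) r$effectiveParams, integer(1)),
    chi2Tilde = vapply(recs, function(r) r$chi2Tilde, numeric(1)),
    logPosterior = vapply(recs, function(r) r$logPosterior, numeric(1)),
    converged = vapply(recs, function(r) isTRUE(r$converged), logical(1)),
    winner = seq_along(recs) == x@winner)
}

setMethod("show", "SelectionResult", function(object) {
  s <- candidateSummary(object)
  cat(sprintf("SelectionResult: %d candidates, winner at level %d (%d nominal, %d effective parameters)\n",
              nrow(s), object@winner, s$nominalParams[object@winner],
              s$effectiveParams[object@winner]))
})
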