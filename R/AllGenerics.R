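#' @include ssinfer-package.R
NULL

#' Number of species in an object
#'
#' @param x a \linkS4class{RateDataset}, \linkS4class{SSystemModel},
#'   \linkS4class{ParameterMask} or \linkS4class{LinearModel}.
#' @return integer scalar, the number of dynamical variables J.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Number of samples in a rate dataset
#'
#' @param x a \linkS4class{RateDataset}.
#' @return integer scalar N.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Accessors for rate datasets
#'
#' `concentrations()` returns the N x J matrix of measured concentrations
#' (assumed noise-free), `measuredRates()` the N x J matrix of measured rates
#' of change, and `rateSD()` the N x J matrix of rate standard errors.
#'
#' @param x a \linkS4class{RateDataset}.
#' @return a numeric N x J matrix.
#' @name dataset-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname dataset-accessors
#' @export
setGeneric("measuredRates", function(x) standardGeneric("measuredRates"))

#' @rdname dataset-accessors
#' @export
setGeneric("rateSD", function(x) standardGeneric("rateSD"))

#' Evaluate the production term of an S-system
#'
#' @param model an \linkS4class{SSystemModel}.
#' @param x strictly positive numeric vector of length J (concentrations).
#' @return strictly positive numeric vector of length J.
#' @export
setGeneric("evaluateProduction",
           function(model, x) standardGeneric("evaluateProduction"))

#' Evaluate the degradation term of an S-system
#'
#' @inheritParams evaluateProduction
#' @return strictly positive numeric vector of length J.
#' @export
setGeneric("evaluateDegradation",
           function(model, x) standardGeneric("evaluateDegradation"))

#' Evaluate the net rate of an S-system at a state
#'
#' @inheritParams evaluateProduction
#' @return numeric vector of length J, production minus degradation.
#' @export
setGeneric("evaluateRate", function(model, x) standardGeneric("evaluateRate"))

#' Predict rates for a matrix of states
#'
#' @param model an \linkS4class{SSystemModel} or \linkS4class{LinearModel}.
#' @param x numeric N x J matrix of states (strictly positive for S-systems).
#' @return numeric N x J matrix of predicted rates.
#' @export
setGeneric("predictRates", function(model, x) standardGeneric("predictRates"))

#' Count free (inferable) parameters
#'
#' @param x a \linkS4class{ParameterMask} or \linkS4class{SSystemModel}.
#' @return nonnegative integer, the number of mask entries flagged free.
#' @export
setGeneric("countFreeParameters",
           function(x) standardGeneric("countFreeParameters"))

#' Weighted goodness of fit of a rate model
#'
#' `chiSquared()` is the weighted sum of squared rate residuals
#' \deqn{\chi^2 = \sum_{i,\mu} \left(\frac{x'_{i\mu} - X'_\mu(x_i)}
#'   {\sigma'_{i\mu}}\right)^2,}
#' and `chiSquaredTilde()` adds the Gaussian-prior penalty
#' \eqn{\sum_k P_k^2/\varsigma_k^2} over the free parameters.
#'
#' @param model an \linkS4class{SSystemModel} or \linkS4class{LinearModel}.
#' @param data a \linkS4class{RateDataset}.
#' @param priorWidth positive scalar prior standard deviation
#'   \eqn{\varsigma} shared by all free parameters (tilde version only).
#' @return numeric scalar.
#' @export
setGeneric("chiSquared", function(model, data) standardGeneric("chiSquared"))

#' @rdname chiSquared
#' @export
setGeneric("chiSquaredTilde", function(model, data, priorWidth)
  standardGeneric("chiSquaredTilde"))

#' Pack the free parameters of a model into a flat vector
#'
#' The ordering is stable and documented: free entries of the production
#' parameter matrix \eqn{P^{(G)}} (prefactor row first, then exponent rows) in
#' row-major order, followed by the free entries of \eqn{P^{(H)}} in the same
#' order. This ordering is used for Hessians and serialization.
#'
#' @param model an \linkS4class{SSystemModel}.
#' @return numeric vector of length `countFreeParameters(model)`.
#' @seealso [unpackParameters()]
#' @export
setGeneric("packParameters", function(model) standardGeneric("packParameters"))
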