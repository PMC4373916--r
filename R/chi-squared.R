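#' @include ssystem-model.R
NULL

.chi2 <- function(model, data) {
  res <- (measuredRates(data) - predictRates(model, concentrations(data))) /
    rateSD(data)
  sum(res * res)
}

#' @export
setMethod("chiSquared", signature("SSystemModel", "RateDataset"), .chi2)

#' @export
setMethod("chiSquared", signature("LinearModel", "RateDataset"), .chi2)

#' @export
setMethod("chiSquaredTilde", signature("SSystemModel", "RateDataset"),
          function(model, data, priorWidth) {
            p <- packParameters(model)
            .chi2(model, data) + sum(p * p) / priorWidth^2
          })
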