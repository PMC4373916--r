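#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Rate datasets: delimited text, one row per sample, header
## x_1..x_J, xprime_1..xprime_J, sigma_1..sigma_J
## ---------------------------------------------------------------------------

#' Read / write rate datasets as CSV
#'
#' The on-disk format is a comma-separated file with one row per sample and
#' a header of three J-column blocks: `x_1..x_J` (concentrations),
#' `xprime_1..xprime_J` (measured rates), `sigma_1..sigma_J` (rate standard
#' errors). J is inferred from the header. Validation errors name the
#' offending row and column.
#'
#' @param path file path.
#' @return `readRateDataset()` returns a \linkS4class{RateDataset}.
#' @export
readRateDataset <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)
  J <- sum(grepl("^x_[0-9]+$", nm))
  if (J < 1L) stop("no x_<j> columns found in ", path)
  need <- c(paste0("x_", 1:J), paste0("xprime_", 1:J), paste0("sigma_", 1:J))
  missing <- setdiff(need, nm)
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(df[, paste0("x_", 1:J)])
  xp <- as.matrix(df[, paste0("xprime_", 1:J)])
  sg <- as.matrix(df[, paste0("sigma_", 1:J)])
  for (blk in list(list(m = x, n = "x", pos = TRUE),
                   list(m = sg, n = "sigma", pos = TRUE))) {
    bad <- which(!is.finite(blk$m) | blk$m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("nonpositive or missing %s value at row %d, column %s_%d",
                   blk$n, bad[1L, 1L], blk$n, bad[1L, 2L]))
  }
  bad <- which(!is.finite(xp), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing rate value at row %d, column xprime_%d",
                 bad[1L, 1L], bad[1L, 2L]))
  RateDataset(conc = unname(x), rate = unname(xp), sd = unname(sg))
}

#' @rdname readRateDataset
#' @param data a \linkS4class{RateDataset}.
#' @export
writeRateDataset <- function(data, path) {
  J <- nSpecies(data)
  m <- cbind(concentrations(data), measuredRates(data), rateSD(data))
  ## %.17g guarantees an exact double round trip through text
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(c(paste0("x_", 1:J), paste0("xprime_", 1:J),
                       paste0("sigma_", 1:J)), collapse = ","), txt), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Models and masks: JSON
## ---------------------------------------------------------------------------

.maskToList <- function(mask) {
  list(thetaG = unname(apply(mask@thetaG, 1L, as.integer, simplify = FALSE)),
       thetaH = unname(apply(mask@thetaH, 1L, as.integer, simplify = FALSE)))
}

.maskFromList <- function(lst, J) {
  ParameterMask(J,
                thetaG = matrix(as.numeric(unlist(lst$thetaG)),
                                J + 1L, J, byrow = TRUE),
                thetaH = matrix(as.numeric(unlist(lst$thetaH)),
                                J + 1L, J, byrow = TRUE))
}

#' Read / write S-system models as JSON
#'
#' A model file stores J, the free-parameter mask (row lists of 0/1 flags)
#' and only the free parameter values, in the stable packed order of
#' [packParameters()]; fixed parameters are implicit (default 0). Numeric
#' values are written with full precision so the round trip is bit-exact.
#'
#' @param path file path.
#' @return `readModel()` returns an \linkS4class{SSystemModel}.
#' @export
readModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "ssinfer-model")
    stop("not an ssinfer model file: ", path)
  J <- as.integer(doc$J)
  mask <- .maskFromList(doc$mask, J)
  theta <- vapply(doc$parameters, as.numeric, numeric(1))
  unpackParameters(theta, mask)
}

#' @rdname readModel
#' @param model an \linkS4class{SSystemModel}.
#' @export
writeModel <- function(model, path) {
  doc <- list(format = "ssinfer-model", version = 1L, J = model@J,
              mask = .maskToList(modelMask(model)),
              parameters = as.list(packParameters(model)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read / write parameter masks as JSON
#'
#' @param path file path.
#' @return `readMask()` returns a \linkS4class{ParameterMask}.
#' @export
readMask <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "ssinfer-mask")
    stop("not an ssinfer mask file: ", path)
  .maskFromList(doc$mask, as.integer(doc$J))
}

#' @rdname readMask
#' @param mask a \linkS4class{ParameterMask}.
#' @export
writeMask <- function(mask, path) {
  doc <- list(format = "ssinfer-mask", version = 1L, J = nSpecies(mask),
              mask = .maskToList(mask))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Selection results: JSON
## ---------------------------------------------------------------------------

.SCHEMA_VERSION <- 1L

#' Read / write selection results as JSON
#'
#' Serializes every per-candidate record (mask, fitted free parameters,
#' penalized chi-squared, Hessian eigenvalues, log-posterior score, nominal
#' and effective parameter counts, convergence flags) plus the winner index.
#' Files carry a schema version; a mismatch is reported rather than
#' silently misread.
#'
#' @param path file path.
#' @return `readSelectionResult()` returns a \linkS4class{SelectionResult}.
#' @export
readSelectionResult <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "ssinfer-selection")
    stop("not an ssinfer selection-result file: ", path)
  if (as.integer(doc$version) != .SCHEMA_VERSION)
    stop(sprintf("selection-result schema version mismatch: file has %s, expected %d",
                 doc$version, .SCHEMA_VERSION))
  J <- as.integer(doc$J)
  records <- lapply(doc$records, function(r) {
    mask <- .maskFromList(r$mask, J)
    theta <- vapply(r$parameters, as.numeric, numeric(1))
    list(mask = mask, model = unpackParameters(theta, mask),
         chi2Tilde = as.numeric(r$chi2Tilde),
         eigenvalues = vapply(r$eigenvalues, as.numeric, numeric(1)),
         logPosterior = as.numeric(r$logPosterior),
         nominalParams = as.integer(r$nominalParams),
         effectiveParams = as.integer(r$effectiveParams),
         converged = isTRUE(r$converged),
         iterations = as.integer(r$iterations),
         failedSpecies = vapply(r$failedSpecies, as.integer, integer(1)))
  })
  new("SelectionResult", records = records,
      winner = as.integer(doc$winner))
}

#' @rdname readSelectionResult
#' @param result a \linkS4class{SelectionResult}.
#' @export
writeSelectionResult <- function(result, path) {
  recs <- lapply(selectionRecords(result), function(r) list(
    mask = .maskToList(r$mask),
    parameters = as.list(packParameters(r$model)),
    chi2Tilde = r$chi2Tilde,
    eigenvalues = as.list(r$eigenvalues),
    logPosterior = r$logPosterior,
    nominalParams = r$nominalParams,
    effectiveParams = r$effectiveParams,
    converged = isTRUE(r$converged),
    iterations = if (is.null(r$iterations)) NA_integer_ else r$iterations,
    failedSpecies = as.list(r$failedSpecies)))
  doc <- list(format = "ssinfer-selection", version = .SCHEMA_VERSION,
              J = nSpecies(selectionRecords(result)[[1L]]$mask),
              winner = winnerIndex(result), records = recs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Run configuration: YAML
## ---------------------------------------------------------------------------

.runConfigDefaults <- function() list(
  seed = 0L,
  methods = c("linear", "full_ssystem", "adaptive_ssystem"),
  N = c(10, 20, 40, 80, 150, 300),
  T = 5,
  realizations = 10L,
  priorWidthFit = 0.1,
  priorWidthSelect = 10,
  relTol = 1e-2,
  maxIter = 100L,
  ordering = "nearest_neighbor",
  nSamples = 100L,
  tTrain = 5,
  tTest = 5,
  noiseFactor = 0.5,
  widenFactor = 0.25)

#' Read an experiment/run configuration from YAML
#'
#' Known keys (with defaults matching the benchmark protocol:
#' `priorWidthFit = 0.1`, `relTol = 1e-2`, `noiseFactor = 0.5`,
#' `tTest = 5`, ...) are merged over the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  defaults <- .runConfigDefaults()
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
  modifyList(defaults, cfg)
}
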