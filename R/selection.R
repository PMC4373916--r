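#' @include altreg.R
NULL

## ---------------------------------------------------------------------------
## Model hierarchy
## ---------------------------------------------------------------------------

#' Build a nested complexity hierarchy of S-system masks
#'
#' The nearest-neighbor ordering grows the free-parameter set in the order:
#' degradation prefactors plus diagonal production exponents (the simplest
#' 2J-parameter model); then the diagonal degradation exponents; then the
#' production prefactors; then off-diagonal production exponents in rings of
#' increasing neighbor distance d = 1, ..., J-1 (all pairs with
#' mu - nu = d mod J, J parameters per ring); then off-diagonal degradation
#' exponents in the same order. For J >= 2 this gives 2J+1 masks ending with
#' all 2J(J+1) parameters free.
#'
#' The random ordering keeps the same mandatory first mask and then adds the
#' remaining 2J^2 parameters in a seed-determined random order, in
#' consecutive groups of J (matching the growth granularity of the
#' nearest-neighbor hierarchy).
#'
#' @param J positive integer, number of species.
#' @param orderingKind `"nearest_neighbor"` (default) or `"random"`.
#' @param seed integer seed for the random ordering.
#' @return a \linkS4class{ModelHierarchy}.
#' @examples
#' h <- buildHierarchy(7)
#' length(hierarchyMasks(h))                          # 15
#' countFreeParameters(hierarchyMasks(h)[[15]])       # 112
#' @export
buildHierarchy <- function(J, orderingKind = c("nearest_neighbor", "random"),
                           seed = 0L) {
  orderingKind <- match.arg(orderingKind)
  J <- as.integer(J)
  if (J < 1L) stop("J must be a positive integer")

  ## parameter ids: list of (which = "G"/"H", row kappa in 1..1+J, col mu)
  baseG <- matrix(0, J + 1L, J); baseH <- matrix(0, J + 1L, J)
  baseH[1L, ] <- 1                               # log beta
  baseG[cbind(1L + seq_len(J), seq_len(J))] <- 1 # g diagonal
  masks <- list(ParameterMask(J, thetaG = baseG, thetaH = baseH))

  addGroup <- function(tg, th, idx) {
    ## idx: 3-column matrix (term 1=G/2=H, kappa, mu)
    for (r in seq_len(nrow(idx))) {
      if (idx[r, 1L] == 1L) tg[idx[r, 2L], idx[r, 3L]] <- 1
      else th[idx[r, 2L], idx[r, 3L]] <- 1
    }
    list(tg = tg, th = th)
  }

  ringIdx <- function(term, d) {
    mu <- seq_len(J)
    nu <- ((mu - 1L - d) %% J) + 1L              # mu - nu = d (mod J)
    cbind(term, 1L + nu, mu)                     # exponent of nu in row 1+nu
  }

  groups <- list()
  groups[[1L]] <- cbind(2L, 1L + seq_len(J), seq_len(J))  # h diagonal
  groups[[2L]] <- cbind(1L, 1L, seq_len(J))               # log alpha
  if (J >= 2L) {
    for (d in seq_len(J - 1L)) groups[[length(groups) + 1L]] <- ringIdx(1L, d)
    for (d in seq_len(J - 1L)) groups[[length(groups) + 1L]] <- ringIdx(2L, d)
  }

  if (orderingKind == "random") {
    all_ <- do.call(rbind, groups)
    perm <- withSeed(seed, sample.int(nrow(all_)))
    all_ <- all_[perm, , drop = FALSE]
    groups <- split.data.frame(all_,
                               rep(seq_len(ceiling(nrow(all_) / J)),
                                   each = J, length.out = nrow(all_)))
    groups <- lapply(groups, as.matrix)
  }

  tg <- baseG; th <- baseH
  for (grp in groups) {
    upd <- addGroup(tg, th, grp)
    tg <- upd$tg; th <- upd$th
    masks[[length(masks) + 1L]] <- ParameterMask(J, thetaG = tg, thetaH = th)
  }
  new("ModelHierarchy", masks = masks, orderingKind = orderingKind,
      seed = if (orderingKind == "random") as.integer(seed) else NA_integer_)
}

## ---------------------------------------------------------------------------
## Fast penalized chi-squared machinery
## ---------------------------------------------------------------------------

## Returns a closure evaluating 0.5 * chiSquaredTilde for a whole matrix of
## packed parameter vectors at once (columns = evaluations); used by the
## finite-difference Hessian, where tens of thousands of evaluations per
## model would otherwise dominate the runtime.
.makeHalfChi2Fun <- function(data, mask, priorWidth, chunk = 2048L) {
  x <- concentrations(data); xp <- measuredRates(data); sg <- rateSD(data)
  N <- nrow(x); J <- ncol(x)
  D <- cbind(1, log(x))
  K1 <- J * (J + 1L)                        # entries per parameter matrix
  flagsG <- which(.rowMajor(mask@thetaG) == 1)
  flagsH <- which(.rowMajor(mask@thetaH) == 1)
  nG <- length(flagsG); nH <- length(flagsH)
  repJ <- rep(seq_len(J), 1L)

  evalChunk <- function(theta) {
    E <- ncol(theta)
    ## scatter the packed vectors into stacked transposed parameter matrices
    VG <- numeric(K1 * E); VH <- numeric(K1 * E)
    if (nG) VG[rep(flagsG, E) + rep((seq_len(E) - 1L) * K1, each = nG)] <-
        as.vector(theta[seq_len(nG), , drop = FALSE])
    if (nH) VH[rep(flagsH, E) + rep((seq_len(E) - 1L) * K1, each = nH)] <-
        as.vector(theta[nG + seq_len(nH), , drop = FALSE])
    ## V* hold t(P) stacked; convert to (1+J) x (J*E) column blocks
    PG <- matrix(aperm(array(VG, c(J, J + 1L, E)), c(2L, 1L, 3L)), J + 1L)
    PH <- matrix(aperm(array(VH, c(J, J + 1L, E)), c(2L, 1L, 3L)), J + 1L)
    rates <- exp(D %*% PG) - exp(D %*% PH)
    res <- (matrix(xp[, rep(seq_len(J), E)], N) - rates) /
      matrix(sg[, rep(seq_len(J), E)], N)
    chi <- colSums(matrix(colSums(res * res), J, E))
    0.5 * (chi + colSums(theta * theta) / priorWidth^2)
  }

  function(theta) {
    theta <- as.matrix(theta)
    E <- ncol(theta)
    out <- numeric(E)
    for (s in seq(1L, E, by = chunk)) {
      e <- min(s + chunk - 1L, E)
      out[s:e] <- evalChunk(theta[, s:e, drop = FALSE])
    }
    out
  }
}

## Single-evaluation objective + analytic gradient of chiSquaredTilde with
## respect to the packed free-parameter vector.
.makeChi2Grad <- function(data, mask, priorWidth) {
  x <- concentrations(data); xp <- measuredRates(data); sg <- rateSD(data)
  D <- cbind(1, log(x))
  isg2 <- 1 / (sg * sg)
  flagsG <- .rowMajor(mask@thetaG) == 1
  flagsH <- .rowMajor(mask@thetaH) == 1
  J <- ncol(x); nG <- sum(flagsG)
  pw2 <- priorWidth^2
  list(
    fn = function(p) {
      PG <- .rowMajorAssign(J, p[seq_len(nG)], t(mask@thetaG))
      PH <- .rowMajorAssign(J, p[nG + seq_len(length(p) - nG)],
                            t(mask@thetaH))
      rates <- exp(D %*% PG) - exp(D %*% PH)
      if (any(!is.finite(rates))) return(1e15 * (1 + sum(p * p)))
      sum((rates - xp)^2 * isg2) + sum(p * p) / pw2
    },
    gr = function(p) {
      PG <- .rowMajorAssign(J, p[seq_len(nG)], t(mask@thetaG))
      PH <- .rowMajorAssign(J, p[nG + seq_len(length(p) - nG)],
                            t(mask@thetaH))
      Gm <- exp(D %*% PG); Hm <- exp(D %*% PH)
      rates <- Gm - Hm
      if (any(!is.finite(rates))) return(2 * p)
      q <- (rates - xp) * isg2
      gPG <- 2 * crossprod(D, q * Gm)
      gPH <- -2 * crossprod(D, q * Hm)
      c(.rowMajor(gPG)[flagsG], .rowMajor(gPH)[flagsH]) + 2 * p / pw2
    })
}

#' Refine a fitted S-system to the penalized-likelihood optimum
#'
#' Quasi-Newton (BFGS, analytic gradient) minimization of the penalized
#' linear-space chi-squared over the free parameters, started from the given
#' model. The log-space alternating updates are fast but not guaranteed to
#' decrease the linear-space objective when the model class cannot represent
#' the data; the selection score requires the actual penalized maximum
#' likelihood, so candidates are refined before scoring.
#'
#' @param model an \linkS4class{SSystemModel} (typically an [alternateFit()]
#'   result).
#' @param data the \linkS4class{RateDataset} being fitted.
#' @param priorWidth ridge prior standard deviation of the fit objective.
#' @param maxit BFGS iteration cap.
#' @return the refined \linkS4class{SSystemModel}.
#' @export
polishFit <- function(model, data, priorWidth = 0.1, maxit = 300L) {
  mask <- modelMask(model)
  if (countFreeParameters(mask) == 0L) return(model)
  fg <- .makeChi2Grad(data, mask, priorWidth)
  p0 <- packParameters(model)
  opt <- optim(p0, fn = fg$fn, gr = fg$gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  if (opt$value <= fg$fn(p0)) unpackParameters(opt$par, mask) else model
}

## ---------------------------------------------------------------------------
## Posterior Hessian, eigenvalues, score
## ---------------------------------------------------------------------------

#' Eigenvalues of the posterior Hessian of a fitted model
#'
#' Numerically estimates the Hessian of \eqn{\frac12 \tilde\chi^2} (the
#' negative posterior log-likelihood up to a constant) with respect to the
#' packed free-parameter vector, by central finite differences with
#' per-parameter step `max(relStep * |p_k|, absStep)`, symmetrizes it as
#' \eqn{(H + H^T)/2}, and returns its eigenvalues in decreasing order.
#'
#' @param model a fitted \linkS4class{SSystemModel}.
#' @param data the \linkS4class{RateDataset} it was fitted to.
#' @param priorWidth prior standard deviation \eqn{\varsigma_k} used in the
#'   selection score (not necessarily the regression ridge width).
#' @param relStep,absStep finite-difference step controls.
#' @return numeric vector of eigenvalues, length `countFreeParameters(model)`
#'   (empty for a fully fixed model).
#' @export
hessianEigenvalues <- function(model, data, priorWidth,
                               relStep = 1e-4, absStep = 1e-6) {
  H <- posteriorHessian(model, data, priorWidth, relStep, absStep)
  if (nrow(H) == 0L) return(numeric(0))
  eigen(H, symmetric = TRUE, only.values = TRUE)$values
}

#' @rdname hessianEigenvalues
#' @return `posteriorHessian()` returns the symmetrized K x K Hessian matrix.
#' @export
posteriorHessian <- function(model, data, priorWidth,
                             relStep = 1e-4, absStep = 1e-6) {
  p0 <- packParameters(model)
  K <- length(p0)
  if (K == 0L) return(matrix(0, 0L, 0L))
  f <- .makeHalfChi2Fun(data, modelMask(model), priorWidth)
  h <- pmax(relStep * abs(p0), absStep)

  ## evaluation points: f0; +/- h_k; the four corners for each pair k<l
  pts <- matrix(p0, K, 1L + 2L * K + 2L * K * (K - 1L))
  col <- 1L
  for (k in seq_len(K)) {
    pts[k, col + 1L] <- p0[k] + h[k]
    pts[k, col + 2L] <- p0[k] - h[k]
    col <- col + 2L
  }
  pairFirst <- col + 1L
  if (K >= 2L) {
    for (k in seq_len(K - 1L)) for (l in seq(k + 1L, K)) {
      sg <- cbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
      for (c_ in 1:4) {
        pts[k, col + c_] <- p0[k] + sg[1L, c_] * h[k]
        pts[l, col + c_] <- p0[l] + sg[2L, c_] * h[l]
      }
      col <- col + 4L
    }
  }
  fv <- f(pts[, seq_len(col), drop = FALSE])
  if (any(!is.finite(fv))) {
    bad <- which(!is.finite(fv))[1L]
    stop(sprintf("non-finite objective while estimating the Hessian (evaluation %d)", bad))
  }

  f0 <- fv[1L]
  H <- matrix(0, K, K)
  for (k in seq_len(K))
    H[k, k] <- (fv[2L * k] - 2 * f0 + fv[2L * k + 1L]) / h[k]^2
  if (K >= 2L) {
    idx <- pairFirst
    for (k in seq_len(K - 1L)) for (l in seq(k + 1L, K)) {
      v <- (fv[idx] - fv[idx + 1L] - fv[idx + 2L] + fv[idx + 3L]) /
        (4 * h[k] * h[l])
      H[k, l] <- v; H[l, k] <- v
      idx <- idx + 4L
    }
  }
  if (any(!is.finite(H))) {
    bad <- which(!is.finite(H), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite Hessian entry for parameter pair (%d, %d)",
                 bad[1L], bad[2L]))
  }
  (H + t(H)) / 2
}

#' Laplace-approximate log posterior of a fitted model
#'
#' The selection score
#' \deqn{\mathcal{L}(M) = -\tfrac12 \tilde\chi^2(P_\mathrm{best})
#'   - \tfrac12 \sum_\mu \log\lambda_\mu
#'   - \tfrac12 \sum_k \log\varsigma_k^2,}
#' a Gaussian estimate of the Bayesian evidence that generalizes BIC by
#' weighting each parameter direction by its actual stiffness
#' \eqn{\lambda_\mu}. Eigenvalues are clipped below at `eigenFloor` before
#' the log; the default floor is the prior curvature
#' \eqn{1/\varsigma_k^2}, the analytic lower bound of the exact Hessian,
#' so a perfectly sloppy direction contributes exactly zero to the score.
#' Estimates below the floor (finite-difference scatter, or optima not
#' exactly reached) are counted in the `"nClipped"` attribute.
#'
#' @inheritParams hessianEigenvalues
#' @param eigenvalues optionally, precomputed [hessianEigenvalues()] output.
#' @param eigenFloor positive clipping floor for the eigenvalues; default
#'   `1/priorWidth^2`.
#' @return numeric scalar score (larger is better), with attribute
#'   `"nClipped"`.
#' @export
logPosterior <- function(model, data, priorWidth, eigenvalues = NULL,
                         eigenFloor = 1 / priorWidth^2) {
  if (is.null(eigenvalues))
    eigenvalues <- hessianEigenvalues(model, data, priorWidth)
  nClipped <- sum(eigenvalues < eigenFloor)
  lam <- pmax(eigenvalues, eigenFloor)
  K <- length(lam)
  score <- -0.5 * chiSquaredTilde(model, data, priorWidth) -
    0.5 * sum(log(lam)) - 0.5 * K * log(priorWidth^2)
  attr(score, "nClipped") <- nClipped
  score
}

#' Number of effective (stiff) parameters
#'
#' Directions with Hessian eigenvalue at most 1 are sloppy: the data do not
#' constrain them beyond the prior. The effective parameter count is the
#' number of eigenvalues strictly greater than 1.
#'
#' @param eigenvalues numeric vector of posterior-Hessian eigenvalues.
#' @return nonnegative integer.
#' @export
effectiveNumParameters <- function(eigenvalues) {
  as.integer(sum(eigenvalues > 1))
}

## ---------------------------------------------------------------------------
## Selection driver
## ---------------------------------------------------------------------------

#' Fit and score every level of a hierarchy, select the winner
#'
#' Each mask in the hierarchy is fitted by [alternateFit()] (ridge width
#' `settings@priorWidth`), then scored with [logPosterior()] under the
#' selection prior width `priorWidthSelect`. The winner maximizes the score;
#' ties are broken toward fewer nominal parameters. A candidate is excluded
#' from the argmax only if every species' fit failed.
#'
#' @param data a \linkS4class{RateDataset}.
#' @param hierarchy a \linkS4class{ModelHierarchy} (default: the
#'   nearest-neighbor hierarchy for the data's species count).
#' @param settings \linkS4class{FitSettings} for the alternating regression.
#' @param priorWidthSelect prior standard deviation \eqn{\varsigma_k} used in
#'   the selection score; default 10, wide enough that data-unconstrained
#'   directions have eigenvalue about \eqn{10^{-2} \ll 1}.
#' @param polish refine each candidate with [polishFit()] before scoring
#'   (default `TRUE`), so that the score expansion is taken at the penalized
#'   maximum likelihood.
#' @return a \linkS4class{SelectionResult}.
#' @export
selectModel <- function(data, hierarchy = buildHierarchy(nSpecies(data)),
                        settings = FitSettings(), priorWidthSelect = 10,
                        polish = TRUE) {
  masks <- hierarchyMasks(hierarchy)
  records <- vector("list", length(masks))
  for (k in seq_along(masks)) {
    fit <- withCallingHandlers(
      alternateFit(data, masks[[k]], settings),
      warning = function(w) invokeRestart("muffleWarning"))
    if (polish)
      fit$model <- polishFit(fit$model, data, settings@priorWidth)
    allFailed <- length(fit$failedSpecies) == nSpecies(data)
    lam <- if (allFailed) numeric(0) else
      hessianEigenvalues(fit$model, data, priorWidthSelect)
    score <- if (allFailed) -Inf else
      logPosterior(fit$model, data, priorWidthSelect, eigenvalues = lam)
    records[[k]] <- list(
      mask = masks[[k]], model = fit$model,
      chi2Tilde = chiSquaredTilde(fit$model, data, priorWidthSelect),
      eigenvalues = lam,
      logPosterior = as.numeric(score),
      nominalParams = countFreeParameters(masks[[k]]),
      effectiveParams = effectiveNumParameters(lam),
      converged = fit$converged, iterations = fit$iterations,
      failedSpecies = fit$failedSpecies)
  }
  scores <- vapply(records, function(r) r$logPosterior, numeric(1))
  nominal <- vapply(records, function(r) r$nominalParams, integer(1))
  if (all(!is.finite(scores)))
    stop("every candidate fit failed; no model can be selected")
  ord <- order(-scores, nominal)
  new("SelectionResult", records = records, winner = as.integer(ord[1L]))
}
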