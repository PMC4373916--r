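#' @include chi-squared.R
NULL

## Alternating log-space ridge regression for masked S-systems.
##
## Each of the production and degradation terms is linear in its parameters
## in log space, so holding one term fixed the other is fit by weighted ridge
## regression; the two half-steps alternate until the penalized linear-space
## chi-squared stops changing.

#' Log-space regression targets for one alternating half-step
#'
#' For the production half-step the target is
#' \eqn{Y^{(G)}_{i\mu} = \log(H_\mu(x_i) + x'_{i\mu})}; for the degradation
#' half-step \eqn{Y^{(H)}_{i\mu} = \log(G_\mu(x_i) - x'_{i\mu})}. Entries
#' whose log argument is nonpositive correspond to rates that cannot be
#' matched by adjusting this term alone; they are flagged invalid (and later
#' given zero weight) rather than raising an error.
#'
#' @param model current \linkS4class{SSystemModel} iterate.
#' @param data a \linkS4class{RateDataset} with the same number of species.
#' @param term `"production"` or `"degradation"`.
#' @return list with `Y` (N x J matrix, `NA` where invalid) and `valid`
#'   (N x J logical matrix).
#' @export
computeTargets <- function(model, data,
                           term = c("production", "degradation")) {
  term <- match.arg(term)
  if (nSpecies(model) != nSpecies(data))
    stop("model and data disagree on the number of species")
  D <- cbind(1, log(concentrations(data)))
  arg <- if (term == "production") {
    exp(D %*% .phMatrix(model)) + measuredRates(data)
  } else {
    exp(D %*% .pgMatrix(model)) - measuredRates(data)
  }
  valid <- is.finite(arg) & arg > 0
  Y <- matrix(NA_real_, nrow(arg), ncol(arg))
  Y[valid] <- log(arg[valid])
  list(Y = Y, valid = valid)
}

#' Regression weights for the log-space targets
#'
#' Residuals in log space are weighted by the Jacobian of the exp transform
#' over the rate uncertainty, \eqn{W_{i\mu} = e^{Y_{i\mu}}/\sigma'_{i\mu}};
#' invalid entries get weight exactly 0, removing them from the regression at
#' this iteration.
#'
#' @param Y N x J target matrix from [computeTargets()].
#' @param sigmaPrime N x J matrix of rate uncertainties.
#' @param valid N x J logical validity matrix.
#' @return N x J nonnegative weight matrix.
#' @export
computeWeights <- function(Y, sigmaPrime, valid) {
  stopifnot(identical(dim(Y), dim(sigmaPrime)),
            identical(dim(Y), dim(valid)))
  W <- matrix(0, nrow(Y), ncol(Y))
  W[valid] <- exp(Y[valid]) / sigmaPrime[valid]
  W[!is.finite(W)] <- 0                # overflowed targets carry no signal
  W
}

#' Masked weighted ridge regression for one species
#'
#' Solves the per-species log-space problem: with the masked, weighted design
#' \eqn{(\check D)_{i\nu} = W_i D_{i\nu} \theta_\nu} and target
#' \eqn{\check Y_i = W_i Y_i}, returns
#' \deqn{P = \left(\check D^T \check D + \varsigma_p^{-2} I +
#'   \mathrm{diag}(1-\theta)\right)^{-1} \check D^T \check Y,}
#' where the \eqn{\mathrm{diag}(1-\theta)} term removes the singularities of
#' the fixed directions, whose solution entries are exactly 0. With all
#' weights zero the result is the zero vector.
#'
#' @param D N x (1+J) design matrix: a column of ones, then the log
#'   concentrations.
#' @param y length-N target column (`NA` allowed where `w` is 0).
#' @param w length-N nonnegative weights.
#' @param theta length-(1+J) 0/1 free-flags for this species' parameters.
#' @param priorWidth positive ridge prior standard deviation.
#' @return length-(1+J) parameter vector; entries with `theta == 0` are 0.
#' @export
maskedRidgeSolve <- function(D, y, w, theta, priorWidth) {
  stopifnot(length(y) == nrow(D), length(w) == nrow(D),
            length(theta) == ncol(D), priorWidth > 0, all(w >= 0))
  y[w == 0] <- 0                       # masked-out entries cannot contribute
  K <- ncol(D)
  Dc <- (D * w) * rep(theta, each = nrow(D))
  ## solve the ridge system as an augmented least-squares problem by QR:
  ## numerically equivalent to the regularized normal equations but stable
  ## under the large dynamic range of the weights
  A <- rbind(Dc, diag(1 / priorWidth, K), diag(sqrt(1 - theta), K))
  b <- c(w * y, numeric(2L * K))
  p <- as.vector(qr.coef(qr(A, LAPACK = TRUE), b))
  if (any(!is.finite(p)))
    stop("masked ridge system unexpectedly singular after regularization")
  p[theta == 0] <- 0
  p
}

#' Fit a masked S-system by alternating regression
#'
#' Starting from the default model (all parameters 0, i.e. unit prefactors
#' and zero exponents), alternately fits the production parameters holding
#' degradation fixed and vice versa, each by [maskedRidgeSolve()] applied
#' species by species. Convergence is declared when the relative change of
#' the penalized linear-space chi-squared ([chiSquaredTilde()]) between
#' successive full sweeps falls below `settings@relTol`. Because the
#' regression optimizes a log-space objective, the linear-space objective is
#' not guaranteed to decrease monotonically; the best iterate seen is kept
#' and returned if the final one is worse.
#'
#' @param data a \linkS4class{RateDataset}.
#' @param mask a \linkS4class{ParameterMask} defining which parameters are
#'   inferred.
#' @param settings a \linkS4class{FitSettings}.
#' @return list with elements:
#'   \describe{
#'     \item{model}{the fitted \linkS4class{SSystemModel}: the best
#'       (lowest penalized linear-space chi-squared) iterate seen}
#'     \item{finalModel}{the last iterate with a finite objective -- the
#'       raw outcome of the alternation without the best-iterate guard,
#'       which at small sample sizes can be a much poorer predictor}
#'     \item{iterations}{number of full sweeps performed}
#'     \item{converged}{logical}
#'     \item{failedSpecies}{integer indices of species whose weights were all
#'       zero in every half-step (parameters left at defaults)}
#'     \item{diagnostics}{per-sweep data.frame with linear-space
#'       `chi2Tilde`, log-space `chi2LogSpace`, and the fraction of
#'       invalidated datapoints in each half-step}
#'   }
#' @examples
#' set.seed(1)
#' truth <- SSystemModel(2, logAlpha = c(0.2, -0.1),
#'                       g = matrix(c(0.5, 0, 0, 0.3), 2, 2),
#'                       h = matrix(c(0.8, 0.1, 0, 0.6), 2, 2))
#' x <- matrix(exp(runif(100, -0.5, 0.5)), 50, 2)
#' d <- RateDataset(x, predictRates(truth, x), sd = 0.05)
#' fit <- alternateFit(d, modelMask(truth), FitSettings())
#' fit$converged
#' @export
alternateFit <- function(data, mask, settings = FitSettings()) {
  J <- nSpecies(data)
  if (nSpecies(mask) != J)
    stop("mask and data disagree on the number of species")
  sw <- settings@priorWidth
  D <- cbind(1, log(concentrations(data)))
  sg <- rateSD(data)
  model <- SSystemModel(J, mask = mask)

  if (countFreeParameters(mask) == 0L)
    return(list(model = model, finalModel = model, iterations = 1L,
                converged = TRUE, failedSpecies = integer(0),
                diagnostics = data.frame(
                  sweep = 1L, chi2Tilde = chiSquaredTilde(model, data, sw),
                  chi2LogSpace = NA_real_, invalidFracG = NA_real_,
                  invalidFracH = NA_real_)))

  halfStep <- function(model, term) {
    tg <- computeTargets(model, data, term)
    W <- computeWeights(tg$Y, sg, tg$valid)
    theta <- if (term == "production") mask@thetaG else mask@thetaH
    P <- if (term == "production") .pgMatrix(model) else .phMatrix(model)
    anyW <- logical(J)
    for (mu in seq_len(J)) {
      anyW[mu] <- any(W[, mu] > 0)
      if (anyW[mu] || any(theta[, mu] == 0))
        P[, mu] <- maskedRidgeSolve(D, tg$Y[, mu], W[, mu], theta[, mu], sw)
    }
    ## log-space penalized objective of this half-step, for diagnostics
    res <- (tg$Y - D %*% P)
    res[!tg$valid] <- 0
    chiY <- sum((W * res)^2) + sum(P[theta == 1]^2) / sw^2
    list(P = P, invalidFrac = mean(!tg$valid), anyWeight = anyW, chiY = chiY)
  }

  chiPrev <- chiSquaredTilde(model, data, sw)
  best <- model; bestChi <- chiPrev
  lastFinite <- model
  everWeighted <- logical(J)
  diag_ <- vector("list", settings@maxIter)
  converged <- FALSE
  iterations <- 0L

  for (it in seq_len(settings@maxIter)) {
    iterations <- it
    gstep <- halfStep(model, "production")
    model <- .modelFromP(gstep$P, .phMatrix(model), mask)
    hstep <- halfStep(model, "degradation")
    model <- .modelFromP(.pgMatrix(model), hstep$P, mask)
    everWeighted <- everWeighted | gstep$anyWeight | hstep$anyWeight

    chi <- chiSquaredTilde(model, data, sw)
    diag_[[it]] <- data.frame(sweep = it, chi2Tilde = chi,
                              chi2LogSpace = hstep$chiY,
                              invalidFracG = gstep$invalidFrac,
                              invalidFracH = hstep$invalidFrac)
    if (is.finite(chi)) lastFinite <- model
    if (is.finite(chi) && chi < bestChi) { best <- model; bestChi <- chi }
    if (is.finite(chi) && abs(chi - chiPrev) <= settings@relTol * abs(chiPrev)) {
      converged <- TRUE
      break
    }
    ## the log-space updates are not guaranteed to decrease the linear-space
    ## objective; once it has run away from the best iterate by many orders
    ## of magnitude further sweeps only amplify, so stop and keep the best
    if (!is.finite(chi) || chi > 1e6 * bestChi) break
    chiPrev <- chi
  }

  failed <- which(!everWeighted &
                  (colSums(mask@thetaG) + colSums(mask@thetaH)) > 0)
  if (length(failed)) {
    PG <- .pgMatrix(best); PH <- .phMatrix(best)
    PG[, failed] <- 0; PH[, failed] <- 0
    best <- .modelFromP(PG, PH, mask)
    warning(sprintf("alternating regression failed for species %s (all weights zero); parameters left at defaults",
                    paste(failed, collapse = ", ")))
  }
  list(model = best, finalModel = lastFinite, iterations = iterations,
       converged = converged, failedSpecies = failed,
       diagnostics = do.call(rbind, diag_))
}
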