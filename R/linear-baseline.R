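#' @include chi-squared.R
NULL

#' Fit the weighted linear-regression baseline
#'
#' Fits \eqn{dx_\mu/dt = \sum_\nu A_{\mu\nu} x_\nu} by minimizing the
#' weighted squared rate residuals with weights \eqn{1/\sigma'^2}, solved
#' species by species. There is no intercept by default (the model form has
#' none) and no ridge prior ("simple linear regression"); both are available
#' as options. Rank-deficient designs fall back to the minimum-norm solution
#' with a warning.
#'
#' @param data a \linkS4class{RateDataset}.
#' @param intercept logical; add a per-species intercept term. Default
#'   `FALSE`.
#' @param ridge nonnegative ridge penalty \eqn{1/\varsigma^2} added to the
#'   normal equations for conditioning. Default 0.
#' @return a \linkS4class{LinearModel}.
#' @examples
#' A <- matrix(c(-1, 0.5, 0, -2), 2, 2)
#' x <- matrix(runif(40, 0.5, 2), 20, 2)
#' d <- RateDataset(x, x %*% t(A), sd = 0.1)
#' max(abs(fitLinear(d)@A - A)) < 1e-8
#' @export
fitLinear <- function(data, intercept = FALSE, ridge = 0) {
  x <- concentrations(data); xp <- measuredRates(data); sg <- rateSD(data)
  J <- ncol(x)
  X <- if (intercept) cbind(1, x) else x
  K <- ncol(X)
  coefs <- matrix(0, J, K)
  for (mu in seq_len(J)) {
    w <- 1 / sg[, mu]
    Xw <- X * w
    yw <- xp[, mu] * w
    M <- crossprod(Xw) + diag(ridge, K)
    p <- tryCatch(solve(M, crossprod(Xw, yw)), error = function(e) NULL)
    if (is.null(p) || rcond(M) < 1e-12) {
      ## minimum-norm solution via the pseudoinverse
      sv <- svd(Xw)
      pos <- sv$d > max(sv$d) * 1e-12
      p <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], yw)) / sv$d[pos])
      warning(sprintf("rank-deficient design for species %d; returning the minimum-norm solution", mu))
    }
    coefs[mu, ] <- p
  }
  if (intercept) LinearModel(coefs[, -1L, drop = FALSE], coefs[, 1L])
  else LinearModel(coefs)
}
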