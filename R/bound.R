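#' Quadratic-bound coefficient lambda(xi)
#'
#' The coefficient \eqn{\lambda(\xi) = \frac{1}{2\xi}(\sigma(\xi) - 1/2)}
#' (with \eqn{\sigma} the logistic function) appearing in the
#' double-majorization bound on the softmax normalizer. It is strictly
#' decreasing on \eqn{[0, \infty)} with \eqn{\lambda(0) = 1/8} (the analytic
#' limit) and values in (0, 1/8]. Near zero the direct expression is 0/0, so
#' a series expansion \eqn{1/8 - \xi^2/96} is used for \eqn{\xi < 10^{-4}}.
#'
#' @param xi nonnegative numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' lambdaXi(0)        # 0.125
#' lambdaXi(c(1, 4))
#' @export
lambdaXi <- function(xi) {
  if (any(xi < 0)) stop("xi must be nonnegative")
  out <- xi
  small <- xi < 1e-4
  out[small] <- 0.125 - xi[small]^2 / 96
  xl <- xi[!small]
  # tanh(x/2)/(4x) is an equivalent form that avoids overflow in exp(xi)
  out[!small] <- tanh(xl / 2) / (4 * xl)
  out
}

# log(1 + exp(x)) without overflow, vectorized.
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# Stable log-sum-exp of a numeric vector.
.logSumExp <- function(a) {
  m <- max(a)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(a - m)))
}

#' Double-majorization upper bound on log-sum-exp
#'
#' Evaluates the logarithm of the quadratic (Bouchard-type) upper bound on
#' \eqn{\sum_j e^{a_j}}:
#' \deqn{\rho + \sum_j \left[\frac{a_j - \rho - \xi_j}{2}
#'   + \lambda(\xi_j)\big((a_j - \rho)^2 - \xi_j^2\big)
#'   + \log(1 + e^{\xi_j})\right]}
#' which dominates \eqn{\log \sum_j e^{a_j}} for every \eqn{\xi_j \ge 0} and
#' \eqn{\rho \in R}, with the per-term bound tight at
#' \eqn{\xi_j = |a_j - \rho|}. This bound turns the softmax normalizer in the
#' annotation prior into a quadratic in the annotation weights, making their
#' variational posterior Gaussian in closed form.
#'
#' @param a numeric vector of logits.
#' @param xi nonnegative vector, same length as `a`.
#' @param rho scalar shift parameter.
#' @return scalar value of the log bound.
#' @export
logsumexpBound <- function(a, xi, rho) {
  if (length(xi) != length(a)) stop("length mismatch between a and xi")
  if (length(rho) != 1L) stop("rho must be a scalar")
  if (any(xi < 0)) stop("xi must be nonnegative")
  d <- a - rho
  rho + sum((d - xi) / 2 + lambdaXi(xi) * (d * d - xi * xi) + .log1pexp(xi))
}
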