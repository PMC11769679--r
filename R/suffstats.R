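#' Sufficient statistics from individual-level data
#'
#' Builds the [FunmapSuffStats-class] quadruple
#' \eqn{(X^\top X, X^\top y, y^\top y, n)} from a genotype matrix and a
#' phenotype vector. Both are standardized with the population variance
#' convention first (unless `standardize = FALSE`, in which case they must
#' already be standardized). Monomorphic (zero-variance) genotype columns are
#' rejected with an error naming the column.
#'
#' @param X n x p numeric genotype matrix (dosages).
#' @param y length-n numeric phenotype vector.
#' @param snpIds SNP identifiers; defaults to `colnames(X)` or "snp1"...
#' @param standardize standardize columns of X and y first (default TRUE).
#' @return a [FunmapSuffStats-class] object.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 5, 2, 0.3), 200, 5)
#' y <- rnorm(200)
#' ss <- suffStatsFromIndividual(X, y)
#' ss@yty  # equals n = 200
#' @export
suffStatsFromIndividual <- function(X, y, snpIds = NULL, standardize = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("dimension mismatch: nrow(X) = ", nrow(X), " but length(y) = ", length(y))
  if (nrow(X) < 2) stop("need n >= 2 samples")
  if (is.null(snpIds)) snpIds <- colnames(X)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(X)))
  if (standardize) {
    X <- standardizeColumns(X, ids = snpIds)
    y <- .standardizeVector(y)
  }
  n <- nrow(X)
  methods::new("FunmapSuffStats",
    XtX = crossprod(X),
    Xty = drop(crossprod(X, y)),
    yty = sum(y * y),
    n = n,
    snpIds = as.character(snpIds)
  )
}

#' Marginal z-scores from individual-level data
#'
#' Per-SNP univariate regression z-scores
#' \eqn{z_j = \hat\beta_j / \hat s_j} with
#' \eqn{\hat\beta_j = (x_j^\top x_j)^{-1} x_j^\top y} and
#' \eqn{\hat s_j^2 = \|y - x_j\hat\beta_j\|^2 / (n\, x_j^\top x_j)}.
#' With standardized input this reduces to
#' \eqn{z_j = t_j / \sqrt{n - t_j^2/n}} where \eqn{t_j = x_j^\top y}.
#'
#' @inheritParams suffStatsFromIndividual
#' @return numeric vector of z-scores, named by SNP id.
#' @export
zFromIndividual <- function(X, y, standardize = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("dimension mismatch between X and y")
  n <- nrow(X)
  if (n <= 2) stop("need n > 2 for marginal z-scores")
  if (standardize) {
    X <- standardizeColumns(X)
    y <- .standardizeVector(y)
  }
  t <- drop(crossprod(X, y))       # x_j' y, with x_j' x_j = n
  denom2 <- n - t * t / n          # n^2 * shat_j^2 / ... residual term
  if (any(denom2 <= 0))
    stop("perfect fit for SNP(s) ", paste(which(denom2 <= 0), collapse = ", "),
         ": z-score is infinite")
  z <- t / sqrt(denom2)
  names(z) <- colnames(X)
  z
}

#' Sufficient statistics from GWAS summary data
#'
#' Maps marginal z-scores and an LD correlation matrix onto the same
#' sufficient statistics as individual-level data:
#' \eqn{X^\top X = nR}, \eqn{(X^\top y)_j = n z_j/\sqrt{n + z_j^2}},
#' \eqn{y^\top y = n}. The expression for \eqn{X^\top y} is the inversion of
#' the marginal z-score formula under population-variance standardization;
#' with in-sample LD the result is elementwise identical to
#' [suffStatsFromIndividual()].
#'
#' R must be symmetric with unit diagonal and near-positive-semidefinite.
#' A minimum eigenvalue in (-1e-6, 0) is treated as rounding noise and
#' clipped to zero (no rescaling); anything more negative is rejected.
#'
#' @param z length-p vector of marginal z-scores.
#' @param R p x p LD correlation matrix, SNP order matching `z`.
#' @param n GWAS sample size (positive).
#' @param snpIds SNP identifiers; defaults to `names(z)` or "snp1"...
#' @param checkR validate symmetry/diagonal/eigenvalues of R (default TRUE).
#'   Skipping the eigenvalue check is cheaper for large, trusted in-sample R.
#' @return a [FunmapSuffStats-class] object.
#' @export
suffStatsFromSummary <- function(z, R, n, snpIds = NULL, checkR = TRUE) {
  p <- length(z)
  if (!is.matrix(R)) R <- as.matrix(R)
  if (nrow(R) != p || ncol(R) != p)
    stop("dimension mismatch: length(z) = ", p, " but dim(R) = ",
         nrow(R), " x ", ncol(R))
  if (length(n) != 1L || !is.finite(n) || n <= 0) stop("n must be a positive scalar")
  if (is.null(snpIds)) snpIds <- names(z)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(p))
  if (checkR) {
    if (max(abs(R - t(R))) > 1e-8) stop("R is not symmetric (tolerance 1e-8)")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("diag(R) must be 1 (tolerance 1e-8)")
    ev <- eigen(R, symmetric = TRUE)
    lmin <- min(ev$values)
    if (lmin < -1e-6)
      stop("R is not positive semidefinite (min eigenvalue ", signif(lmin, 3), ")")
    if (lmin < 0) {
      d <- pmax(ev$values, 0)
      R <- ev$vectors %*% (d * t(ev$vectors))
      R <- (R + t(R)) / 2
    }
  }
  methods::new("FunmapSuffStats",
    XtX = n * R,
    Xty = n * z / sqrt(n + z * z),
    yty = n,
    n = n,
    snpIds = as.character(snpIds)
  )
}

#' @describeIn snpIds SNP ids of a sufficient-statistics object.
#' @export
setMethod("snpIds", "FunmapSuffStats", function(object) object@snpIds)

#' @export
setMethod("show", "FunmapSuffStats", function(object) {
  cat("FunmapSuffStats: p =", length(object@Xty),
      "SNPs, n =", object@n, "\n")
  cat("  max |z| implied:",
      signif(max(abs(object@Xty) / sqrt(pmax(object@n - object@Xty^2 / object@n, 1e-12))), 4),
      "\n")
  invisible(object)
})
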