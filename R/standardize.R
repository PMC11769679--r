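# Column means/variances with the population convention (denominator n).
.colVars <- function(M) {
  mu <- colMeans(M)
  colMeans(M * M) - mu * mu
}

#' Standardize matrix columns to zero mean and unit variance
#'
#' Uses the population variance convention (denominator n, not n - 1), so a
#' standardized column x satisfies \eqn{x^\top x = n} exactly. This is what
#' makes the sufficient-statistic identities \eqn{X^\top X = nR} and
#' \eqn{y^\top y = n} hold without correction factors.
#'
#' @param M numeric matrix (a vector is treated as a one-column matrix).
#' @param ids optional column identifiers used in error messages; defaults to
#'   column names or indices.
#' @return matrix of the same dimensions with each column standardized.
#'   Columns already standardized are returned unchanged up to rounding.
#' @examples
#' M <- cbind(a = c(0, 1, 2), b = c(5, 3, 1))
#' S <- standardizeColumns(M)
#' colMeans(S)            # 0 0
#' colMeans(S^2)          # 1 1
#' @export
standardizeColumns <- function(M, ids = NULL) {
  if (is.vector(M)) M <- matrix(M, ncol = 1L)
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  if (is.null(ids)) ids <- colnames(M)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(M)))
  mu <- colMeans(M)
  v <- colMeans(M * M) - mu * mu
  bad <- which(v <= 0)
  if (length(bad))
    stop("zero variance in column(s): ", paste(ids[bad], collapse = ", "))
  out <- sweep(M, 2L, mu, "-")
  sweep(out, 2L, sqrt(v), "/")
}

# Standardize a vector with the population convention.
.standardizeVector <- function(y, what = "y") {
  mu <- mean(y)
  v <- mean(y * y) - mu * mu
  if (v <= 0) stop("zero variance in ", what)
  (y - mu) / sqrt(v)
}
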