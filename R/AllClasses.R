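#' @import methods
NULL

#' Sufficient statistics for a fine-mapping region
#'
#' All likelihood computation in the package flows through the quadruple
#' \eqn{(X^\top X, X^\top y, y^\top y, n)}. For individual-level data these
#' are exact cross-products of the column-standardized genotype matrix and the
#' standardized phenotype; for summary-level data they are reconstructed from
#' marginal z-scores and an LD correlation matrix R via
#' \eqn{X^\top X = nR}, \eqn{(X^\top y)_j = n z_j / \sqrt{n + z_j^2}},
#' \eqn{y^\top y = n}. The two constructions agree exactly when R is the
#' in-sample LD.
#'
#' Standardization uses the population convention (variance denominator
#' \eqn{n}), so that every diagonal entry of \eqn{X^\top X} equals \eqn{n}.
#'
#' @slot XtX p x p cross-product matrix (equals n times the LD matrix).
#' @slot Xty length-p cross-product of genotypes with the phenotype.
#' @slot yty scalar, equals n for standardized phenotypes.
#' @slot n GWAS sample size.
#' @slot snpIds character vector of SNP identifiers, length p.
#'
#' @seealso [suffStatsFromIndividual()], [suffStatsFromSummary()]
#' @export
setClass("FunmapSuffStats",
  slots = c(
    XtX = "matrix",
    Xty = "numeric",
    yty = "numeric",
    n = "numeric",
    snpIds = "character"
  )
)

setValidity("FunmapSuffStats", function(object) {
  p <- length(object@Xty)
  msg <- character()
  if (!is.numeric(object@XtX)) msg <- c(msg, "XtX must be numeric")
  if (nrow(object@XtX) != p || ncol(object@XtX) != p)
    msg <- c(msg, "XtX must be p x p with p = length(Xty)")
  if (length(object@snpIds) != p)
    msg <- c(msg, "snpIds must have length p")
  if (length(object@n) != 1L || object@n < 2)
    msg <- c(msg, "n must be a single value >= 2")
  if (length(object@yty) != 1L || !is.finite(object@yty))
    msg <- c(msg, "yty must be a finite scalar")
  if (length(msg) == 0L) {
    n <- object@n
    if (max(abs(object@XtX - t(object@XtX))) > 1e-6 * max(1, n))
      msg <- c(msg, "XtX is not symmetric")
    if (max(abs(diag(object@XtX) - n)) > 1e-6 * max(1, n))
      msg <- c(msg, "diag(XtX) must equal n (standardized genotypes)")
    if (abs(object@yty - n) > 1e-6 * max(1, n))
      msg <- c(msg, "yty must equal n (standardized phenotype)")
  }
  if (length(msg)) msg else TRUE
})

#' Annotation matrix for a SNP panel
#'
#' Holds the p x m matrix of functional annotations together with the kind
#' of each column (continuous or binary) and its standardization state.
#' Continuous columns are standardized to zero mean and unit variance, binary
#' columns are centered only, and no intercept column is ever added: the
#' softmax prior is invariant to a shared shift of all logits, which would
#' make an intercept unidentifiable.
#'
#' @slot A p x m numeric matrix; column names carry annotation names.
#' @slot kinds character vector, "continuous" or "binary" per column.
#' @slot standardized logical flag recording whether columns were processed.
#'
#' @seealso [annotationMatrix()]
#' @export
setClass("FunmapAnnotations",
  slots = c(
    A = "matrix",
    kinds = "character",
    standardized = "logical"
  )
)

setValidity("FunmapAnnotations", function(object) {
  m <- ncol(object@A)
  msg <- character()
  if (length(object@kinds) != m)
    msg <- c(msg, "kinds must have one entry per annotation column")
  if (!all(object@kinds %in% c("continuous", "binary")))
    msg <- c(msg, "kinds must be 'continuous' or 'binary'")
  if (m > 0 && is.null(colnames(object@A)))
    msg <- c(msg, "A must have column names (annotation names)")
  if (m > 0) {
    v <- .colVars(object@A)
    if (any(v == 0))
      msg <- c(msg, "constant annotation columns are not allowed; use annotationMatrix() which drops them")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted fine-mapping model
#'
#' Container for the variational state and posterior summaries of a fitted
#' model: per-component single-effect posteriors (alpha, mu, s2), annotation
#' weight posteriors (muW, SigmaW), the softmax-bound variational parameters
#' (xi, rho), variance components, the per-SNP posterior inclusion
#' probabilities, and fit diagnostics (ELBO trace with stage markers,
#' iteration counts, convergence flags). The state after stage 1 (the
#' annotation-free special case of the model) is kept in `alphaStage1` so
#' annotated and annotation-free posteriors from the same fit can be compared.
#'
#' Use the accessors [pip()], [credibleSets()], [selectCausal()],
#' [featureImportance()], [elboTrace()] rather than reaching into slots.
#'
#' @slot alpha L x p matrix; row l is q(gamma_l), the posterior probability
#'   that component l's causal signal is SNP j. Rows sum to one.
#' @slot mu,s2 L x p matrices of posterior means/variances of the effect size
#'   b_l given gamma_lj = 1.
#' @slot alphaStage1 L x p matrix, q(gamma_l) at the end of stage 1.
#' @slot muW m x L matrix of posterior mean annotation weights per component.
#' @slot SigmaW list of L m x m posterior covariance matrices.
#' @slot xi L x p matrix of nonnegative bound parameters.
#' @slot rho length-L vector of bound shift parameters.
#' @slot sigma2 residual variance.
#' @slot sigmab2,sigmaw2 length-L effect-size and annotation-weight variances.
#' @slot pip length-p posterior inclusion probabilities.
#' @slot elboTrace numeric ELBO trace across all stages.
#' @slot elboStage integer stage marker (1, 2, 3) per trace entry.
#' @slot niter integer iterations run per stage.
#' @slot converged logical per stage.
#' @slot snpIds,annotationNames identifiers.
#' @slot config list of fitting options used.
#' @export
setClass("FunmapFit",
  slots = c(
    alpha = "matrix",
    mu = "matrix",
    s2 = "matrix",
    alphaStage1 = "matrix",
    muW = "matrix",
    SigmaW = "list",
    xi = "matrix",
    rho = "numeric",
    sigma2 = "numeric",
    sigmab2 = "numeric",
    sigmaw2 = "numeric",
    pip = "numeric",
    elboTrace = "numeric",
    elboStage = "integer",
    niter = "integer",
    converged = "logical",
    snpIds = "character",
    annotationNames = "character",
    config = "list"
  )
)

setValidity("FunmapFit", function(object) {
  L <- nrow(object@alpha)
  p <- ncol(object@alpha)
  msg <- character()
  if (!all(dim(object@mu) == c(L, p)) || !all(dim(object@s2) == c(L, p)))
    msg <- c(msg, "alpha, mu, s2 must share dimensions L x p")
  rs <- rowSums(object@alpha)
  if (any(abs(rs - 1) > 1e-6))
    msg <- c(msg, "each row of alpha must sum to 1")
  if (length(object@pip) != p || any(object@pip < -1e-12 | object@pip > 1 + 1e-12))
    msg <- c(msg, "pip must be length p with entries in [0, 1]")
  if (any(object@xi < 0))
    msg <- c(msg, "xi must be nonnegative")
  if (length(object@elboStage) != length(object@elboTrace))
    msg <- c(msg, "elboStage must align with elboTrace")
  if (length(msg)) msg else TRUE
})
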