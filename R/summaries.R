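#' Posterior inclusion probabilities from component posteriors
#'
#' \eqn{PIP_j = 1 - \prod_l (1 - \alpha_{lj})}, accumulated on the log scale
#' via `log1p` for stability when many components carry small mass.
#'
#' @param alpha L x p matrix of per-component posterior probabilities, each
#'   row summing to one.
#' @return numeric vector of length p.
#' @export
computePip <- function(alpha) {
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = 1L)
  a <- pmin(pmax(alpha, 0), 1)
  lognot <- colSums(log1p(-a))           # -Inf where some alpha = 1
  out <- -expm1(lognot)
  out[lognot == -Inf] <- 1
  pmin(pmax(out, 0), 1)
}

#' Global-FDR selection of putative causal SNPs
#'
#' The local fdr of SNP j is \eqn{1 - PIP_j}. Sorting local fdrs in ascending
#' order (ties broken by original index), the global FDR of the top-i set is
#' the running mean \eqn{FDR(i) = \sum_{k \le i} fdr_{(k)} / i}. All SNPs in
#' the longest prefix with \eqn{FDR(i) \le \eta} are selected (step-up rule:
#' FDR(i) is not monotone in general, so the last qualifying index is used,
#' not the first crossing).
#'
#' @param pip numeric vector of posterior inclusion probabilities.
#' @param eta global FDR threshold in (0, 1).
#' @return logical vector, TRUE for selected SNPs, with attribute
#'   `globalFdr` giving the running-mean FDR in the sorted order.
#' @examples
#' selectByGlobalFdr(c(0.99, 0.96, 0.80), eta = 0.05)  # first two selected
#' @export
selectByGlobalFdr <- function(pip, eta = 0.05) {
  if (eta <= 0 || eta >= 1) stop("eta must be in (0, 1)")
  fdr <- 1 - pip
  ord <- order(fdr, seq_along(fdr))
  cum <- cumsum(fdr[ord]) / seq_along(fdr)
  k <- which(cum <= eta)
  sel <- logical(length(pip))
  if (length(k)) sel[ord[seq_len(max(k))]] <- TRUE
  attr(sel, "globalFdr") <- cum
  sel
}

#' Credible sets from component posteriors
#'
#' For each single-effect component the level-delta credible set is the
#' smallest set of SNPs whose posterior mass \eqn{q(\gamma_l)} sums to at
#' least delta (SNPs taken in decreasing order of alpha, ties by index).
#' Components whose posterior is spread over essentially all SNPs carry no
#' localizable signal and are dropped: a component is reported only when its
#' largest alpha exceeds 2/p and its set is smaller than the full panel.
#' When an LD matrix is supplied, sets whose minimum absolute pairwise
#' correlation (purity) falls below `purityThreshold` are also dropped; for
#' sets larger than `purityMaxSnps` the purity is computed on the
#' `purityMaxSnps` highest-alpha members.
#'
#' @param alpha L x p matrix of component posteriors.
#' @param delta coverage level in (0, 1), default 0.95.
#' @param R optional p x p LD correlation matrix for purity filtering.
#' @param purityThreshold minimum purity; default 0.5 when R is supplied,
#'   0 (no filtering) otherwise.
#' @param purityMaxSnps cap on the number of SNPs used in the purity
#'   computation (default 100).
#' @return list of credible sets; each element has fields `component`,
#'   `snps` (integer indices), `coverage` (achieved mass) and `purity`
#'   (NA when R is absent).
#' @export
credibleSetsFromAlpha <- function(alpha, delta = 0.95, R = NULL,
                                  purityThreshold = if (is.null(R)) 0 else 0.5,
                                  purityMaxSnps = 100L) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = 1L)
  p <- ncol(alpha)
  out <- list()
  for (l in seq_len(nrow(alpha))) {
    al <- alpha[l, ]
    if (max(al) <= 2 / p) next        # near-uniform component, no signal
    ord <- order(-al, seq_len(p))
    k <- which(cumsum(al[ord]) >= delta)[1]
    if (is.na(k) || k == p) next      # trivial all-SNP set
    snps <- sort(ord[seq_len(k)])
    purity <- NA_real_
    if (!is.null(R)) {
      sub <- snps
      if (length(sub) > purityMaxSnps)
        sub <- sort(ord[seq_len(purityMaxSnps)])
      purity <- if (length(sub) == 1L) 1 else {
        Rs <- abs(R[sub, sub])
        min(Rs[upper.tri(Rs)])
      }
      if (purity < purityThreshold) next
    }
    out[[length(out) + 1L]] <- list(component = l, snps = snps,
                                    coverage = sum(al[snps]), purity = purity)
  }
  out
}

#' Annotation importance from weight posteriors
#'
#' @param muW m x L matrix of posterior mean annotation weights (one column
#'   per component).
#' @return length-m vector \eqn{FI_k = \max_l \mu_{w_{lk}}^2}.
#' @export
featureImportanceFromWeights <- function(muW) {
  if (!is.matrix(muW)) muW <- matrix(muW, ncol = 1L)
  if (ncol(muW) == 0L || nrow(muW) == 0L)
    return(structure(numeric(nrow(muW)), names = rownames(muW)))
  out <- apply(muW * muW, 1L, max)
  names(out) <- rownames(muW)
  out
}

#' Rank annotations by importance
#'
#' @param FI numeric importance vector.
#' @param topFraction fraction of annotations to return, in (0, 1]; the top
#'   `ceiling(topFraction * m)` are returned. Ties broken by original order.
#' @return integer indices of the top-ranked annotations (named when FI is).
#' @export
rankAnnotations <- function(FI, topFraction = 0.05) {
  if (topFraction <= 0 || topFraction > 1) stop("topFraction must be in (0, 1]")
  m <- length(FI)
  k <- ceiling(topFraction * m)
  ord <- order(-FI, seq_len(m))
  out <- ord[seq_len(k)]
  if (!is.null(names(FI))) names(out) <- names(FI)[out]
  out
}

#' @describeIn pip PIPs of a fitted model.
#' @export
setMethod("pip", "FunmapFit", function(object, ...) {
  structure(object@pip, names = object@snpIds)
})

#' @describeIn credibleSets Credible sets of a fitted model; arguments
#'   `delta`, `R`, `purityThreshold` as in [credibleSetsFromAlpha()]. SNP ids
#'   are attached to each set.
#' @param delta coverage level.
#' @param R optional LD matrix for purity filtering.
#' @param purityThreshold minimum purity (default 0.5 when R given).
#' @export
setMethod("credibleSets", "FunmapFit",
  function(object, delta = 0.95, R = NULL,
           purityThreshold = if (is.null(R)) 0 else 0.5, ...) {
    cs <- credibleSetsFromAlpha(object@alpha, delta = delta, R = R,
                                purityThreshold = purityThreshold)
    lapply(cs, function(s) { s$snpIds <- object@snpIds[s$snps]; s })
  })

#' @describeIn selectCausal Step-up global-FDR selection on the fit's PIPs.
#' @param eta global FDR threshold.
#' @export
setMethod("selectCausal", "FunmapFit", function(object, eta = 0.05, ...) {
  sel <- selectByGlobalFdr(object@pip, eta = eta)
  names(sel) <- object@snpIds
  sel
})

#' @describeIn featureImportance Importance scores of a fitted model.
#' @export
setMethod("featureImportance", "FunmapFit", function(object, ...) {
  structure(featureImportanceFromWeights(object@muW),
            names = object@annotationNames)
})
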