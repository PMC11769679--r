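#' Posterior inclusion probabilities
#'
#' PIP(j) is the posterior probability that SNP j carries at least one of the
#' L single-effect signals, \eqn{1 - \prod_l (1 - q(\gamma_{lj}=1))}.
#'
#' @param object a [FunmapFit-class] object.
#' @param ... further arguments for methods.
#' @return numeric vector of length p, named by SNP id.
#' @export
setGeneric("pip", function(object, ...) standardGeneric("pip"))

#' Level-delta credible sets
#'
#' @param object a [FunmapFit-class] object.
#' @param ... passed on to methods; see the FunmapFit method.
#' @return a list of credible sets; see [credibleSetsFromAlpha()].
#' @export
setGeneric("credibleSets", function(object, ...) standardGeneric("credibleSets"))

#' Select putative causal SNPs at a global FDR level
#'
#' @param object a [FunmapFit-class] object (or use
#'   [selectByGlobalFdr()] directly on a PIP vector).
#' @param ... passed on to methods.
#' @return logical vector of length p.
#' @export
setGeneric("selectCausal", function(object, ...) standardGeneric("selectCausal"))

#' Annotation importance scores
#'
#' For annotation k the importance score is the largest squared posterior
#' mean weight across components, \eqn{FI_k = \max_l \mu_{w_{lk}}^2},
#' capturing the strongest evidence of relevance in any single-effect signal.
#'
#' @param object a [FunmapFit-class] object.
#' @param ... further arguments for methods.
#' @return nonnegative numeric vector of length m, named by annotation.
#' @export
setGeneric("featureImportance", function(object, ...) standardGeneric("featureImportance"))

#' ELBO trace of a fit
#'
#' @param object a [FunmapFit-class] object.
#' @param ... further arguments for methods.
#' @return numeric vector with attribute `stage` marking the fitting stage
#'   of each entry.
#' @export
setGeneric("elboTrace", function(object, ...) standardGeneric("elboTrace"))

#' SNP identifiers
#'
#' @param object an object carrying a SNP panel.
#' @return character vector of SNP ids.
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' Annotation names
#'
#' @param object an object carrying annotations.
#' @return character vector of annotation names.
#' @export
setGeneric("annotationNames", function(object) standardGeneric("annotationNames"))
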