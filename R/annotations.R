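#' Prepare an annotation matrix for model fitting
#'
#' Validates and preprocesses raw annotations: constant columns are dropped
#' (with a warning naming them), continuous columns are standardized to zero
#' mean and unit variance, and binary columns are centered only (their scale
#' carries meaning). Column kind is taken from `kinds` when supplied and
#' auto-detected otherwise (at most two distinct values = binary). No
#' intercept column is ever added: the softmax prior is invariant to a shared
#' shift of all logits, so an intercept is unidentifiable.
#'
#' @param A p x m numeric matrix of raw annotations, one row per SNP.
#' @param kinds optional character vector ("continuous"/"binary") per column.
#' @param annotationNames column names; defaults to `colnames(A)` or "annot1"...
#' @param p expected number of rows (SNP panel size); checked when given.
#' @param standardize process columns as described (default TRUE). With
#'   FALSE the matrix is only validated.
#' @return a [FunmapAnnotations-class] object (possibly with fewer columns
#'   than the input if constant columns were dropped).
#' @examples
#' A <- cbind(cons = rnorm(100), bin = rbinom(100, 1, 0.3))
#' ann <- annotationMatrix(A)
#' ann@kinds
#' @export
annotationMatrix <- function(A, kinds = NULL, annotationNames = NULL,
                             p = NULL, standardize = TRUE) {
  if (is.null(A) || ncol(as.matrix(A)) == 0L) {
    return(methods::new("FunmapAnnotations",
                        A = matrix(0, if (is.null(p)) 0L else p, 0L),
                        kinds = character(), standardized = TRUE))
  }
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (!is.null(p) && nrow(A) != p)
    stop("annotation row count (", nrow(A), ") does not match SNP panel size (", p, ")")
  if (is.null(annotationNames)) annotationNames <- colnames(A)
  if (is.null(annotationNames)) annotationNames <- paste0("annot", seq_len(ncol(A)))
  colnames(A) <- annotationNames

  v <- .colVars(A)
  if (any(v == 0)) {
    drop <- which(v == 0)
    warning("dropping constant annotation column(s): ",
            paste(annotationNames[drop], collapse = ", "))
    A <- A[, -drop, drop = FALSE]
    if (!is.null(kinds)) kinds <- kinds[-drop]
  }
  m <- ncol(A)
  if (is.null(kinds)) {
    kinds <- vapply(seq_len(m), function(k) {
      if (length(unique(A[, k])) <= 2L) "binary" else "continuous"
    }, character(1))
  }
  if (length(kinds) != m || !all(kinds %in% c("continuous", "binary")))
    stop("kinds must be 'continuous' or 'binary', one per retained column")

  if (standardize && m > 0) {
    cont <- kinds == "continuous"
    if (any(cont))
      A[, cont] <- standardizeColumns(A[, cont, drop = FALSE])
    if (any(!cont)) {
      bin <- which(!cont)
      A[, bin] <- sweep(A[, bin, drop = FALSE], 2L, colMeans(A[, bin, drop = FALSE]), "-")
    }
  }
  methods::new("FunmapAnnotations", A = A, kinds = kinds,
               standardized = standardize)
}

#' @describeIn annotationNames Names of the annotation columns.
#' @export
setMethod("annotationNames", "FunmapAnnotations", function(object) colnames(object@A))

#' @export
setMethod("show", "FunmapAnnotations", function(object) {
  cat("FunmapAnnotations:", nrow(object@A), "SNPs x", ncol(object@A),
      "annotations (", sum(object@kinds == "continuous"), "continuous,",
      sum(object@kinds == "binary"), "binary;",
      if (object@standardized) "standardized" else "raw", ")\n")
  invisible(object)
})
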