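# Readers and writers for the tabular interchange formats.
#
# Input is assumed pre-harmonized: SNP order and allele orientation must
# already agree across the z-score, LD, and annotation files. The readers
# validate SNP id sequences strictly (no silent joins or reordering).

#' Read a z-score table
#'
#' Tab-separated with header; requires columns `snp_id` and `z`; optional
#' `chr` and `pos` columns are passed through.
#'
#' @param path file path.
#' @return data.table with at least `snp_id` and `z`.
#' @export
readZScores <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("snp_id", "z") %in% names(dt)))
    stop("z-score file must have columns 'snp_id' and 'z': ", path)
  if (anyNA(dt$z)) stop("missing z values in ", path)
  dt
}

#' Read a dense LD matrix
#'
#' Whitespace-delimited dense p x p numeric matrix, no header. Row/column
#' order must match the z-score file order (validated by length here and by
#' id order at the [runFit()] level).
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
readLDMatrix <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  R <- as.matrix(dt)
  dimnames(R) <- NULL
  if (nrow(R) != ncol(R)) stop("LD matrix is not square: ", path)
  R
}

#' Read an annotation table
#'
#' Tab-separated with header; first column `snp_id`, remaining columns one
#' annotation each. Column kinds may be declared in a sidecar file (two
#' columns: `annotation`, `kind`); otherwise kinds are auto-detected by
#' [annotationMatrix()].
#'
#' @param path file path.
#' @param kindsFile optional sidecar declaring binary columns.
#' @return list with `snp_id`, `A` (matrix), `kinds` (or NULL).
#' @export
readAnnotations <- function(path, kindsFile = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  if (names(dt)[1] != "snp_id")
    stop("annotation file must have 'snp_id' as its first column: ", path)
  A <- as.matrix(dt[, -1, drop = FALSE])
  kinds <- NULL
  if (!is.null(kindsFile)) {
    kd <- data.table::fread(kindsFile, header = TRUE)
    if (!all(c("annotation", "kind") %in% names(kd)))
      stop("kinds file must have columns 'annotation' and 'kind'")
    kinds <- rep("continuous", ncol(A))
    names(kinds) <- colnames(A)
    hit <- intersect(kd$annotation, colnames(A))
    kinds[hit] <- kd$kind[match(hit, kd$annotation)]
    kinds <- unname(kinds)
  }
  list(snp_id = dt$snp_id, A = A, kinds = kinds)
}

#' Read a dense genotype matrix
#'
#' Tab-separated; header row of SNP ids; one row per sample.
#'
#' @param path file path.
#' @return numeric matrix with SNP ids as column names.
#' @export
readGenotypeMatrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  as.matrix(dt)
}

#' Read a phenotype table
#'
#' Tab-separated with header; columns `sample_id` and `y`.
#'
#' @param path file path.
#' @return data.table with `sample_id` and `y`.
#' @export
readPhenotype <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("sample_id", "y") %in% names(dt)))
    stop("phenotype file must have columns 'sample_id' and 'y': ", path)
  dt
}

# First index where two id sequences disagree, or 0 if identical.
.firstIdMismatch <- function(a, b) {
  if (length(a) != length(b)) return(min(length(a), length(b)) + 1L)
  d <- which(a != b)
  if (length(d)) d[1] else 0L
}

#' Write fine-mapping results
#'
#' Writes `<prefix>.snps.tsv` (snp_id, pip, local_fdr, selected, cs_id),
#' `<prefix>.annotations.tsv` (annotation, importance, rank) when
#' annotations were used, and `<prefix>.meta.json` (config, ELBO trace,
#' stage iteration counts, seed, package version).
#'
#' @param fit a [FunmapFit-class] object.
#' @param prefix output path prefix.
#' @param eta global FDR threshold used for the `selected` column.
#' @param delta credible-set coverage level.
#' @param R optional LD matrix for credible-set purity filtering.
#' @param seed seed recorded in the metadata.
#' @param extraMeta optional named list merged into the metadata JSON.
#' @return invisibly, the paths written.
#' @export
writeFineMapResult <- function(fit, prefix, eta = 0.05, delta = 0.95,
                               R = NULL, seed = NULL, extraMeta = list()) {
  p <- length(fit@pip)
  sel <- selectCausal(fit, eta = eta)
  cs <- credibleSets(fit, delta = delta, R = R)
  csId <- rep(NA_integer_, p)
  for (i in seq_along(cs)) csId[cs[[i]]$snps] <- i
  snps <- data.table::data.table(
    snp_id = fit@snpIds,
    pip = fit@pip,
    local_fdr = 1 - fit@pip,
    selected = as.logical(sel),
    cs_id = csId
  )
  paths <- paste0(prefix, ".snps.tsv")
  data.table::fwrite(snps, paths[1], sep = "\t")

  if (length(fit@annotationNames)) {
    FI <- featureImportance(fit)
    annTab <- data.table::data.table(
      annotation = fit@annotationNames,
      importance = as.numeric(FI),
      rank = rank(-FI, ties.method = "first")
    )
    annPath <- paste0(prefix, ".annotations.tsv")
    data.table::fwrite(annTab, annPath, sep = "\t")
    paths <- c(paths, annPath)
  }

  meta <- c(list(
    package = "funmapr",
    version = as.character(utils::packageVersion("funmapr")),
    config = fit@config,
    eta = eta, delta = delta, seed = seed,
    niter = fit@niter, converged = fit@converged,
    elboTrace = fit@elboTrace, elboStage = fit@elboStage,
    sigma2 = fit@sigma2,
    annotations = if (length(fit@annotationNames)) fit@annotationNames else "none"
  ), extraMeta)
  metaPath <- paste0(prefix, ".meta.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, metaPath))
}
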