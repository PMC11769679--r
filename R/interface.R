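# End-to-end workflows tying the modules together. These are what the
# command-line wrapper (inst/cli/funmap.R) calls.

#' Run a fine-mapping fit from files
#'
#' Loads summary-level input (`zFile` + `ldFile` + `n`) or individual-level
#' input (`genoFile` + `phenoFile`), optionally with annotations, validates
#' SNP-order consistency across files (a hard error names the first
#' mismatched id — silent reordering is the classic fine-mapping foot-gun),
#' builds sufficient statistics, runs the three-stage fit, and writes the
#' result files via [writeFineMapResult()].
#'
#' @param zFile,ldFile,n summary-mode inputs: z-score TSV, dense LD matrix,
#'   GWAS sample size.
#' @param genoFile,phenoFile individual-mode inputs.
#' @param annotFile optional annotation TSV; omitted = annotation-free fit.
#' @param annotKindsFile optional sidecar declaring binary annotations.
#' @param outPrefix output path prefix; NULL skips writing.
#' @param L,eta,delta,purityThreshold,elboTol,maxIterPerStage,seed options;
#'   defaults L = 10, eta = 0.05, delta = 0.95, 100 iterations per stage.
#' @param verbose print per-stage progress.
#' @return the [FunmapFit-class] object, invisibly.
#' @export
runFit <- function(zFile = NULL, ldFile = NULL, n = NULL,
                   genoFile = NULL, phenoFile = NULL,
                   annotFile = NULL, annotKindsFile = NULL,
                   outPrefix = NULL, L = 10L, eta = 0.05, delta = 0.95,
                   purityThreshold = 0.5, elboTol = 1e-4,
                   maxIterPerStage = 100L, seed = 1L, verbose = FALSE) {
  summaryMode <- !is.null(zFile)
  if (summaryMode) {
    if (is.null(ldFile) || is.null(n))
      stop("summary mode requires zFile, ldFile and n")
    zdt <- readZScores(zFile)
    R <- readLDMatrix(ldFile)
    if (nrow(R) != nrow(zdt))
      stop("LD matrix dimension (", nrow(R), ") does not match z-score rows (",
           nrow(zdt), ")")
    ss <- suffStatsFromSummary(zdt$z, R, n, snpIds = zdt$snp_id)
    Rld <- R
  } else {
    if (is.null(genoFile) || is.null(phenoFile))
      stop("individual mode requires genoFile and phenoFile")
    X <- readGenotypeMatrix(genoFile)
    ph <- readPhenotype(phenoFile)
    if (nrow(X) != nrow(ph))
      stop("genotype rows (", nrow(X), ") do not match phenotype rows (",
           nrow(ph), ")")
    ss <- suffStatsFromIndividual(X, ph$y)
    Rld <- ss@XtX / ss@n
  }

  ann <- NULL
  if (!is.null(annotFile)) {
    araw <- readAnnotations(annotFile, annotKindsFile)
    mis <- .firstIdMismatch(as.character(ss@snpIds), as.character(araw$snp_id))
    if (mis > 0)
      stop("SNP order mismatch between inputs and annotation file at row ", mis,
           ": '", ss@snpIds[min(mis, length(ss@snpIds))], "' vs '",
           araw$snp_id[min(mis, length(araw$snp_id))], "'")
    ann <- annotationMatrix(araw$A, kinds = araw$kinds, p = length(ss@snpIds))
  }

  fit <- funmapFit(ss, ann, L = L, elboTol = elboTol,
                   maxIterPerStage = maxIterPerStage, verbose = verbose)

  if (!is.null(outPrefix)) {
    writeFineMapResult(fit, outPrefix, eta = eta, delta = delta, R = Rld,
                       seed = seed,
                       extraMeta = list(
                         mode = if (summaryMode) "summary" else "individual",
                         annotations = if (is.null(ann)) "none"
                                       else annotationNames(ann)))
  }
  invisible(fit)
}

#' Simulate a locus and write the standard input file set
#'
#' Writes `z.tsv`, `ld.tsv`, `annotations.tsv` in the formats read by
#' [runFit()], plus `truth.json` recording causal indices, true weights,
#' causal probabilities, effect sizes and the realized heritability.
#'
#' @param design a [simulationDesign()] object.
#' @param outDir output directory (created if needed).
#' @return invisibly, the simulated locus (as from [simulateLocus()]).
#' @export
runSimulate <- function(design, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateLocus(design)
  snpIds <- colnames(sim$X)
  data.table::fwrite(data.table::data.table(snp_id = snpIds, z = sim$z),
                     file.path(outDir, "z.tsv"), sep = "\t")
  R <- crossprod(sim$X) / nrow(sim$X)
  data.table::fwrite(data.table::as.data.table(R),
                     file.path(outDir, "ld.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(snp_id = snpIds, sim$A),
    file.path(outDir, "annotations.tsv"), sep = "\t")
  jsonlite::write_json(
    c(sim$truth, list(n = design$n, seed = design$seed)),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Run the benchmark and write metrics files
#'
#' Wraps [runBenchmark()]: writes `metrics_replicates.tsv`, `efdr.tsv`,
#' `power.tsv`, `credible_sets.tsv`, `annotations.tsv`, a calibration curve
#' (`calibration.pdf`) and a machine-readable `summary.json`.
#'
#' @param design a [simulationDesign()] object.
#' @param nReplicates number of replicates.
#' @param outDir output directory.
#' @param ... passed to [runBenchmark()].
#' @return invisibly, the benchmark result list.
#' @export
runBenchmarkFiles <- function(design, nReplicates, outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bm <- runBenchmark(design, nReplicates = nReplicates, ...)
  data.table::fwrite(bm$perReplicate,
                     file.path(outDir, "metrics_replicates.tsv"), sep = "\t")
  data.table::fwrite(bm$efdr, file.path(outDir, "efdr.tsv"), sep = "\t")
  data.table::fwrite(bm$power, file.path(outDir, "power.tsv"), sep = "\t")
  data.table::fwrite(bm$credibleSets,
                     file.path(outDir, "credible_sets.tsv"), sep = "\t")
  if (!is.null(bm$annotations))
    data.table::fwrite(bm$annotations,
                       file.path(outDir, "annotations.tsv"), sep = "\t")

  grDevices::pdf(file.path(outDir, "calibration.pdf"), width = 5, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  ef <- bm$efdr[bm$efdr$method == "funmap", ]
  plot(ef$nominal, ef$efdr, type = "b", pch = 19,
       xlab = "nominal global FDR", ylab = "empirical FDR",
       xlim = range(ef$nominal), ylim = c(0, max(0.25, ef$efdr + 2 * ef$se, na.rm = TRUE)),
       main = "FDR calibration")
  graphics::abline(0, 1, lty = 2, col = "grey40")
  ok <- !is.na(ef$se)
  graphics::arrows(ef$nominal[ok], pmax(ef$efdr[ok] - 2 * ef$se[ok], 0),
                   ef$nominal[ok], ef$efdr[ok] + 2 * ef$se[ok],
                   angle = 90, code = 3, length = 0.03)

  summary <- list(
    design = unclass(design),
    nReplicates = nReplicates,
    failures = bm$failures,
    efdr = bm$efdr,
    power = bm$power,
    credibleSets = bm$credibleSets,
    annotations = bm$annotations
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(bm)
}
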