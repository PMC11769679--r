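#' Run the simulation benchmark
#'
#' Repeats the generative design for `nReplicates` experiments spread across
#' a pool of `nRegions` simulated genotype regions (replicate r uses region
#' r mod nRegions), mirroring the repeat-across-regions structure of GWAS
#' fine-mapping benchmarks: genotypes and their LD are a fixed property of a
#' region, while annotations, weights, causal SNPs, and phenotypes are
#' redrawn per experiment. Each replicate is fitted once and both the
#' annotated fit and its stage-1 (annotation-free) state are scored against
#' the simulation truth. Because stage 1 is exactly the annotation-free
#' special case of the model, the "no annotations" arm comes for free from
#' the same fit.
#'
#' Metrics per replicate and method: discoveries and true positives of the
#' global-FDR selection on a grid of nominal levels, power at fixed PIP
#' thresholds, credible-set count and sizes, and (for the annotated arm)
#' annotation-selection power/FPR at several top fractions.
#'
#' @param design a [simulationDesign()] object; its `seed` is the master
#'   seed.
#' @param nReplicates number of simulated experiments.
#' @param nRegions number of distinct genotype regions shared by the
#'   replicates (default 10).
#' @param nominalFdr grid of global-FDR levels.
#' @param pipThresholds PIP thresholds for power.
#' @param topFractions top fractions for annotation selection.
#' @param L,maxIterPerStage,elboTol fitting options passed to [funmapFit()].
#' @param verbose print a progress line per replicate.
#' @return list with elements `perReplicate` (data.table, one row per
#'   replicate x method), `efdr` (pooled empirical FDR per nominal level and
#'   method, with the pooled discovery count and a binomial standard error),
#'   `power` (mean power per threshold and method), `credibleSets` (size
#'   summaries), `annotations` (mean selection power/FPR per top fraction),
#'   `failures` (count of failed replicates), and `design`.
#' @export
runBenchmark <- function(design, nReplicates = 50L, nRegions = 10L,
                         nominalFdr = c(0.01, 0.05, 0.1, 0.15, 0.2),
                         pipThresholds = c(0.9, 0.95, 0.99),
                         topFractions = c(0.05, 0.1, 0.2, 0.5),
                         L = 10L, maxIterPerStage = 100L, elboTol = 1e-4,
                         verbose = FALSE) {
  masterSeed <- design$seed
  nRegions <- max(1L, min(as.integer(nRegions), nReplicates))
  regions <- lapply(seq_len(nRegions), function(k) {
    dk <- design
    dk$seed <- masterSeed
    geno <- simulateGenotypes(dk, seed = .substreamSeed(masterSeed, paste0("region", k)))
    XtX <- crossprod(geno$X)
    list(X = geno$X, XtX = XtX, Rld = XtX / design$n)
  })
  rows <- list()
  failures <- 0L
  for (r in seq_len(nReplicates)) {
    repSeed <- .substreamSeed(masterSeed, paste0("replicate", r))
    d <- design
    d$seed <- repSeed
    reg <- regions[[(r - 1L) %% nRegions + 1L]]
    res <- tryCatch({
      ann0 <- simulateAnnotations(d)
      piV <- causalProbabilities(ann0$A, ann0$w)
      causal <- selectCausalSnps(piV, reg$X, d$L0, d$maxCausalCorr)
      ph <- simulatePhenotype(reg$X, causal, d)
      sim <- list(A = ann0$A,
                  truth = list(causal = causal, w = ann0$w, pi = piV,
                               b0 = ph$b0, relevant = ann0$relevant,
                               h2Realized = ph$h2Realized))
      ss <- methods::new("FunmapSuffStats", XtX = reg$XtX,
                         Xty = drop(crossprod(reg$X, ph$y)),
                         yty = design$n, n = design$n,
                         snpIds = colnames(reg$X))
      ann <- annotationMatrix(sim$A, p = d$p)
      fit <- funmapFit(ss, ann, L = L, maxIterPerStage = maxIterPerStage,
                       elboTol = elboTol)
      Rld <- reg$Rld
      pips <- list(funmap = fit@pip,
                   stage1_only = computePip(fit@alphaStage1))
      alphas <- list(funmap = fit@alpha, stage1_only = fit@alphaStage1)
      FI <- featureImportanceFromWeights(fit@muW)
      out <- list()
      for (meth in names(pips)) {
        pp <- pips[[meth]]
        selStats <- lapply(nominalFdr, function(eta) {
          sel <- selectByGlobalFdr(pp, eta)
          list(D = sum(sel), tp = sum(which(sel) %in% sim$truth$causal))
        })
        cs <- credibleSetsFromAlpha(alphas[[meth]], delta = 0.95, R = Rld,
                                    purityThreshold = 0.5)
        row <- data.table::data.table(
          replicate = r, method = meth,
          L0 = d$L0, h2Realized = sim$truth$h2Realized,
          nCS = length(cs),
          meanCSsize = if (length(cs)) mean(lengths(lapply(cs, `[[`, "snps"))) else NA_real_
        )
        for (i in seq_along(nominalFdr)) {
          row[[paste0("D_", nominalFdr[i])]] <- selStats[[i]]$D
          row[[paste0("TP_", nominalFdr[i])]] <- selStats[[i]]$tp
        }
        for (th in pipThresholds)
          row[[paste0("power_", th)]] <- powerAtPip(pp, sim$truth$causal, th)
        if (meth == "funmap" && length(FI)) {
          for (tf in topFractions) {
            am <- annotationSelectionMetrics(FI, sim$truth$relevant, tf)
            row[[paste0("annPower_", tf)]] <- am$power
            row[[paste0("annFpr_", tf)]] <- am$fpr
          }
        }
        out[[meth]] <- row
      }
      data.table::rbindlist(out, fill = TRUE)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[length(rows) + 1L]] <- res
    if (verbose) message("replicate ", r, "/", nReplicates, " done")
  }
  perRep <- data.table::rbindlist(rows, fill = TRUE)

  efdrTab <- data.table::rbindlist(lapply(nominalFdr, function(eta) {
    do.call(rbind, lapply(unique(perRep$method), function(meth) {
      sub <- perRep[perRep$method == meth, ]
      D <- sum(sub[[paste0("D_", eta)]])
      tp <- sum(sub[[paste0("TP_", eta)]])
      ef <- if (D > 0) 1 - tp / D else 0
      data.table::data.table(nominal = eta, method = meth, discoveries = D,
                             truePositives = tp, efdr = ef,
                             se = if (D > 0) sqrt(eta * (1 - eta) / D) else NA_real_)
    }))
  }))

  powerTab <- data.table::rbindlist(lapply(pipThresholds, function(th) {
    do.call(rbind, lapply(unique(perRep$method), function(meth) {
      sub <- perRep[perRep$method == meth, ]
      data.table::data.table(threshold = th, method = meth,
                             power = mean(sub[[paste0("power_", th)]]),
                             se = stats::sd(sub[[paste0("power_", th)]]) /
                               sqrt(nrow(sub)))
    }))
  }))

  csTab <- do.call(rbind, lapply(unique(perRep$method), function(meth) {
    sub <- perRep[perRep$method == meth, ]
    data.table::data.table(method = meth,
                           meanNCS = mean(sub$nCS),
                           meanCSsize = mean(sub$meanCSsize, na.rm = TRUE),
                           medianCSsize = stats::median(sub$meanCSsize, na.rm = TRUE))
  }))

  annCols <- grep("^annPower_", names(perRep), value = TRUE)
  annTab <- NULL
  if (length(annCols)) {
    sub <- perRep[perRep$method == "funmap", ]
    annTab <- data.table::rbindlist(lapply(topFractions, function(tf) {
      data.table::data.table(topFraction = tf,
                             power = mean(sub[[paste0("annPower_", tf)]], na.rm = TRUE),
                             fpr = mean(sub[[paste0("annFpr_", tf)]], na.rm = TRUE))
    }))
  }

  list(perReplicate = perRep, efdr = efdrTab, power = powerTab,
       credibleSets = csTab, annotations = annTab,
       failures = failures, design = design)
}
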