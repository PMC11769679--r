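# Coordinate-ascent variational inference for the annotation-informed
# sum-of-single-effects model.
#
# The joint model is
#   y = X sum_l gamma_l b_l + e,     e ~ N(0, sigma2 I)
#   gamma_l ~ Mult(1, pi_l),         b_l ~ N(0, sigmab2_l)
#   pi_lj = softmax_j(A_j' w_l),     w_l ~ N(0, sigmaw2_l I_m)
# with the softmax normalizer replaced by its double-majorization quadratic
# upper bound (parameters xi_lj >= 0, rho_l), which makes every variational
# factor closed-form under the mean-field family
#   q = prod_l q(b_l | gamma_l) q(gamma_l) q(w_l).
#
# All data enter only through the sufficient statistics (XtX, Xty, yty, n),
# so individual-level and summary-level input share one code path.
#
# Internal state lives in an environment:
#   alpha, mu, s2, beta = alpha * mu   (L x p)
#   XtXbeta (p x L cache of XtX %*% beta_l), XtXb (p, = rowSums(XtXbeta))
#   muW (m x L), SigmaW (list of m x m), trSigmaW, logdetSigmaW (L)
#   abar, quad (p x L caches of A mu_wl and diag(A Sigma_wl A'))
#   xi (L x p), rho (L), sigma2, sigmab2 (L), sigmaw2 (L)

.VAR_FLOOR <- 1e-10

.newEngineState <- function(ss, A, L, sigma2Init, sigmab2Init, sigmaw2Init) {
  p <- length(ss@Xty)
  m <- ncol(A)
  st <- new.env(parent = emptyenv())
  st$p <- p; st$L <- L; st$m <- m; st$n <- ss@n
  st$XtX <- ss@XtX; st$Xty <- ss@Xty; st$yty <- ss@yty
  st$d <- diag(ss@XtX)
  st$A <- A
  st$alpha <- matrix(1 / p, L, p)
  st$mu <- matrix(0, L, p)
  st$s2 <- matrix(sigmab2Init, L, p)
  st$beta <- matrix(0, L, p)
  st$XtXbeta <- matrix(0, p, L)
  st$XtXb <- numeric(p)
  st$muW <- matrix(0, m, L)
  st$SigmaW <- replicate(L, diag(sigmaw2Init, m), simplify = FALSE)
  st$trSigmaW <- rep(m * sigmaw2Init, L)
  st$logdetSigmaW <- rep(m * log(sigmaw2Init), L)
  st$tA <- if (m > 0) t(A) else NULL
  st$abar <- matrix(0, p, L)
  st$quad <- matrix(0, p, L)
  st$quadFresh <- logical(L)
  st$xi <- matrix(0, L, p)
  st$rho <- numeric(L)
  st$sigma2 <- sigma2Init
  st$sigmab2 <- rep(sigmab2Init, L)
  st$sigmaw2 <- rep(sigmaw2Init, L)
  st
}

# Single-effect regression update for component l given prior logits.
# priorLogit may be unnormalized; the softmax normalization absorbs the
# constant (the bound's denominator terms do not depend on which SNP carries
# the component, so they cancel here).
#
# With estimateV = TRUE the component's effect variance sigmab2_l is first
# set to the maximizer of the single-effect evidence
#   log sum_j pi_j BF_j(sigmab2)
# (the component's contribution to F profiled over its posterior), then the
# posterior is computed at the maximizer. Jointly this is an exact block
# maximization, so F cannot decrease, and components with no signal are
# switched off in one step instead of decaying geometrically.
.serUpdate <- function(st, l, priorLogit, estimateV = FALSE) {
  r <- st$Xty - st$XtXb + st$XtXbeta[, l]
  if (any(!is.finite(r))) stop("non-finite residual cross-products in component ", l)
  if (estimateV) {
    rr <- (r / st$sigma2)^2
    dd <- st$d / st$sigma2
    evidence <- function(lv) {
      v <- exp(lv)
      s2v <- 1 / (dd + 1 / v)
      .logSumExp(priorLogit + 0.5 * log(s2v / v) + 0.5 * rr * s2v)
    }
    opt <- optimize(evidence, c(log(.VAR_FLOOR), log(2)), maximum = TRUE,
                    tol = 1e-3)
    st$sigmab2[l] <- exp(opt$maximum)
  }
  s2l <- 1 / (st$d / st$sigma2 + 1 / st$sigmab2[l])
  mul <- s2l * r / st$sigma2
  lbf <- 0.5 * log(s2l / st$sigmab2[l]) + 0.5 * mul * mul / s2l
  logw <- priorLogit + lbf
  a <- exp(logw - max(logw))
  alpha <- a / sum(a)
  st$alpha[l, ] <- alpha
  st$mu[l, ] <- mul
  st$s2[l, ] <- s2l
  newbeta <- alpha * mul
  newXtXbeta <- cppSymv(st$XtX, newbeta)
  st$XtXb <- st$XtXb - st$XtXbeta[, l] + newXtXbeta
  st$XtXbeta[, l] <- newXtXbeta
  st$beta[l, ] <- newbeta
  invisible(st)
}

# Expected residual sum of squares E_q || y - X b ||^2 through suff stats.
.erss <- function(st) {
  bbar <- colSums(st$beta)
  quadFull <- sum(bbar * st$XtXb)                 # bbar' XtX bbar
  quadSelf <- sum(t(st$beta) * st$XtXbeta)        # sum_l beta_l' XtX beta_l
  postm2 <- st$alpha * (st$mu * st$mu + st$s2)    # L x p
  quadDiag <- sum(t(postm2) * st$d)               # sum_l sum_j alpha(mu^2+s2) d_j
  st$yty - 2 * sum(bbar * st$Xty) + quadFull - quadSelf + quadDiag
}

# Gaussian variational posterior for annotation weights w_l.
# Under the quadratic bound the optimal q(w_l) has
#   precision = I/sigmaw2_l + 2 sum_j lambda(xi_lj) A_j A_j'
#   mean      = Sigma %*% sum_j (alpha_lj - 1/2 + 2 lambda(xi_lj) rho_l) A_j
# The heavy linear algebra runs in the compiled kernel (src/wblock.cpp);
# the full covariance matrix is materialized only when wantSigma = TRUE
# (the per-iteration updates need just its trace, log-determinant, and the
# quadratic forms A_j' Sigma A_j).
.updateQW <- function(st, l, wantSigma = TRUE) {
  res <- cppUpdateQW(st$A, st$tA, st$alpha[l, ], st$xi[l, ], st$rho[l],
                     st$sigmaw2[l], wantSigma)
  st$muW[, l] <- res$mu
  if (wantSigma) st$SigmaW[[l]] <- res$Sigma
  st$trSigmaW[l] <- res$trS
  st$logdetSigmaW[l] <- res$logdetS
  st$abar[, l] <- res$abar
  st$quad[, l] <- res$quad
  st$quadFresh[l] <- TRUE
  invisible(st)
}

# Bound parameters: xi_lj tight at sqrt(E[(A_j'w_l - rho_l)^2]); rho_l at the
# stationary point of the expected bound given xi (the bound is convex
# quadratic in rho, so the closed form is the exact maximizer of F).
.updateXiRho <- function(st, l, maxInner = 10L) {
  if (isTRUE(st$quadFresh[l])) {
    abar <- st$abar[, l]
    quad <- st$quad[, l]
  } else {
    abar <- drop(st$A %*% st$muW[, l])
    quad <- rowSums((st$A %*% st$SigmaW[[l]]) * st$A)
  }
  res <- cppUpdateXiRho(abar, quad, st$rho[l], as.integer(maxInner))
  st$abar[, l] <- abar
  st$quad[, l] <- quad
  st$quadFresh[l] <- FALSE
  st$xi[l, ] <- res$xi
  st$rho[l] <- res$rho
  invisible(st)
}

# EM update of the weight variance, sigmaw2_l <- (||mu||^2 + tr Sigma)/m.
# This is the exact maximizer of F over sigmaw2_l given q(w_l) fixed.
.updateSigmaW <- function(st, l) {
  st$sigmaw2[l] <- max((sum(st$muW[, l]^2) + st$trSigmaW[l]) / st$m, .VAR_FLOOR)
  invisible(st)
}

.updateVariances <- function(st, estimateResidual) {
  if (estimateResidual)
    st$sigma2 <- max(.erss(st) / st$n, .VAR_FLOOR)
  invisible(st)
}

# Evidence lower bound F(q, Theta). With useAnnotations = FALSE (or m = 0)
# the prior on gamma is uniform and the annotation-weight terms are absent;
# this is the ELBO of the annotation-free special case and is the objective
# of stage 1. Expects abar/quad caches to be current when annotations are on.
.engineElbo <- function(st, useAnnotations) {
  ERSS <- .erss(st)
  F <- -0.5 * st$n * log(2 * pi * st$sigma2) - ERSS / (2 * st$sigma2)
  # effect prior and entropy of q(b, gamma)
  postm2 <- st$mu * st$mu + st$s2
  F <- F + sum(-0.5 * st$alpha * log(2 * pi * st$sigmab2)) -
    sum((st$alpha * postm2) / (2 * st$sigmab2))
  a <- st$alpha[st$alpha > 0]
  F <- F - sum(a * log(a))
  F <- F + sum(st$alpha * 0.5 * log(2 * pi * exp(1) * st$s2))
  if (!useAnnotations || st$m == 0) {
    F <- F - st$L * log(st$p)
  } else {
    for (l in seq_len(st$L)) {
      abar <- st$abar[, l]
      dv <- abar - st$rho[l]
      xi <- st$xi[l, ]
      lam <- lambdaXi(xi)
      ebound <- st$rho[l] + sum((dv - xi) / 2 +
        lam * (dv * dv + st$quad[, l] - xi * xi) + .log1pexp(xi))
      F <- F + sum(st$alpha[l, ] * abar) - ebound
      F <- F - 0.5 * st$m * log(st$sigmaw2[l]) -
        (sum(st$muW[, l]^2) + st$trSigmaW[l]) / (2 * st$sigmaw2[l]) +
        0.5 * st$logdetSigmaW[l] + st$m / 2
    }
  }
  if (!is.finite(F)) stop("non-finite ELBO; sigma2 = ", st$sigma2)
  F
}

# Run one fitting stage to convergence. `iterFun(st)` performs one full
# coordinate sweep; returns list(trace, converged, niter).
.runStage <- function(st, iterFun, elboFun, maxIter, tol, stageName) {
  trace <- numeric(0)
  Fold <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    iterFun(st)
    F <- elboFun(st)
    if (is.finite(Fold) && F < Fold - 1e-4)
      stop("ELBO decreased by ", signif(Fold - F, 4), " in ", stageName,
           " iteration ", it, "; this indicates an update-order or formula bug")
    trace <- c(trace, F)
    if (is.finite(Fold) && abs(F - Fold) < tol) { converged <- TRUE; break }
    Fold <- F
  }
  list(trace = trace, converged = converged, niter = it)
}

#' Fit the annotation-informed sum-of-single-effects model
#'
#' Runs the three-stage warm-started coordinate-ascent variational algorithm:
#' \enumerate{
#'   \item \strong{Stage 1} fits the annotation-free special case of the model
#'     (all annotation weights fixed at zero, uniform causal prior), yielding
#'     initial estimates of the residual variance, the per-component effect
#'     variances, and the single-effect posteriors.
#'   \item \strong{Stage 2} holds the causal-assignment posteriors
#'     \eqn{q(\gamma_l)} fixed at their stage-1 values (their posterior mean)
#'     and iterates the annotation-weight posterior, bound-parameter, and
#'     weight-variance updates to obtain rough annotation estimates.
#'   \item \strong{Stage 3} runs the full joint coordinate ascent over all
#'     variational factors and variance components, warm-started from the
#'     previous stages.
#' }
#' Each stage maximizes the same evidence lower bound (the stage-1 objective
#' is its annotation-free restriction), so the ELBO is non-decreasing within
#' every stage; a decrease beyond numerical noise raises an error. With no
#' annotations (`annotations = NULL`, an empty matrix, or all columns
#' constant) only stage 1 runs and the result is the plain sum-of-single-
#' effects (SuSiE) fit.
#'
#' @param suffstats a [FunmapSuffStats-class] object from
#'   [suffStatsFromIndividual()] or [suffStatsFromSummary()].
#' @param annotations a [FunmapAnnotations-class] object, a raw p x m matrix
#'   (passed through [annotationMatrix()]), or NULL for the annotation-free
#'   model.
#' @param L number of single-effect components (default 10). When the true
#'   number of causal signals is unknown, set L generously: excess components
#'   end up spread over all SNPs with small posterior probabilities and do
#'   not inflate PIPs appreciably.
#' @param maxIterPerStage iteration cap per stage (default 100).
#' @param elboTol convergence threshold on the absolute ELBO change
#'   (default 1e-4).
#' @param estimateResidualVariance update sigma^2 by EM (default TRUE).
#' @param estimatePriorVariances update the per-component effect variances
#'   sigma_bl^2 by EM (default TRUE). Fixing them is mainly useful for
#'   comparing against single-effect-regression oracles.
#' @param sigma2Init,sigmab2Init,sigmaw2Init initial values for the variance
#'   components. `sigma2Init = NULL` uses yty/n (= 1 for standardized
#'   phenotypes). `sigmab2Init` is the initial fraction of phenotypic
#'   variance per effect; `sigmaw2Init` the initial annotation-weight
#'   variance, on the scale of squared logits per standardized annotation.
#' @param verbose print per-stage progress.
#' @return a [FunmapFit-class] object.
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(300 * 40), 300, 40)
#' y <- drop(X[, 5] * 0.5 + rnorm(300))
#' ss <- suffStatsFromIndividual(X, y)
#' fit <- funmapFit(ss, L = 5)
#' which.max(pip(fit))  # SNP 5
#' @export
funmapFit <- function(suffstats, annotations = NULL,
                      L = 10L, maxIterPerStage = 100L, elboTol = 1e-4,
                      estimateResidualVariance = TRUE,
                      estimatePriorVariances = TRUE,
                      sigma2Init = NULL, sigmab2Init = 0.2,
                      sigmaw2Init = 0.01, verbose = FALSE) {
  stopifnot(methods::is(suffstats, "FunmapSuffStats"))
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (maxIterPerStage < 1L) stop("maxIterPerStage must be >= 1")
  if (elboTol <= 0) stop("elboTol must be positive")
  p <- length(suffstats@Xty)

  if (is.null(annotations)) {
    ann <- annotationMatrix(NULL, p = p)
  } else if (methods::is(annotations, "FunmapAnnotations")) {
    ann <- annotations
  } else {
    ann <- annotationMatrix(annotations, p = p)
  }
  if (nrow(ann@A) != p && ncol(ann@A) > 0)
    stop("annotation rows (", nrow(ann@A), ") do not match SNP panel (", p, ")")
  m <- ncol(ann@A)

  if (is.null(sigma2Init)) sigma2Init <- suffstats@yty / suffstats@n
  st <- .newEngineState(suffstats, ann@A, L, sigma2Init, sigmab2Init, sigmaw2Init)

  zeroLogit <- numeric(p)
  stage1Iter <- function(st) {
    for (l in seq_len(L)) .serUpdate(st, l, zeroLogit, estimatePriorVariances)
    .updateVariances(st, estimateResidualVariance)
  }
  s1 <- .runStage(st, stage1Iter, function(s) .engineElbo(s, FALSE),
                  maxIterPerStage, elboTol, "stage 1")
  if (verbose)
    message("stage 1: ", s1$niter, " iterations, ELBO ",
            signif(utils::tail(s1$trace, 1), 8),
            if (!s1$converged) " (not converged)" else "")
  alphaStage1 <- st$alpha

  traces <- list(s1$trace)
  stages <- list(rep(1L, length(s1$trace)))
  niter <- c(s1$niter, 0L, 0L)
  converged <- c(s1$converged, NA, NA)

  if (m > 0) {
    # stage 2: q(gamma) frozen; initialize bound parameters consistently
    # with muW = 0, SigmaW = sigmaw2 I, rho = 0
    for (l in seq_len(L)) {
      st$abar[, l] <- 0
      st$quad[, l] <- st$sigmaw2[l] * rowSums(st$A * st$A)
      st$xi[l, ] <- sqrt(st$quad[, l])
    }
    stage2Iter <- function(st) {
      for (l in seq_len(L)) {
        .updateQW(st, l, wantSigma = FALSE)
        .updateXiRho(st, l)
        .updateSigmaW(st, l)
      }
    }
    s2 <- .runStage(st, stage2Iter, function(s) .engineElbo(s, TRUE),
                    maxIterPerStage, elboTol, "stage 2")
    if (verbose)
      message("stage 2: ", s2$niter, " iterations, ELBO ",
              signif(utils::tail(s2$trace, 1), 8),
              if (!s2$converged) " (not converged)" else "")

    stage3Iter <- function(st) {
      for (l in seq_len(L))
        .serUpdate(st, l, drop(st$A %*% st$muW[, l]), estimatePriorVariances)
      for (l in seq_len(L)) {
        .updateQW(st, l, wantSigma = FALSE)
        .updateXiRho(st, l)
        .updateSigmaW(st, l)
      }
      .updateVariances(st, estimateResidualVariance)
    }
    s3 <- .runStage(st, stage3Iter, function(s) .engineElbo(s, TRUE),
                    maxIterPerStage, elboTol, "stage 3")
    if (verbose)
      message("stage 3: ", s3$niter, " iterations, ELBO ",
              signif(utils::tail(s3$trace, 1), 8),
              if (!s3$converged) " (not converged)" else "")

    # one closing q(w) update per component so the stored (muW, SigmaW)
    # pair is the exact Gaussian coordinate maximizer for the stored
    # (alpha, xi, rho, sigmaw2) -- a further monotone step, and the state
    # the annotation-importance scores are read from
    for (l in seq_len(L)) .updateQW(st, l, wantSigma = TRUE)

    traces <- c(traces, list(s2$trace, s3$trace))
    stages <- c(stages, list(rep(2L, length(s2$trace)), rep(3L, length(s3$trace))))
    niter <- c(s1$niter, s2$niter, s3$niter)
    converged <- c(s1$converged, s2$converged, s3$converged)
  }

  # non-convergence is not an error: the best state is returned and the
  # per-stage `converged` flags record it (check `fit@converged`)
  if (verbose && any(!converged, na.rm = TRUE))
    message("note: iteration cap reached in stage(s) ",
            paste(which(!converged), collapse = ", "))

  annNames <- annotationNames(ann)
  if (is.null(annNames)) annNames <- character(0)
  methods::new("FunmapFit",
    alpha = st$alpha, mu = st$mu, s2 = st$s2,
    alphaStage1 = alphaStage1,
    muW = st$muW, SigmaW = st$SigmaW,
    xi = st$xi, rho = st$rho,
    sigma2 = st$sigma2, sigmab2 = st$sigmab2, sigmaw2 = st$sigmaw2,
    pip = computePip(st$alpha),
    elboTrace = unlist(traces),
    elboStage = unlist(stages),
    niter = as.integer(niter),
    converged = as.logical(ifelse(is.na(converged), TRUE, converged)),
    snpIds = suffstats@snpIds,
    annotationNames = annNames,
    config = list(L = L, maxIterPerStage = maxIterPerStage, elboTol = elboTol,
                  estimateResidualVariance = estimateResidualVariance,
                  estimatePriorVariances = estimatePriorVariances,
                  sigma2Init = sigma2Init, sigmab2Init = sigmab2Init,
                  sigmaw2Init = sigmaw2Init, m = m)
  )
}

#' @describeIn elboTrace ELBO values with a `stage` attribute.
#' @export
setMethod("elboTrace", "FunmapFit", function(object) {
  structure(object@elboTrace, stage = object@elboStage)
})

#' @describeIn snpIds SNP ids of a fitted model.
#' @export
setMethod("snpIds", "FunmapFit", function(object) object@snpIds)

#' @describeIn annotationNames Annotation names of a fitted model.
#' @export
setMethod("annotationNames", "FunmapFit", function(object) object@annotationNames)

#' @export
setMethod("show", "FunmapFit", function(object) {
  L <- nrow(object@alpha); p <- ncol(object@alpha)
  m <- length(object@annotationNames)
  cat("FunmapFit: p =", p, "SNPs, L =", L, "components, m =", m, "annotations\n")
  cat("  final ELBO:", signif(utils::tail(object@elboTrace, 1), 8),
      " iterations per stage:", paste(object@niter, collapse = "/"), "\n")
  cat("  sigma2 =", signif(object@sigma2, 4),
      "; top PIP:", signif(max(object@pip), 4),
      "(", object@snpIds[which.max(object@pip)], ")\n")
  cs <- credibleSets(object)
  cat("  credible sets (delta = 0.95, no purity filter):", length(cs), "\n")
  invisible(object)
})
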