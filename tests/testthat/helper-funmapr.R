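# Shared fixtures, built in code at test time.

# A small simulated locus with sufficient statistics and annotations.
smallLocus <- function(seed, n = 400, p = 60, m = 8, L0 = 2, h2 = 0.02,
                       wVar = 0.02, sparsity = 1, rho = 0.5) {
  d <- simulationDesign(n = n, p = p, m = m, L0 = L0, h2 = h2, wVar = wVar,
                        sparsity = sparsity,
                        ldModel = list(type = "ar1", rho = rho), seed = seed)
  sim <- simulateLocus(d)
  ss <- suffStatsFromIndividual(sim$X, sim$y, standardize = FALSE)
  list(design = d, sim = sim, ss = ss,
       ann = annotationMatrix(sim$A, p = p))
}

# Orthogonal mean-zero standardized columns (Helmert contrasts).
orthogonalGenotypes <- function(n, p) {
  stopifnot(p < n)
  H <- stats::contr.helmert(n)[, seq_len(p), drop = FALSE]
  standardizeColumns(unname(H))
}

# Independent oracle for the single-SNP marginal likelihood
# log p(y | gamma = j) under y ~ N(0, sigma2 I + sigmab2 x x'),
# evaluated through the marginal covariance (Sherman-Morrison), i.e. a
# different algebraic route than the engine's posterior-variance/BF path.
logMarginalSingleSnp <- function(x, y, sigma2, sigmab2) {
  n <- length(y)
  xx <- sum(x * x)
  xy <- sum(x * y)
  yy <- sum(y * y)
  logdet <- n * log(sigma2) + log1p(sigmab2 * xx / sigma2)
  quad <- (yy - sigmab2 * xy^2 / (sigma2 + sigmab2 * xx)) / sigma2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

# Exact log marginal likelihood of the p-model single-effect mixture with
# uniform prior, by enumeration.
logMarginalEnumeration <- function(X, y, sigma2, sigmab2) {
  lm <- vapply(seq_len(ncol(X)), function(j)
    logMarginalSingleSnp(X[, j], y, sigma2, sigmab2), numeric(1))
  a <- lm - log(ncol(X))
  mx <- max(a)
  mx + log(sum(exp(a - mx)))
}

# Stable reference log-sum-exp.
refLogSumExp <- function(a) {
  m <- max(a)
  m + log(sum(exp(a - m)))
}

# Within-stage ELBO increments of a fit.
stageDeltas <- function(fit) {
  tr <- elboTrace(fit)
  st <- attr(tr, "stage")
  unlist(lapply(unique(st), function(s) diff(tr[st == s])))
}
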