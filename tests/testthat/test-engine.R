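# Internal-state helpers for exercising single coordinate updates.
newState <- function(ss, A = NULL, L = 1L, sigma2 = 1, sigmab2 = 0.3,
                     sigmaw2 = 0.01) {
  if (is.null(A)) A <- matrix(0, length(ss@Xty), 0)
  funmapr:::.newEngineState(ss, A, L, sigma2, sigmab2, sigmaw2)
}

test_that("single-effect update gives uniform alpha when nothing distinguishes SNPs", {
  n <- 24; p <- 4
  X <- orthogonalGenotypes(n, p)
  y <- standardizeColumns(matrix(stats::contr.helmert(n)[, p + 1], ncol = 1))
  ss <- suffStatsFromIndividual(X, drop(y), standardize = FALSE)
  expect_lt(max(abs(ss@Xty)), 1e-8)   # y orthogonal to every SNP
  st <- newState(ss)
  funmapr:::.serUpdate(st, 1L, numeric(p))
  expect_equal(drop(st$alpha), rep(1 / p, p), tolerance = 1e-10)
})

test_that("a dominant prior logit concentrates alpha on that SNP", {
  loc <- smallLocus(seed = 21, n = 200, p = 20, m = 0)
  st <- newState(loc$ss)
  logits <- numeric(20)
  logits[7] <- 50
  funmapr:::.serUpdate(st, 1L, logits)
  expect_gte(st$alpha[1, 7], 0.99)
})

test_that("SER posterior matches exhaustive single-SNP model enumeration", {
  set.seed(22)
  n <- 40; p <- 3
  X <- orthogonalGenotypes(n, p)
  y <- drop(0.5 * X[, 2]) + rnorm(n)
  y <- (y - mean(y)) / sqrt(mean(y^2) - mean(y)^2)
  ss <- suffStatsFromIndividual(X, y, standardize = FALSE)
  sigma2 <- 0.8; sigmab2 <- 0.25
  st <- newState(ss, sigma2 = sigma2, sigmab2 = sigmab2)
  funmapr:::.serUpdate(st, 1L, numeric(p))
  # oracle: exact marginal likelihood of each of the 3 single-SNP models via
  # the marginal covariance (different algebra than the engine's BF path)
  lm3 <- vapply(1:3, function(j)
    logMarginalSingleSnp(X[, j], y, sigma2, sigmab2), numeric(1))
  alphaOracle <- exp(lm3 - refLogSumExp(lm3))
  expect_equal(drop(st$alpha), alphaOracle, tolerance = 1e-10)
})

test_that("q(w) reduces to the prior when annotations carry no signal", {
  # A = 0 is excluded upstream (constant columns dropped); calling the
  # kernel directly confirms the no-data-term limit mu = 0, Sigma = v I
  p <- 12; m <- 3; v <- 0.05
  A <- matrix(0, p, m)
  res <- funmapr:::cppUpdateQW(A, t(A), rep(1 / p, p), rep(0.5, p), 0.2, v, TRUE)
  expect_equal(drop(res$mu), rep(0, m))
  expect_equal(res$Sigma, diag(v, m), tolerance = 1e-12)
})

test_that("q(w) shrinks to zero as the prior variance vanishes", {
  set.seed(23)
  p <- 50; m <- 4
  A <- matrix(rnorm(p * m), p, m)
  alpha <- as.numeric(prop.table(runif(p)))
  xi <- runif(p, 0, 2)
  big <- funmapr:::cppUpdateQW(A, t(A), alpha, xi, 0.1, 0.5, FALSE)
  small <- funmapr:::cppUpdateQW(A, t(A), alpha, xi, 0.1, 0.5 / 100, FALSE)
  tiny <- funmapr:::cppUpdateQW(A, t(A), alpha, xi, 0.1, 1e-10, FALSE)
  expect_lt(sqrt(sum(small$mu^2)), sqrt(sum(big$mu^2)))
  expect_lt(sqrt(sum(tiny$mu^2)), 1e-6)
})

test_that("q(w) mean is a stationary point of the bound-augmented objective", {
  set.seed(24)
  for (i in 1:5) {
    p <- 5; m <- 2
    A <- matrix(rnorm(p * m), p, m)
    alpha <- as.numeric(prop.table(runif(p)))
    xi <- runif(p, 0, 3)
    rho <- rnorm(1)
    sw <- runif(1, 0.01, 1)
    res <- funmapr:::cppUpdateQW(A, t(A), alpha, xi, rho, sw, FALSE)
    obj <- function(w) {
      aw <- drop(A %*% w)
      lam <- lambdaXi(xi)
      sum(alpha * aw) -
        (rho + sum((aw - rho - xi) / 2 + lam * ((aw - rho)^2 - xi^2) +
                     log1p(exp(xi)))) -
        sum(w^2) / (2 * sw)
    }
    mu <- res$mu
    eps <- 1e-6
    grad <- vapply(seq_len(m), function(k) {
      e <- numeric(m); e[k] <- eps
      (obj(mu + e) - obj(mu - e)) / (2 * eps)
    }, numeric(1))
    expect_lt(sqrt(sum(grad^2)), 1e-6)
  }
})

test_that("xi update degenerates correctly when q(w) collapses", {
  # w-posterior a point mass at 0 and rho = 0: xi = 0 for all SNPs
  res <- funmapr:::cppUpdateXiRho(rep(0, 8), rep(0, 8), 0, 0L)
  expect_equal(drop(res$xi), rep(0, 8))
  # Sigma = 0, mu fixed: xi = |A_j' mu - rho|
  set.seed(25)
  abar <- rnorm(10)
  res2 <- funmapr:::cppUpdateXiRho(abar, rep(0, 10), 0.3, 0L)
  expect_equal(drop(res2$xi), abs(abar - 0.3), tolerance = 1e-12)
})

test_that("variance component updates honor their closed forms", {
  # all alpha mass on one SNP with mu = 0 everywhere: sigma2 = yty/n = 1
  loc <- smallLocus(seed = 26, n = 100, p = 10, m = 0)
  st <- newState(loc$ss, L = 2L)
  st$alpha[, ] <- 0
  st$alpha[, 3] <- 1
  st$mu[, ] <- 0
  st$s2[, ] <- 0
  st$beta[, ] <- 0
  st$XtXbeta[, ] <- 0
  st$XtXb[] <- 0
  funmapr:::.updateVariances(st, TRUE)
  expect_equal(st$sigma2, loc$ss@yty / loc$ss@n, tolerance = 1e-10)
  expect_equal(st$sigma2, 1, tolerance = 1e-6)
  # muW = 0, Sigma = c I: EM weight variance equals c (trace identity)
  st2 <- newState(loc$ss, A = matrix(rnorm(50), 10, 5), L = 1L)
  st2$muW[, 1] <- 0
  st2$SigmaW[[1]] <- diag(0.07, 5)
  st2$trSigmaW[1] <- 5 * 0.07
  funmapr:::.updateSigmaW(st2, 1L)
  expect_equal(st2$sigmaw2[1], 0.07, tolerance = 1e-12)
})

test_that("expected residual sum of squares matches a Monte-Carlo oracle", {
  set.seed(27)
  loc <- smallLocus(seed = 27, n = 60, p = 4, m = 0, L0 = 1, h2 = 0.05)
  ss <- loc$ss
  st <- newState(ss, L = 2L, sigmab2 = 0.1)
  for (it in 1:2) for (l in 1:2) funmapr:::.serUpdate(st, l, numeric(4))
  erss <- funmapr:::.erss(st)
  # brute-force draws from q: gamma_l ~ Cat(alpha_l), b_l | gamma_l ~ N(mu, s2)
  X <- loc$sim$X; y <- loc$sim$y
  nmc <- 1e5
  tot <- 0
  for (l in 1:2) assign(paste0("idx", l), sample.int(4, nmc, TRUE, prob = st$alpha[l, ]))
  b1 <- rnorm(nmc, st$mu[1, idx1], sqrt(st$s2[1, idx1]))
  b2 <- rnorm(nmc, st$mu[2, idx2], sqrt(st$s2[2, idx2]))
  rss <- numeric(nmc)
  Xy <- crossprod(X, y); XX <- crossprod(X); yy <- sum(y * y)
  for (i in seq_len(nmc)) {
    bv <- numeric(4)
    bv[idx1[i]] <- bv[idx1[i]] + b1[i]
    bv[idx2[i]] <- bv[idx2[i]] + b2[i]
    rss[i] <- yy - 2 * sum(bv * Xy) + drop(t(bv) %*% XX %*% bv)
  }
  se <- sd(rss) / sqrt(nmc)
  expect_lt(abs(mean(rss) - erss), 5 * se)
})

test_that("the ELBO of the annotation-free single-effect fit equals the exact evidence", {
  # with L = 1, m = 0 and fixed variances the mean-field family contains the
  # exact posterior, so F must equal the enumerated log marginal likelihood
  set.seed(28)
  n <- 80; p <- 3
  X <- standardizeColumns(matrix(rnorm(n * p), n, p))
  y <- drop(0.3 * X[, 2] + rnorm(n))
  y <- (y - mean(y)) / sqrt(mean(y^2) - mean(y)^2)
  ss <- suffStatsFromIndividual(X, y, standardize = FALSE)
  fit <- funmapFit(ss, NULL, L = 1, estimateResidualVariance = FALSE,
                   estimatePriorVariances = FALSE, sigma2Init = 1,
                   sigmab2Init = 0.2)
  exact <- logMarginalEnumeration(X, y, 1, 0.2)
  Ffinal <- unname(tail(elboTrace(fit), 1))
  expect_lte(Ffinal, exact + 1e-8)
  expect_equal(Ffinal, exact, tolerance = 1e-8)
})

test_that("stage 1 recovers a strong causal SNP under weak LD", {
  loc <- smallLocus(seed = 29, n = 1000, p = 50, m = 0, L0 = 1, h2 = 0.05,
                    rho = 0.1)
  fit <- funmapFit(loc$ss, NULL, L = 5)
  causal <- loc$sim$truth$causal
  expect_gte(max(fit@alpha[, causal]), 0.95)
})

test_that("null phenotypes rarely reach high PIPs", {
  set.seed(30)
  high <- 0
  for (r in 1:50) {
    X <- matrix(rnorm(200 * 50), 200, 50)
    y <- rnorm(200)
    fit <- funmapFit(suffStatsFromIndividual(X, y), NULL, L = 5)
    if (max(fit@pip) >= 0.5) high <- high + 1
  }
  expect_lte(high, 2)  # >= 95% of replicates below 0.5
})

test_that("stage 2 leaves weights near zero for uninformative annotations and finds informative ones", {
  # null: stage-1 alpha carries signal but annotations are pure noise
  set.seed(31)
  n <- 1500; p <- 80; m <- 6
  X <- standardizeColumns(matrix(rnorm(n * p), n, p))
  y <- drop(0.25 * X[, 10] + rnorm(n))
  ss <- suffStatsFromIndividual(X, y)
  Anoise <- matrix(rnorm(p * m), p, m)
  fitNoise <- funmapFit(ss, annotationMatrix(Anoise), L = 5)
  # informative: one annotation singles out the causal SNP
  Ainfo <- Anoise
  Ainfo[, 3] <- 0
  Ainfo[10, 3] <- 10
  fitInfo <- funmapFit(ss, annotationMatrix(Ainfo), L = 5)
  FI <- featureImportance(fitInfo)
  expect_equal(unname(which.max(FI)), 3L)
  # the informative annotation dominates the noise-fit importance scale
  expect_gt(max(FI), 10 * max(featureImportance(fitNoise)))
})

test_that("zero-information annotations reproduce the stage-1 fit exactly", {
  loc <- smallLocus(seed = 32, n = 400, p = 60, m = 0, h2 = 0.03)
  A0 <- matrix(0, 60, 4)
  expect_warning(fit <- funmapFit(loc$ss, A0, L = 5), "constant")
  expect_lt(max(abs(fit@pip - computePip(fit@alphaStage1))), 1e-6)
  fitNull <- funmapFit(loc$ss, NULL, L = 5)
  expect_equal(fit@pip, fitNull@pip, tolerance = 1e-12)
})

test_that("fits are deterministic", {
  loc <- smallLocus(seed = 33)
  f1 <- funmapFit(loc$ss, loc$ann, L = 5)
  f2 <- funmapFit(loc$ss, loc$ann, L = 5)
  expect_identical(f1@elboTrace, f2@elboTrace)
  expect_identical(f1@pip, f2@pip)
})

test_that("the fit is equivariant under SNP permutation", {
  loc <- smallLocus(seed = 34, n = 500, p = 40, m = 5, h2 = 0.03)
  fit <- funmapFit(loc$ss, loc$ann, L = 4)
  set.seed(1)
  perm <- sample(40)
  Xp <- loc$sim$X[, perm]
  ssP <- suffStatsFromIndividual(Xp, loc$sim$y, standardize = FALSE)
  annP <- annotationMatrix(loc$sim$A[perm, , drop = FALSE], p = 40)
  fitP <- funmapFit(ssP, annP, L = 4)
  expect_equal(unname(fitP@pip), unname(fit@pip[perm]), tolerance = 1e-8)
  expect_equal(tail(fitP@elboTrace, 1), tail(fit@elboTrace, 1),
               tolerance = 1e-8)
})

test_that("excess components are spread out rather than inventing signals", {
  set.seed(35)
  bad <- 0
  for (r in 1:20) {
    loc <- smallLocus(seed = 3500 + r, n = 2000, p = 100, m = 0, L0 = 2,
                      h2 = 0.05)
    fit <- funmapFit(loc$ss, NULL, L = 10)
    concentrated <- sum(apply(fit@alpha, 1, max) > 0.5)
    if (concentrated > 3) bad <- bad + 1
  }
  expect_lte(bad, 2)  # at most 3 concentrated components in >= 90% of reps
})

test_that("invalid fitting configurations are rejected", {
  loc <- smallLocus(seed = 36, n = 100, p = 10, m = 0)
  expect_error(funmapFit(loc$ss, NULL, L = 0), "L must be")
  expect_error(funmapFit(loc$ss, NULL, elboTol = 0), "elboTol")
  expect_error(funmapFit(loc$ss, matrix(rnorm(22), 11, 2)), "does not match")
})
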