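# Theoretical correlation of two thresholded-Gaussian haplotype indicators
# with latent correlation rho and allele frequencies f1, f2, by 1-D numeric
# integration of the bivariate normal orthant probability.
thresholdedCorr <- function(rho, f1, f2) {
  t1 <- qnorm(f1); t2 <- qnorm(f2)
  p11 <- integrate(function(z) dnorm(z) * pnorm((t2 - rho * z) / sqrt(1 - rho^2)),
                   -Inf, t1, rel.tol = 1e-10)$value
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

test_that("independent latent SNPs give near-zero sample correlations", {
  d <- simulationDesign(n = 2000, p = 40, ldModel = list(type = "ar1", rho = 0),
                        seed = 50)
  g <- simulateGenotypes(d)
  C <- crossprod(g$X) / d$n
  off <- abs(C[upper.tri(C)])
  expect_lt(mean(off), 3 / sqrt(d$n))
})

test_that("adjacent-SNP correlation matches the thresholded-Gaussian theory", {
  d <- simulationDesign(n = 4000, p = 60, ldModel = list(type = "ar1", rho = 0.9),
                        seed = 51)
  g <- simulateGenotypes(d)
  obs <- vapply(seq_len(d$p - 1), function(j)
    cor(g$X[, j], g$X[, j + 1]), numeric(1))
  theo <- vapply(seq_len(d$p - 1), function(j)
    thresholdedCorr(0.9, g$maf[j], g$maf[j + 1]), numeric(1))
  expect_lt(abs(mean(obs) - mean(theo)), 0.1)
  # realized LD increases with rho
  d0 <- simulationDesign(n = 4000, p = 60, ldModel = list(type = "ar1", rho = 0.3),
                         seed = 51)
  g0 <- simulateGenotypes(d0)
  obs0 <- vapply(seq_len(d0$p - 1), function(j)
    cor(g0$X[, j], g0$X[, j + 1]), numeric(1))
  expect_gt(mean(obs), mean(obs0))
})

test_that("block LD model produces within-block but not between-block correlation", {
  d <- simulationDesign(n = 3000, p = 30,
                        ldModel = list(type = "block", size = 10, rho = 0.8),
                        seed = 52)
  g <- simulateGenotypes(d)
  C <- crossprod(g$X) / d$n
  within <- mean(abs(C[1:10, 1:10][upper.tri(matrix(0, 10, 10))]))
  between <- mean(abs(C[1:10, 11:20]))
  expect_gt(within, 5 * between)
})

test_that("genotype simulation is reproducible and standardized", {
  d <- simulationDesign(n = 300, p = 20, seed = 53)
  g1 <- simulateGenotypes(d)
  g2 <- simulateGenotypes(d)
  expect_identical(g1$X, g2$X)
  expect_lt(max(abs(colMeans(g1$X))), 1e-10)
  expect_lt(max(abs(colMeans(g1$X^2) - 1)), 1e-8)
  expect_true(all(g1$Xraw %in% 0:2))
})

test_that("annotation weights honor sparsity and scale", {
  d <- simulationDesign(p = 500, m = 100, sparsity = 1, wVar = 0.01, seed = 54)
  aw <- simulateAnnotations(d)
  expect_equal(sum(aw$w != 0), 100)
  # sample variance of w within 3 standard errors of wVar
  se <- 0.01 * sqrt(2 / (100 - 1))
  expect_lt(abs(var(aw$w) - 0.01), 3 * se)
  d2 <- simulationDesign(p = 100, m = 100, sparsity = 0.01, seed = 55)
  aw2 <- simulateAnnotations(d2)
  expect_equal(sum(aw2$w != 0), 1)
  expect_identical(which(aw2$w != 0), aw2$relevant)
  d3 <- simulationDesign(p = 50, m = 10, sparsity = 0, seed = 56)
  aw3 <- simulateAnnotations(d3)
  expect_true(all(aw3$w == 0))
  expect_equal(unname(causalProbabilities(aw3$A, aw3$w)), rep(1 / 50, 50))
})

test_that("softmax causal probabilities behave as a softmax", {
  A <- diag(2)
  expect_equal(causalProbabilities(A, c(log(3), 0)), c(0.75, 0.25))
  set.seed(57)
  A2 <- matrix(rnorm(40), 20, 2)
  w <- c(0.5, -1)
  p1 <- causalProbabilities(A2, w)
  expect_equal(sum(p1), 1)
  # invariant to a shared shift of all logits
  p2 <- causalProbabilities(cbind(A2, 1), c(w, 7))
  expect_equal(p1, p2, tolerance = 1e-12)
  # overflow guard
  expect_false(any(is.nan(causalProbabilities(A2 * 500, w))))
})

test_that("greedy causal selection respects the correlation cap", {
  set.seed(58)
  X <- standardizeColumns(matrix(rnorm(500 * 6), 500, 6))
  pi <- c(0.4, 0.3, 0.15, 0.1, 0.03, 0.02)
  expect_equal(selectCausalSnps(pi, X, 2), c(1L, 2L))
  # make the top-2 SNPs perfectly correlated: the second pick must skip to
  # the next eligible SNP
  X2 <- X
  X2[, 2] <- X2[, 1]
  expect_equal(selectCausalSnps(pi, X2, 2), c(1L, 3L))
  expect_error(selectCausalSnps(pi, X, 0), "L0")
  # all SNPs identical: impossible to find 2 weakly correlated causals
  X3 <- X[, c(1, 1, 1, 1, 1, 1)]
  expect_error(selectCausalSnps(pi, X3, 2), "too correlated")
})

test_that("phenotype generation hits the target regional heritability on average", {
  d <- simulationDesign(n = 4000, p = 50, m = 10, L0 = 2, h2 = 0.0075, seed = 59)
  g <- simulateGenotypes(d)
  h2s <- vapply(1:200, function(r)
    simulatePhenotype(g$X, c(3, 27), d, seed = 59000 + r)$h2Realized,
    numeric(1))
  se <- sd(h2s) / sqrt(length(h2s))
  expect_lt(abs(mean(h2s) - 0.0075), 3 * se)
})

test_that("the high-heritability limit gives diverging causal z-scores", {
  d <- simulationDesign(n = 1000, p = 30, L0 = 1, h2 = 0.999, seed = 60)
  g <- simulateGenotypes(d)
  ph <- simulatePhenotype(g$X, 7, d)
  expect_gt(abs(ph$z[7]), 15)
  # and reproducibility under a fixed seed
  ph2 <- simulatePhenotype(g$X, 7, d)
  expect_identical(ph$y, ph2$y)
  expect_identical(ph$z, ph2$z)
})

test_that("benchmark metrics follow their counting definitions", {
  sel <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(efdr(sel, c(1, 3)), 0)
  expect_equal(efdr(sel, c(1, 2)), 0.5)
  expect_equal(efdr(rep(FALSE, 4), c(1)), 0)
  pipv <- c(0.95, 0.5, 0.99, 0.1)
  expect_equal(powerAtPip(pipv, c(1, 3), 0.9), 1)
  expect_equal(powerAtPip(pipv, c(2, 4), 0.9), 0)
  expect_equal(powerAtPip(pipv, c(1, 2), 0.9), 0.5)
  am <- annotationSelectionMetrics(c(1, rep(0, 99)), relevant = 1,
                                   topFraction = 0.05)
  expect_equal(am$power, 1)
  expect_equal(am$fpr, 4 / 99)
  am2 <- annotationSelectionMetrics(c(5, 4, 1, 0), relevant = 1:2,
                                    topFraction = 0.5)
  expect_equal(am2$power, 1)
  expect_equal(am2$fpr, 0)
  expect_true(is.na(annotationSelectionMetrics(runif(10), integer(0), 0.1)$power))
})

test_that("random importance scores select relevant annotations at chance level", {
  set.seed(61)
  pw <- vapply(1:300, function(i) {
    FI <- runif(100)
    annotationSelectionMetrics(FI, relevant = 1:10, topFraction = 0.2)$power
  }, numeric(1))
  expect_lt(abs(mean(pw) - 0.2), 0.03)
})

test_that("a reduced benchmark run completes, is deterministic, and is well-formed", {
  d <- simulationDesign(n = 500, p = 60, m = 10, L0 = 2, h2 = 0.05,
                        wVar = 0.05, seed = 62)
  bm <- runBenchmark(d, nReplicates = 4, nRegions = 2,
                     nominalFdr = c(0.05, 0.1), pipThresholds = c(0.9),
                     topFractions = c(0.1), L = 5)
  expect_equal(bm$failures, 0)
  expect_setequal(unique(bm$perReplicate$method), c("funmap", "stage1_only"))
  expect_equal(nrow(bm$perReplicate), 8)
  expect_true(all(c("D_0.05", "TP_0.05", "power_0.9") %in% names(bm$perReplicate)))
  expect_true(all(bm$efdr$efdr >= 0 & bm$efdr$efdr <= 1))
  bm2 <- runBenchmark(d, nReplicates = 4, nRegions = 2,
                      nominalFdr = c(0.05, 0.1), pipThresholds = c(0.9),
                      topFractions = c(0.1), L = 5)
  expect_identical(bm$perReplicate, bm2$perReplicate)
})
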