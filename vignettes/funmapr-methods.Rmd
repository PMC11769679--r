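---
title: "Annotation-informed fine-mapping with funmapr: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed fine-mapping with funmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funmapr)
```

## The model

Fine-mapping asks which variants inside a GWAS-associated region are causal,
given that linkage disequilibrium (LD) makes many variants statistically
indistinguishable. `funmapr` fits a sum-of-single-effects linear model in
which the causal prior of each SNP is informed by its functional
annotations:

$$
y = X\sum_{l=1}^{L}\gamma_l b_l + e, \qquad e \sim N(0, \sigma^2 I_n),
$$

where each component $l$ carries exactly one causal signal:
$\gamma_l \in \{0,1\}^p$ is a one-hot indicator with
$\gamma_l \sim \mathrm{Mult}(1, \pi_l)$ and $b_l \sim N(0, \sigma^2_{b_l})$
its scalar effect. The causal prior of component $l$ is a softmax over the
annotation matrix $A \in \mathbb{R}^{p\times m}$:

$$
\pi_{lj} = \frac{e^{A_j^\top w_l}}{\sum_{j'} e^{A_{j'}^\top w_l}},
\qquad w_l \sim N(0, \sigma^2_{w_l} I_m).
$$

The annotation weights are *component-specific random effects*, not shared
fixed effects. This is the key robustness device: $\sigma^2_{w_l}$ is
estimated from the data, so when the annotations carry no information about
where component $l$'s signal sits, the weights are shrunk toward zero and
the model degrades gracefully to the uniform-prior (SuSiE) special case
instead of overfitting $m$ free parameters to a single region. Both columns
of $X$ and $y$ are standardized with the population convention (variance
denominator $n$), so $x_j^\top x_j = n$ exactly.

### Summary-statistics input

The likelihood depends on the data only through
$(X^\top X,\ X^\top y,\ y^\top y,\ n)$. Given marginal z-scores
$z_j = \hat\beta_j/\hat s_j$ (with
$\hat s_j^2 = \lVert y - x_j\hat\beta_j\rVert^2/(n\,x_j^\top x_j)$) and an
LD correlation matrix $R$, these are recovered as

$$
X^\top X = nR, \qquad
(X^\top y)_j = \frac{n z_j}{\sqrt{n + z_j^2}}, \qquad
y^\top y = n .
$$

The middle identity is the exact algebraic inversion of the z-score formula
under population-variance standardization; the package's round-trip test
(simulate individual data, compute z and in-sample R, reconstruct) verifies
elementwise agreement to $10^{-8}$, and summary-mode and individual-mode
fits agree in PIP to $10^{-6}$. With out-of-sample (reference-panel) LD this
identity is approximate; `suffStatsFromSummary()` accepts any
near-positive-semidefinite $R$, clipping eigenvalues in $(-10^{-6}, 0)$ to
zero without rescaling and rejecting anything more indefinite.

## Variational inference with a softmax bound

The softmax normalizer makes the marginal likelihood intractable. The
package bounds it with the double-majorization (quadratic) upper bound

$$
\log\!\sum_{j'} e^{a_{j'}} \le
\rho + \sum_{j'}\left[\frac{a_{j'}-\rho-\xi_{j'}}{2}
+ \lambda(\xi_{j'})\big((a_{j'}-\rho)^2 - \xi_{j'}^2\big)
+ \log(1+e^{\xi_{j'}})\right],
$$

with $\lambda(\xi) = \frac{1}{2\xi}(\frac{1}{1+e^{-\xi}}-\frac12)$,
per-term parameters $\xi_{lj}\ge 0$ and a per-component shift
$\rho_l \in \mathbb{R}$. $\lambda$ is evaluated as
$\tanh(\xi/2)/(4\xi)$ with the series $1/8-\xi^2/96$ below $10^{-4}$, so the
$0/0$ limit $\lambda(0)=1/8$ is exact. Substituting the bound for the
softmax denominator makes the complete-data log-likelihood quadratic in
$w_l$, so under the mean-field family
$q = \prod_l q(b_l\mid\gamma_l)\,q(\gamma_l)\,q(w_l)$ every factor has a
closed-form coordinate update:

* $q(\gamma_l, b_l)$: a Bayesian single-effect regression on the residual
  cross-products, with unnormalized prior log-weights $A_j^\top \mu_{w_l}$
  — the bound's denominator terms do not depend on *which* SNP carries the
  component, so they cancel in the softmax normalization of
  $\alpha_{lj} = q(\gamma_{lj}=1)$.
* $q(w_l) = N(\mu_{w_l}, \Sigma_{w_l})$ with precision
  $I/\sigma^2_{w_l} + 2\sum_j \lambda(\xi_{lj}) A_j A_j^\top$ and mean
  $\Sigma_{w_l}\sum_j(\alpha_{lj} - \tfrac12 + 2\lambda(\xi_{lj})\rho_l)A_j$.
  The test suite certifies this closed form against a numerical-gradient
  oracle: the gradient of the bound-augmented objective at the returned mean
  is zero to $10^{-6}$.
* $\xi_{lj} \leftarrow \sqrt{(A_j^\top\mu_{w_l}-\rho_l)^2 +
  A_j^\top\Sigma_{w_l}A_j}$ (the tightness condition), and $\rho_l$ at the
  stationary point of the expected bound,
  $\rho_l = \big(\sum_j 2\lambda(\xi_{lj})A_j^\top\mu_{w_l} + p/2 - 1\big)
  / \sum_j 2\lambda(\xi_{lj})$. The expected bound is convex quadratic in
  $\rho_l$, so this closed form is its exact maximizer. Because a single
  $\xi\leftrightarrow\rho$ alternation approaches their joint fixed point
  only geometrically, the implementation runs a short burst (up to 10) of
  these $O(p)$ alternations per outer iteration; every sub-step is a
  monotone coordinate update, so any burst length preserves the ascent
  guarantee.

Variance components: $\sigma^2$ is updated as the expected residual sum of
squares over $n$ (computed entirely through sufficient statistics, including
posterior second moments); $\sigma^2_{w_l} \leftarrow
(\lVert\mu_{w_l}\rVert^2 + \mathrm{tr}\,\Sigma_{w_l})/m$; and
$\sigma^2_{b_l}$ is set, inside each single-effect update, to the maximizer
of that component's evidence $\log\sum_j \pi_{lj}\,\mathrm{BF}_j(\sigma^2_b)$
(a 1-D optimization on the log scale over $[10^{-10}, 2]$). The profile
update for $\sigma^2_{b_l}$ is an exact block maximization — jointly with
the subsequent posterior computation it cannot decrease the objective — and
it switches signal-free components off in one step instead of letting their
variance decay geometrically over many iterations. All variances are floored
at $10^{-10}$.

## Three-stage fitting

1. **Stage 1** fits the annotation-free special case (uniform prior, all
   $w_l \equiv 0$): the objective is the SuSiE evidence lower bound, and the
   result initializes $\sigma^2$, $\sigma^2_{b_l}$, and $q(b,\gamma)$.
2. **Stage 2** freezes each $\alpha_l$ at its stage-1 value (the posterior
   mean of $\gamma_l$) and iterates the $q(w_l)$, $(\xi,\rho)$, and
   $\sigma^2_{w_l}$ updates, producing rough annotation estimates.
3. **Stage 3** runs the full joint coordinate ascent, warm-started from
   stages 1–2. One closing $q(w_l)$ update per component is applied after
   convergence so the stored weight posterior is exactly the Gaussian
   coordinate maximizer of the stored state.

The update order within a stage-3 iteration is: all $L$ single-effect
updates, then the weight block ($q(w_l)$, $\xi$, $\rho$, $\sigma^2_{w_l}$
per component), then the residual variance. Each block is a valid coordinate
ascent step on the same objective, so the evidence lower bound is
non-decreasing within every stage; the engine raises a hard error if it ever
drops by more than $10^{-4}$ (that would indicate an update-order or formula
bug), and the test suite checks $10^{-6}$-level monotonicity across dozens
of random fits. Whether $(\xi, \rho)$ is updated before or after $q(w)$ is
not determined by the model; the implemented order ($q(w)$ first, then
$\xi,\rho$) is certified by the same monotonicity contract.

Convergence is declared when the ELBO changes by less than `elboTol`
(default $10^{-4}$) within a stage, with at most `maxIterPerStage` (default
100) iterations per stage. In practice stage 1 converges in a handful of
iterations; stages 2–3 often run to the iteration cap, because the EM update
for $\sigma^2_{w_l}$ approaches its stationary point only geometrically when
the annotation evidence is weak. This is expected behavior of the
random-effects construction, and the iteration cap is an integral part of
the method: the warm-started, capped schedule is precisely what prevents the
high-dimensional annotation block from overfitting. With `L`
set generously (default 10), excess components end their trajectory spread
over all SNPs with small posterior probabilities; they inflate PIPs by at
most about $L/p$ and are excluded from credible-set reporting by the
near-uniform rule below.

## Reported quantities

* **PIP**: $\mathrm{PIP}_j = 1-\prod_l(1-\alpha_{lj})$, accumulated via
  `log1p`.
* **Causal SNP set at global FDR $\eta$**: local fdr is $1-\mathrm{PIP}$;
  sorting ascending, the global FDR of the top-$i$ set is the running mean
  $\mathrm{FDR}(i) = \sum_{k\le i}\mathrm{fdr}_{(k)}/i$; the longest prefix
  with $\mathrm{FDR}(i)\le\eta$ is selected (step-up), with ties in local
  fdr broken by SNP index for determinism.
* **Level-$\delta$ credible sets**: per component, the smallest set of
  SNPs (by decreasing $\alpha$) with mass $\ge\delta$. A component is
  reported only if $\max_j \alpha_{lj} > 2/p$ and its set is smaller than
  the whole panel — near-uniform components carry no localizable signal.
  When an LD matrix is available, sets whose minimum absolute pairwise
  correlation (purity) is below 0.5 are additionally discarded; purity
  filtering is the field's convention rather than part of the model, so it
  is on by default only when $R$ is supplied and is exposed as a parameter.
* **Annotation importance**: $FI_k = \max_l \mu^2_{w_lk}$, ranking
  annotations by their strongest per-component evidence; the top 5–10% are
  candidates for relevance. This is a ranking device, not a calibrated test.

## The synthetic benchmark

Real biobank genotypes are not redistributable, so the generator emulates
the benchmark design with a synthetic stand-in whose only essential feature
is controllable LD — the engine sees data solely through standardized
sufficient statistics:

* **Genotypes**: two latent Gaussian haplotypes per individual with AR(1)
  (or block-equicorrelated) correlation along the SNP index, thresholded at
  per-SNP allele-frequency quantiles (MAF $\sim U(0.05, 0.5)$) and summed to
  dosages in $\{0,1,2\}$, then standardized. Thresholding attenuates the
  latent correlation; the realized adjacent-SNP correlation is checked
  against a numeric-integration oracle in the tests. Defaults: AR(1) with
  $\rho = 0.5$.
* **Annotations and weights**: $A_{jk}\sim N(0,1)$ iid;
  $w_k \sim N(0, 0.01)$ for a `sparsity` fraction of annotations (default
  all of them), the rest exactly zero — sparsity values of 0.5, 0.1, 0.05,
  0.01 reproduce the sparse robustness settings.
* **Causal SNPs**: softmax probabilities $\pi = \mathrm{softmax}(Aw)$; the
  $L_0$ causal SNPs (default 2) are chosen greedily by descending $\pi$
  subject to pairwise genotype correlation below 0.1. Greedy scanning is the
  simplest deterministic reading of "highest $\pi$ with pairwise correlation
  below 0.1". Note this selection induces a stronger annotation–causality
  coupling than the raw $N(0, 0.01)$ weights alone would; the generator
  reproduces the selection rather than resampling causality from $\pi$.
* **Phenotype**: $b_0 \sim N(0, h^2/L_0)$ with regional heritability
  $h^2 = 0.0075$; noise variance $\frac{1-h^2}{h^2}\mathrm{Var}(X_0 b_0)$
  estimated from the realized genetic values, so the realized heritability
  fluctuates around $h^2$ across draws (its mean is checked against 0.0075).
  The phenotype is standardized and marginal z-scores computed.

`runBenchmark()` spreads replicates across a pool of simulated genotype
regions (default 10) and redraws annotations, weights, causal SNPs, and
phenotypes per replicate, mirroring the repeat-across-regions structure of
fine-mapping benchmarks; all randomness flows from one master seed through
named substreams, so runs are bit-reproducible. Each replicate is fitted
once; the annotation-free comparison arm is the stage-1 state of the same
fit, which is exactly the SuSiE special case. The empirical FDR of a
selection is $1 - \mathrm{TP}/D$; with zero discoveries it is defined as 0
and the replicate still counts toward aggregate denominators.

Desk-scale defaults are $n = 10{,}000$ and $p$ of a few hundred (the
reference studies use tens of thousands of individuals and up to a few
thousand SNPs per region); the acceptance checks run 50–100 replicates at
$n = 10{,}000$, $p = 200$–$500$, $m = 100$. Two effect-size choices are
deliberately amplified and recorded rather than silent: power-gain checks
use annotation-weight variance 0.02 (chosen so the largest causal
probability averages at least $20/p$ — the baseline 0.01 concentrates the
prior too weakly for annotations to matter), and the sparse
annotation-recovery check uses a single weight with variance 4, i.e. logits
of order one from one annotation, the "strong single weight" regime.

### What the synthetic benchmark does and does not show

The generator reproduces the *statistical* structure the model assumes:
standardized dosages with local LD, Gaussian annotations, softmax causal
probabilities, a fixed small regional heritability. It does not reproduce
real LD block structure, allele-frequency/LD-dependent annotation
correlations, binary annotation sparsity patterns, population stratification
or assortative mating, or mismatched reference-panel LD. Passing the
calibration and power checks therefore demonstrates internal correctness of
the machinery under the model's own assumptions, not robustness to the full
messiness of biobank data.

## Numerical choices and limitations

* All heavy per-iteration linear algebra (the annotation-weight block) runs
  in compiled kernels that call BLAS/LAPACK directly; an R reference path
  for the same closed forms is kept for validation, and the two agree to
  machine precision in tests. The per-component covariance is $m\times m$
  and dense; $m$ up to a few hundred is the intended regime ($O(m^3)$ per
  component per iteration).
* Initial values: $\sigma^2 = y^\top y/n$ (1 for standardized phenotypes),
  $\sigma^2_{b_l} = 0.2$ (a conventional fraction of phenotypic variance
  per effect), $\sigma^2_{w_l} = 0.01$ — the natural prior scale for
  standardized annotations, matching the magnitude the benchmark design
  itself uses. Stage 2 initializes $\mu_w = 0$, $\rho = 0$, and $\xi$ at its
  tightness value under those settings.
* Annotation preprocessing: constant columns are dropped with a warning;
  continuous columns are standardized; binary columns are centered but not
  rescaled (their scale is meaningful); and no intercept is ever added,
  because the softmax is invariant to a shared shift of all logits, which
  would make an intercept unidentifiable and contaminate importance scores.
  Whether annotations should be standardized in a given application is a
  modelling choice; standardization makes importance scores comparable
  across annotations and is the default here.
* SNP alignment across input files is by strict id-sequence equality;
  silent joins or reordering are refused. Inputs are assumed pre-harmonized
  (no allele flipping, no liftover).
* Degenerate inputs: monomorphic SNPs are rejected (or resampled, inside
  the generator); a perfect single-SNP fit (infinite z) is an error; an LD
  matrix with eigenvalues below $-10^{-6}$ is rejected.
* The `FunmapFit` object stores the stage-1 component posteriors alongside
  the final ones, so annotated and annotation-free summaries always come
  from one fit and remain directly comparable.
* Known limitations: one region at a time (no cross-region joint fitting or
  functional-enrichment meta-analysis); annotation importance is a ranking,
  not an FDR-controlled selection of annotations; and with reference-panel
  LD the summary-mode identities are approximate, inheriting the usual
  sensitivity of summary-based fine-mapping to LD mismatch.

## Problem sizes used in the checks

The packaged tests exercise unit oracles at $n \le 4{,}000$, $p \le 200$
and the end-to-end statistical properties at $n = 10{,}000$, $p = 200$–$500$,
$m = 100$ with 20–100 replicates; `scripts/acceptance.R` re-runs the
headline quantities at the same scale with 25–50 replicates per design.
These sizes were chosen so that a complete from-scratch reproduction runs
comfortably on a single workstation core while keeping Monte-Carlo standard
errors small relative to the thresholds being checked.
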