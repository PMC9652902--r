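---
title: "Iterative Bayesian model search for GWAS: model, algorithm and design choices"
author: "bicoss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative Bayesian model search for GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicoss)
```

## The problem

Single marker analysis (SMA) tests every SNP separately against the
phenotype. Under linkage disequilibrium (LD) a causal SNP drags its
correlated neighbours past the significance threshold, inflating the false
discovery rate; and when a few SNPs have large effects, their unmodelled
genetic variance inflates the residual variance of every single-SNP fit,
masking small and medium effects. This package implements an iterative
multi-SNP alternative under the kinship linear mixed model, together with
SMA baselines, a synthetic-data generator, and evaluation tooling.

## Model

All fits assume the kinship linear mixed model

$$Y = X\beta + Zu + \epsilon, \qquad u \sim N(0,\ \sigma^2 \tau K),
\qquad \epsilon \sim N(0,\ \sigma^2 I),$$

with $Y$ the $n$ phenotypes, $X$ the intercept, covariates and any SNPs of
the current model, $Z$ an $n \times t$ incidence matrix mapping
observations to inbred strains (the identity when every strain is observed
once), $K$ the known realized-relationship (kinship) matrix, $\tau \ge 0$
the kinship dependence parameter and $\sigma^2$ the error variance.

Fitting uses the spectral device: with
$ZKZ^\top = U \Lambda U^\top$, the rotated data $U^\top Y$ have diagonal
covariance $\sigma^2(I + \tau\Lambda)$, so for any fixed $\tau$ the fit is
weighted least squares and the $\tau$ profile likelihood is cheap. The
profile is maximized on a 100-point log-spaced grid over
$[10^{-6}, 10^6]$, refined by Brent search in the best bracket. Ties within
numerical tolerance break toward smaller $\tau$; this matters because the
profile is exactly flat when $K = I$ (the model is then
over-parameterized), and parsimony sends $\hat\tau$ to the bottom of the
grid. Estimation is maximum likelihood, not REML, because model comparison
is based on
$\mathrm{BIC} = -2\,\ell(\hat\theta) + d \log n$ evaluated at the ML
estimate; REML is available behind a flag for variance-component
diagnostics but plays no role in model scoring. The parameter count $d$
includes the fixed effects plus $\sigma^2$ and $\tau$; since only BIC
*differences* enter downstream, constant conventions cancel.

## Bayesian scoring of models

Models are compared through the unit-information approximation to the
Bayes factor,
$BF_{ib} \approx \exp\{-0.5(\mathrm{BIC}_i - \mathrm{BIC}_b)\}$, so no
explicit parameter priors are needed. The prior over the model space treats
inclusion of each of $s$ eligible SNPs as an independent Bernoulli trial
with success probability $1 - \pi_0$:
$P(M_i) = \pi_0^{\,s - p_i} (1 - \pi_0)^{p_i}$ for a model with $p_i$
SNPs. Posterior model probabilities are
$P(M_i \mid Y) \propto P(M_i)\,BF_{ib}$, normalized with the log-sum-exp
trick; all Bayes-factor arithmetic is done in log space with
$|\log BF|$ clamped at 700 to keep `exp()` finite.

$\pi_0$, the proportion of null SNPs, is estimated from the single-marker
Wald p-values by the Storey estimator:
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (L(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed by a cubic smoothing spline
(df = 3) and read off at $\lambda = 0.95$. When the estimate is
conservative ($\ge 1$), the fallback $\pi_0 = 1 - 100/L$ is used — "expect
about 100 non-null SNPs genome-wide". That fallback is negative for
$L \le 100$, so it is floored at $0.5$ on small panels; genome-scale
inputs are unaffected.

## The iterative procedure

Iteration starts from the base model with no SNPs.

1. **Screening.** The base model is fitted by ML, giving $\hat\beta$ and
   $\hat\tau$. The fixed-effect residual $\hat Y = Y - X\hat\beta$ has
   exact covariance
   $\sigma^2 \Sigma(\hat\tau)$ with
   $\Sigma(\hat\tau) = V - X(X^\top V^{-1} X)^{-1}X^\top$ and
   $V = I + \hat\tau Z K Z^\top$: the generalized-least-squares projection
   of $V$ off the fixed-effect space. $\Sigma$ is singular with rank
   $n - \mathrm{rank}(X)$; the screening likelihood is defined on its
   column space. Each SNP is regressed (no intercept — the residual is
   already adjusted for the fixed effects) against $\hat Y$ in the
   whitened eigenbasis of $\Sigma$, eigenvalues below $10^{-10}$ of the
   maximum treated as zero and the retained rank used as the BIC sample
   size, which keeps the density proper. The two-model Bayes factor and
   the Bernoulli prior give each SNP's posterior probability $p_l$ of
   being causal conditional on the base model.
2. **Bayesian FDR control.** SNPs are ranked by decreasing $p_l$ (ties by
   ascending index, for determinism) and the posterior expected FDR of
   flagging the top $d$ is $\widehat{FDR}_d = \sum_{l\le d}(1 -
   p_{(l)})/d$. All SNPs in the largest prefix with
   $\widehat{FDR}_d < q_0$ (strict, as the decision rule is printed) are
   candidates; $q_0 = 0.05$ by default.
3. **Model selection.** The search space is every subset of base $\cup$
   candidate SNPs (base SNPs can be dropped). $\tau$ is estimated once
   from the full model and then fixed for every fit in the step (P3D),
   turning each model score into one small Cholesky solve of the
   precomputed weighted Gram matrix. Spaces of up to 15 SNPs are
   enumerated completely; for 16 or more, a genetic algorithm searches
   the space. The highest-posterior model becomes the next base model.
4. **Convergence.** The loop stops when the best model equals its base
   model. $\pi_0$ is re-estimated at every screening, but every selection
   step reuses the first screening's $\pi_0$ so early discoveries stay
   competitive against SNPs surfacing later.

The conditioning is the point: once a large effect is in the base model,
its variance leaves the residual, and smaller effects become detectable in
the next screening — the mechanism the small-effect-rescue acceptance
check exercises.

Two safeguards are extensions beyond the core procedure, which assumes
convergence: a cap of 50 outer iterations, and cycle detection on the
sequence of base models. On a cycle, the visited base models are re-scored
(BIC with $\tau$ re-profiled, prior-adjusted) and the best is returned
with `stopReason = "cycle"`. Cycles have not been observed in the
package's own simulations; the behavior is defined so the procedure is
total.

### Genetic algorithm

Binary inclusion chromosomes over the union SNPs. The initial population
(100 models) holds the intercept-only model, one-SNP models for up to 99
SNPs ranked by screening posterior (base-model SNPs first), and random
fill. Each generation applies selection with probabilities proportional to
$\exp(-0.5\,\mathrm{score}_i)$, single-point crossover (probability 0.8
per pair), single-bit mutation (probability 0.1 per model) and elitism
(the best model always survives — added for convergence stability). It
stops after 400 generations or 40 consecutive generations with an
unchanged best model; the slower pair (4000, 400) is available through
`GAConfig`. The mutation and crossover rates are conventional GA defaults
and are configurable.

Two fitness definitions are exposed because the literature is ambiguous
about whether the selection pressure should include the model prior:
`priorAdjusted = TRUE` (default) uses
$\mathrm{BIC}_i - 2\log P(M_i)$ so the GA optimizes exactly the posterior
that complete enumeration maximizes — internal coherence between the two
search modes — while `FALSE` uses the raw $\exp(-0.5\,\mathrm{BIC}_i)$
fitness. Every evaluated model is cached by a canonical key, so no BIC is
computed twice; with a fixed seed the whole search is bit-reproducible.

Whether "16 or more" counts candidates only or the searched union is a
judgment call; the union is used, since it is the dimension of the space
actually searched.

## Single-marker baselines

* `smaExact()` re-maximizes the $\tau$ profile per SNP (a shared 50-point
  log-grid profile evaluated for all SNPs simultaneously, then per-SNP
  Brent refinement) — the EMMA-style exact mixed-model scan.
* `smaApprox()` fixes $\tau$ at the no-SNP null-model estimate and runs
  per-SNP GLS — the EMMAX-style approximation, orders of magnitude faster
  and near-identical in ranking (rank correlation $\ge$ 0.99 in the test
  suite).
* `smaOLS()` is the classic simple-regression t-test, for data without
  population structure.

All three report Wald p-values (the test statistic for the mixed-model
scans is not dictated by the method definition; Wald is standard and
cheap) and a Bonferroni decision at family level $0.05/L$.

## Synthetic data generator

`simulateGWAS()` emulates the conditions the method was evaluated under:
$n = 328$ inbred accessions observed once ($Z = I$), $L = 60000$ SNPs in
10 LD blocks of 6000 with MAF $\ge 0.01$, kinship built from the simulated
genotypes by the VanRaden estimator ($K = WW^\top / 2\sum_j \bar p_j(1-\bar
p_j)$, $W$ the column-centered dosages — the `A.mat` construction), and
phenotypes
$Y = \alpha \mathbf{1} + X\beta + Zu + \epsilon$ with $\alpha = 1$,
$\tau = 0.1$, $\sigma^2 = 0.2$; ten causal SNPs sit at the block centers
with seven effects fixed at 0.4 and three varying together
(`betaPattern()`). "null" (no causal SNPs) and "linear" (no random effect)
variants drop the corresponding term.

Genotypes come from a latent Gaussian AR(1) process per block, thresholded
at the Hardy–Weinberg quantiles of a MAF drawn uniformly from
$[0.01, 0.5]$. The within-block correlation defaults to $\rho = 0.9$,
giving a median adjacent-dosage correlation above 0.5 after tetrachoric
attenuation — strong local LD of the kind found in selfing species, where
real SMA overcounts discoveries. This stand-in reproduces block-diagonal
LD and a realistic relatedness spectrum but not coalescent LD decay,
allele-frequency spectra, or population stratification beyond the kinship
random effect; passing tests on it show algorithmic correctness and the
qualitative method ordering, not field performance on any particular
organism. Columns that land below the MAF floor are redrawn independently
(they lose their LD; rare at these settings). Real genotype panels are
deliberately not bundled: analyses of real data go through `readInputs()`.

## Numerical choices

* Eigenvalues of $ZKZ^\top$ are clipped at zero; $\Sigma(\hat\tau)$ is
  pseudo-inverted over eigenvalues above $10^{-10}$ of the largest.
* A zero-variance SNP after projection gets screening posterior 0 and
  p-value 1, with a warning.
* Perfectly correlated SNPs ($|r| > 1 - 10^{-10}$) in a search space are
  collapsed to the lowest-index representative; dropped columns are
  reported as aliases of the kept one, mirroring how perfectly duplicated
  markers should be read in output tables.
* Enumeration ties (posterior within $10^{-9}$) break toward fewer SNPs,
  then lexicographic order.
* Metric conventions: FDR and F1 report 0 on 0/0 (needed for null-model
  runs); truth matching is strictly positional, with an optional
  off-by-default window mode for LD-aware scoring.
* Missing dosages are mean-imputed per column on input, with a logged
  count (a pragmatic convention; the method itself assumes complete
  dosages).

## Problem sizes used in the checks

The test suite and the acceptance script run scaled studies chosen to be
informative yet quick on a laptop: oracle equivalences at $n \le 80$;
GA-versus-enumeration on 20 spaces of 10–15 SNPs; replicated studies at
$n = 300$, $L = 2000$ (20 replicates) and $n = 500$, $L \le 600$ (50
replicates). At these scales the method ordering is stable across seeds;
the absolute rates differ from genome-scale runs ($L$ in the tens of
thousands, 100 replicates), which are hours of compute and need real
genotype panels.

One comparison deserves a caveat: with *independent* SNPs, Bonferroni SMA
controls the family-wise error, so its realized FDR is near zero by
construction and no method can undercut it meaningfully. The SMA FDR
inflation that motivates multi-SNP modelling is an LD phenomenon — causal
SNPs drag their neighbours past the threshold. The LD-block study
($\rho = 0.9$) is therefore the comparison that carries the qualitative
ordering (iterative search: higher recall *and* lower FDR); the
independent-SNP study still shows the recall advantage and FDR below the
nominal level, and the corresponding acceptance check documents this
expectation explicitly.

## Known limitations

* ML-based BIC model scoring is asymptotic ($O(n^{-1/2})$ error in the
  Bayes-factor approximation); very small $n$ with many candidates can
  over-penalize.
* The Bayesian FDR guarantee is with respect to the model's own
  posteriors; misspecified kinship shifts realized FDR.
* Single phenotype, Gaussian errors only; no interaction terms, no
  automatic covariate selection, no explicit parameter priors.
* The GA is a stochastic search: with enormous candidate sets it can
  return a local mode; the archive (`models` slot) and the fixed-seed
  reproducibility make such runs auditable.

## A worked example

```{r example, eval = FALSE}
sim <- simulateGWAS(SimSettings(n = 300, L = 2000, nBlocks = 10,
                                rho = 0.9, seed = 42))
run <- runBicoss(sim$data, seed = 1)
run
scoreDiscoveries(finalModel(run)@snps, sim$truth)
smaRes <- smaExact(sim$data)
scoreDiscoveries(smaRes@significant, sim$truth)
```
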