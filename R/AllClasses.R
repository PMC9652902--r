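#' @import methods
NULL

#' GWASData: container for one association analysis
#'
#' Holds the phenotype, genotype dosages, fixed-effect covariates, the
#' strain-incidence matrix and the kinship (realized-relationship) matrix
#' for a single GWAS under the kinship linear mixed model
#' \deqn{Y = X\beta + Zu + \epsilon,\quad u \sim N(0, \sigma^2 \tau K),\quad
#'       \epsilon \sim N(0, \sigma^2 I).}
#'
#' @slot Y numeric phenotype vector, length n.
#' @slot G n x L genotype matrix, minor-allele dosages in \{0, 1, 2\}.
#' @slot X n x c fixed-effect design; first column is the all-ones intercept.
#' @slot Z n x t incidence matrix mapping observations to strains; each row
#'   has exactly one 1. Defaults to the identity (one observation per strain).
#' @slot K t x t kinship matrix, symmetric positive semi-definite.
#' @slot snpInfo data.frame with columns \code{snp}, \code{chrom}, \code{pos}
#'   describing the L genotype columns.
#'
#' @seealso [GWASData()] for the validated constructor, [runBicoss()],
#'   [smaExact()].
#' @exportClass GWASData
setClass("GWASData",
  representation(
    Y = "numeric",
    G = "matrix",
    X = "matrix",
    Z = "matrix",
    K = "matrix",
    snpInfo = "data.frame"
  )
)

setValidity("GWASData", function(object) {
  n <- length(object@Y)
  msg <- character()
  if (!all(is.finite(object@Y))) msg <- c(msg, "phenotype contains non-finite values")
  if (nrow(object@G) != n) msg <- c(msg, "nrow(G) != length(Y)")
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) != length(Y)")
  if (nrow(object@Z) != n) msg <- c(msg, "nrow(Z) != length(Y)")
  if (ncol(object@Z) != nrow(object@K)) msg <- c(msg, "ncol(Z) != nrow(K)")
  if (nrow(object@K) != ncol(object@K)) msg <- c(msg, "K is not square")
  if (nrow(object@snpInfo) != ncol(object@G)) msg <- c(msg, "snpInfo rows != ncol(G)")
  bad <- rowSums(object@Z == 1) != 1 | rowSums(object@Z != 0 & object@Z != 1) > 0
  if (any(bad)) msg <- c(msg, "Z is not a 0/1 incidence matrix with one 1 per row")
  if (length(msg)) msg else TRUE
})

#' LMMFit: a fitted kinship linear mixed model
#'
#' Maximum-likelihood fit of one SNP model under the kinship LMM, together
#' with its BIC, \eqn{BIC = -2\,\ell(\hat\theta) + d \log n}, where d counts
#' the fixed-effect coefficients plus the two variance parameters
#' (\eqn{\sigma^2}, \eqn{\tau}).
#'
#' @slot modelSnps integer indices of the SNPs included as fixed effects.
#' @slot beta named coefficient vector (covariates first, then SNPs).
#' @slot sigma2 error-variance estimate (> 0).
#' @slot tau kinship dependence estimate (>= 0).
#' @slot loglik maximized log-likelihood.
#' @slot df parameter count d used in the BIC penalty.
#' @slot bic scalar BIC.
#' @slot n sample size.
#' @slot method "ML" or "REML".
#' @slot tauProfiled FALSE when tau was supplied (P3D) rather than estimated.
#' @exportClass LMMFit
setClass("LMMFit",
  representation(
    modelSnps = "integer",
    beta = "numeric",
    sigma2 = "numeric",
    tau = "numeric",
    loglik = "numeric",
    df = "numeric",
    bic = "numeric",
    n = "integer",
    method = "character",
    tauProfiled = "logical"
  )
)

setValidity("LMMFit", function(object) {
  msg <- character()
  if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be > 0")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (abs(object@bic - (-2 * object@loglik + object@df * log(object@n))) > 1e-8 * max(1, abs(object@bic)))
    msg <- c(msg, "bic != -2*loglik + df*log(n)")
  if (length(msg)) msg else TRUE
})

#' ModelPrior: Bernoulli prior over the SNP model space
#'
#' Inclusion of each of s eligible SNPs is an independent Bernoulli trial
#' with success probability \eqn{1 - \pi_0}, so a model with p SNPs has
#' prior probability \eqn{\pi_0^{s-p} (1-\pi_0)^p}.
#'
#' @slot pi0 proportion-of-null prior parameter in (0, 1).
#' @slot s number of SNPs eligible for inclusion.
#' @slot source "estimated" (Storey-type estimate from SMA p-values) or
#'   "fallback" (\eqn{1 - 100/L} when the estimate hits 1).
#' @exportClass ModelPrior
setClass("ModelPrior",
  representation(pi0 = "numeric", s = "integer", source = "character")
)

setValidity("ModelPrior", function(object) {
  msg <- character()
  if (object@pi0 <= 0 || object@pi0 >= 1) msg <- c(msg, "pi0 must be in (0, 1)")
  if (!object@source %in% c("estimated", "fallback")) msg <- c(msg, "unknown source")
  if (length(msg)) msg else TRUE
})

#' SNPModel: one candidate multi-SNP model with its Bayesian score
#'
#' @slot snps integer index set of the SNPs in the model.
#' @slot bic BIC of the model.
#' @slot logBF log Bayes factor versus the base model,
#'   \eqn{\log BF \approx -0.5 (BIC_i - BIC_b)}.
#' @slot logPrior log prior model probability under the Bernoulli prior.
#' @slot posterior posterior model probability within the scored collection.
#' @exportClass SNPModel
setClass("SNPModel",
  representation(
    snps = "integer",
    bic = "numeric",
    logBF = "numeric",
    logPrior = "numeric",
    posterior = "numeric"
  )
)

#' ScreeningResult: per-SNP posteriors and the Bayesian-FDR candidate set
#'
#' @slot pPost length-L posterior probabilities that each SNP is causal
#'   conditional on the base model (NA for SNPs already in the base model).
#' @slot pvals length-L frequentist (Wald) p-values from the whitened
#'   single-SNP regressions; these feed the pi0 estimate.
#' @slot prior the [ModelPrior-class] used to convert Bayes factors to
#'   posterior probabilities.
#' @slot candidates indices flagged by posterior-expected FDR control.
#' @slot fdrCurve cumulative posterior-expected FDR over the ranked SNPs.
#' @slot q0 nominal Bayesian FDR level.
#' @slot baseSnps SNPs in the base model (excluded from candidacy).
#' @exportClass ScreeningResult
setClass("ScreeningResult",
  representation(
    pPost = "numeric",
    pvals = "numeric",
    prior = "ModelPrior",
    candidates = "integer",
    fdrCurve = "numeric",
    q0 = "numeric",
    baseSnps = "integer"
  )
)

#' GAConfig: genetic-algorithm settings for the model-selection step
#'
#' @slot popSize population size (default 100).
#' @slot maxIter maximum generations (default 400).
#' @slot runStop stop after this many consecutive generations with the same
#'   best model (default 40). The slower alternative pair (4000, 400) can be
#'   requested explicitly.
#' @slot pMutation per-model probability of flipping one SNP's status.
#' @slot pCrossover per-pair probability of single-point crossover.
#' @slot priorAdjusted when TRUE (default) selection fitness uses the
#'   prior-adjusted score \eqn{BIC_i - 2 \log P(M_i)} so the GA optimizes the
#'   posterior; when FALSE it uses \eqn{\exp(-0.5\,BIC_i)} alone.
#' @export GAConfig
#' @exportClass GAConfig
GAConfig <- setClass("GAConfig",
  representation(
    popSize = "integer",
    maxIter = "integer",
    runStop = "integer",
    pMutation = "numeric",
    pCrossover = "numeric",
    priorAdjusted = "logical"
  ),
  prototype(
    popSize = 100L, maxIter = 400L, runStop = 40L,
    pMutation = 0.1, pCrossover = 0.8, priorAdjusted = TRUE
  )
)

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@popSize < 2) msg <- c(msg, "popSize must be >= 2")
  if (object@runStop > object@maxIter) msg <- c(msg, "runStop must be <= maxIter")
  if (object@pMutation < 0 || object@pMutation > 1) msg <- c(msg, "pMutation not in [0,1]")
  if (object@pCrossover < 0 || object@pCrossover > 1) msg <- c(msg, "pCrossover not in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SearchResult: outcome of one model-selection step
#'
#' @slot best the highest-posterior [SNPModel-class].
#' @slot models data.frame archive of all distinct evaluated models
#'   (key, nsnps, bic, logPrior, posterior).
#' @slot method "enumeration" or "ga".
#' @slot tauP3D the kinship dependence parameter fixed for all fits in this
#'   step (P3D).
#' @slot nEval number of distinct models whose BIC was computed.
#' @slot cacheHits number of times an already-scored model was re-proposed.
#' @slot generations GA generations used (0 for enumeration).
#' @slot trace best objective value after each GA generation (empty for
#'   enumeration); non-increasing under elitism.
#' @exportClass SearchResult
setClass("SearchResult",
  representation(
    best = "SNPModel",
    models = "data.frame",
    method = "character",
    tauP3D = "numeric",
    nEval = "integer",
    cacheHits = "integer",
    generations = "integer",
    trace = "numeric"
  )
)

#' BicossRun: full record of the iterative screening/selection procedure
#'
#' @slot iterations list with one entry per outer iteration: base model,
#'   candidate set, best model, tau estimates and pi0 used.
#' @slot finalModel the converged [SNPModel-class].
#' @slot finalFit [LMMFit-class] of the final model with tau re-profiled.
#' @slot converged TRUE when the loop reached a fixed point.
#' @slot stopReason "fixed_point", "cycle" or "max_iter".
#' @slot provenance data.frame mapping each final SNP to the iteration where
#'   it first entered a candidate set.
#' @slot aliases data.frame of dropped perfectly-correlated SNPs (columns
#'   \code{kept}, \code{dropped}).
#' @slot pi0First the model-space prior frozen at the first screening.
#' @exportClass BicossRun
setClass("BicossRun",
  representation(
    iterations = "list",
    finalModel = "SNPModel",
    finalFit = "LMMFit",
    converged = "logical",
    stopReason = "character",
    provenance = "data.frame",
    aliases = "data.frame",
    pi0First = "numeric"
  )
)

#' SMAResult: single-marker-analysis output
#'
#' @slot pvals length-L p-values.
#' @slot betas per-SNP effect estimates.
#' @slot ses per-SNP standard errors.
#' @slot significant indices significant under Bonferroni at family level
#'   0.05 (p < 0.05 / L).
#' @slot method "exact", "approx" or "ols".
#' @slot tau tau estimate(s) used: per-SNP vector for "exact", the single
#'   null-model estimate for "approx", NA for "ols".
#' @exportClass SMAResult
setClass("SMAResult",
  representation(
    pvals = "numeric",
    betas = "numeric",
    ses = "numeric",
    significant = "integer",
    method = "character",
    tau = "numeric"
  )
)

#' SimSettings: study conditions for the synthetic GWAS generator
#'
#' Defaults mirror the simulation conditions the method was designed for:
#' n = 328 inbred accessions with Z = I, L = 60000 SNPs in 10 LD blocks of
#' 6000, MAF >= 0.01, intercept alpha = 1, kinship dependence tau = 0.1 and
#' error variance sigma2 = 0.2, with 10 causal SNPs at the block centers and
#' seven of the ten effects fixed at 0.4 (see [betaPattern()]).
#'
#' @slot n individuals. @slot L SNPs. @slot nBlocks LD blocks.
#' @slot blockSize SNPs per block (nBlocks * blockSize = L).
#' @slot rho latent AR(1) correlation between adjacent SNPs within a block.
#' @slot mafMin minimum minor-allele frequency (0.01).
#' @slot causal causal SNP indices. @slot beta causal effect sizes.
#' @slot alpha intercept. @slot tau kinship dependence. @slot sigma2 error
#'   variance.
#' @slot model "mixed" (kinship LMM), "null" (no causal SNPs) or "linear"
#'   (no kinship random effect).
#' @slot seed integer RNG seed.
#' @exportClass SimSettings
setClass("SimSettings",
  representation(
    n = "integer", L = "integer", nBlocks = "integer", blockSize = "integer",
    rho = "numeric", mafMin = "numeric",
    causal = "integer", beta = "numeric",
    alpha = "numeric", tau = "numeric", sigma2 = "numeric",
    model = "character", seed = "integer"
  )
)

setValidity("SimSettings", function(object) {
  msg <- character()
  if (object@nBlocks * object@blockSize != object@L)
    msg <- c(msg, "nBlocks * blockSize must equal L")
  if (object@rho >= 1 || object@rho < 0) msg <- c(msg, "rho must be in [0, 1)")
  if (length(object@beta) != length(object@causal))
    msg <- c(msg, "length(beta) != length(causal)")
  if (length(object@causal) && (min(object@causal) < 1 || max(object@causal) > object@L))
    msg <- c(msg, "causal positions outside 1..L")
  if (!object@model %in% c("mixed", "null", "linear")) msg <- c(msg, "unknown model")
  if (object@mafMin <= 0 || object@mafMin >= 0.5) msg <- c(msg, "mafMin outside (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth attached to a simulated dataset
#'
#' @slot causalIndicator length-L 0/1 vector marking the true causal SNPs.
#' @slot betaTrue length-L effect vector (0 for non-causal SNPs).
#' @slot u the simulated random-effect vector (length 0 for "linear").
#' @slot kinship the kinship matrix used when drawing u.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(
    causalIndicator = "integer",
    betaTrue = "numeric",
    u = "numeric",
    kinship = "matrix"
  )
)
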