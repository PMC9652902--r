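#' @include AllClasses.R
NULL

## log Bayes factors are clamped here to keep exp() finite
.LOGBF_CLAMP <- 700

#' BIC approximation to the Bayes factor
#'
#' Approximates the Bayes factor of model i versus the base model b by
#' \eqn{BF_{ib} \approx \exp\{-0.5 (BIC_i - BIC_b)\}} (the unit-information
#' prior approximation). Computed in log space with the log Bayes factor
#' clamped at +/- 700 to avoid overflow.
#'
#' @param bicI,bicB BIC values of the model and the base model.
#' @param log return the log Bayes factor instead.
#' @return the (log) Bayes factor; vectorized over \code{bicI}.
#' @examples
#' bayesFactorApprox(98, 100)   # exp(1)
#' bayesFactorApprox(102, 100)  # exp(-1)
#' @export
bayesFactorApprox <- function(bicI, bicB, log = FALSE) {
  if (anyNA(bicI) || anyNA(bicB)) stop("NaN/NA BIC input")
  lbf <- pmin(pmax(-0.5 * (bicI - bicB), -.LOGBF_CLAMP), .LOGBF_CLAMP)
  if (log) lbf else exp(lbf)
}

#' Log prior probability of a model under the Bernoulli model-space prior
#'
#' With s eligible SNPs each included independently with probability
#' \eqn{1 - \pi_0}, a model containing p SNPs has log prior
#' \eqn{(s - p)\log\pi_0 + p\log(1 - \pi_0)}.
#'
#' @param prior a [ModelPrior-class].
#' @param pI number of SNPs in the model (vectorized).
#' @param s number of eligible SNPs; defaults to \code{prior@s}.
#' @return log prior probability.
#' @export
priorModelProb <- function(prior, pI, s = prior@s) {
  if (any(pI < 0) || any(pI > s)) stop("model size outside 0..s")
  (s - pI) * log(prior@pi0) + pI * log1p(-prior@pi0)
}

#' Estimate the proportion of null SNPs (pi0)
#'
#' Storey-type estimate from single-marker p-values:
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (L(1-\lambda))} is computed
#' on the grid \eqn{\lambda = 0.05, 0.10, \dots, 0.95}, smoothed by a cubic
#' smoothing spline (df = 3) and evaluated at \eqn{\lambda = 0.95}. When the
#' estimate is conservative (>= 1), the fallback \eqn{\pi_0 = 1 - 100/L} is
#' used, L being the total number of SNPs.
#'
#' @param pvalues vector of p-values in [0, 1]; NAs are dropped.
#' @param L total number of SNPs (defaults to \code{length(pvalues)}); used
#'   by the fallback.
#' @return a [ModelPrior-class] with \code{s = L}.
#' @export
estimatePi0 <- function(pvalues, L = length(pvalues)) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values outside [0, 1]")
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lam, function(l) mean(pvalues > l) / (1 - l), numeric(1))
  est <- tryCatch(
    stats::predict(stats::smooth.spline(lam, pi0l, df = 3), x = 0.95)$y,
    error = function(e) NA_real_)
  if (!is.finite(est) || est >= 1) {
    ## 1 - 100/L presumes genome-scale L; floor at 0.5 for small panels
    new("ModelPrior", pi0 = max(1 - 100 / L, 0.5), s = as.integer(L),
        source = "fallback")
  } else {
    new("ModelPrior", pi0 = max(est, 1e-8), s = as.integer(L),
        source = "estimated")
  }
}

#' Posterior probability of a single SNP given the base model
#'
#' Two-model special case of the posterior model probability: comparing the
#' base model against the base model plus one SNP, with prior inclusion odds
#' \eqn{(1-\pi_0)/\pi_0},
#' \deqn{p_l = \frac{(1-\pi_0)\,BF}{\pi_0 + (1-\pi_0)\,BF}.}
#'
#' @param bf Bayes factor(s) of the one-SNP model versus the base model, or
#'   log Bayes factor(s) when \code{log = TRUE} (preferred for stability).
#' @param prior a [ModelPrior-class].
#' @param log interpret \code{bf} as log Bayes factors.
#' @return posterior probability in [0, 1]; vectorized.
#' @export
snpPosterior <- function(bf, prior, log = FALSE) {
  if (any(!log & bf < 0)) stop("Bayes factors must be >= 0")
  lbf <- if (log) bf else ifelse(bf == 0, -Inf, base::log(bf))
  stats::plogis(lbf - (base::log(prior@pi0) - log1p(-prior@pi0)))
}

## normalize log-weights with the log-sum-exp trick
.normalizeLog <- function(logw) {
  m <- max(logw)
  w <- exp(logw - m)
  w / sum(w)
}

#' Normalized posterior probabilities over a set of scored models
#'
#' Posterior probabilities proportional to
#' \eqn{P(M_i)\,BF_{ib} = \exp\{\log P(M_i) - 0.5(BIC_i - BIC_b)\}},
#' normalized with the log-sum-exp trick so they sum to one.
#'
#' @param models list of [SNPModel-class] objects scored against the same
#'   base BIC (their \code{logBF} and \code{logPrior} slots are used).
#' @return the same list with the \code{posterior} slots filled in.
#' @export
posteriorOverModels <- function(models) {
  if (!length(models)) stop("empty model list")
  logw <- vapply(models, function(m) m@logPrior + m@logBF, numeric(1))
  post <- .normalizeLog(logw)
  for (i in seq_along(models)) models[[i]]@posterior <- post[i]
  models
}
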