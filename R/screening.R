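#' @include AllClasses.R
NULL

#' Single-SNP screening against the base-model residuals
#'
#' For every SNP l not in the base model, fits the no-intercept regression
#' \eqn{\hat Y = X_l \beta_l + \epsilon^*},
#' \eqn{\epsilon^* \sim N(0, \sigma^2\Sigma(\hat\tau))}, by projecting
#' \eqn{\hat Y} and \eqn{X_l} onto the retained eigenbasis of
#' \eqn{\Sigma(\hat\tau)} (see [residualize()]) and rescaling each coordinate
#' by the inverse square-root eigenvalue, which whitens the errors. The BIC
#' of the one-SNP versus the zero-SNP model is computed with sample size
#' equal to the retained rank; the BIC-approximated Bayes factor and the
#' Bernoulli prior give the posterior probability p_l of SNP l being causal
#' conditional on the base model. Wald p-values of \eqn{\hat\beta_l} in the
#' same whitened regression are recorded and feed the pi0 estimate.
#'
#' @param data a [GWASData-class] object.
#' @param resid result of [residualize()] on the base-model fit.
#' @param baseSnps SNPs of the base model; their entries are NA and they are
#'   never candidates.
#' @param prior a [ModelPrior-class]; when NULL, pi0 is estimated from this
#'   screening's own Wald p-values with [estimatePi0()].
#' @param q0 nominal Bayesian FDR level for the candidate selection
#'   (default 0.05).
#' @return a [ScreeningResult-class] object.
#' @seealso [bayesianFdrSelect()] for the selection rule.
#' @export
screenSNPs <- function(data, resid, baseSnps = integer(0), prior = NULL,
                       q0 = 0.05) {
  stopifnot(is(data, "GWASData"))
  baseSnps <- sort(unique(as.integer(baseSnps)))
  L <- ncol(data@G)
  r <- resid$rank
  W <- resid$vectors * rep(1 / sqrt(resid$values), each = nrow(resid$vectors))
  yt <- drop(crossprod(W, resid$yhat))
  Gt <- crossprod(W, data@G)                      # r x L whitened genotypes
  yy <- sum(yt^2)
  xx <- colSums(Gt^2)
  xy <- drop(crossprod(Gt, yt))

  degenerate <- xx < 1e-12 * max(xx, 1)
  xxs <- ifelse(degenerate, 1, xx)
  beta <- xy / xxs
  rss1 <- pmax(yy - xy^2 / xxs, .Machine$double.xmin)

  ## BIC difference (one-SNP minus zero-SNP) in the whitened space; the
  ## log|Sigma| term is shared and cancels
  dBic <- r * log(rss1 / yy) + log(r)
  lbf <- bayesFactorApprox(dBic, 0, log = TRUE)

  ## Wald p-values
  s2u <- rss1 / (r - 1)
  tstat <- beta / sqrt(s2u / xxs)
  pvals <- 2 * stats::pt(-abs(tstat), df = r - 1)

  pvals[degenerate] <- 1
  if (length(baseSnps)) pvals[baseSnps] <- NA_real_
  if (is.null(prior)) prior <- estimatePi0(pvals, L = L)

  pPost <- snpPosterior(lbf, prior, log = TRUE)
  if (any(degenerate & !seq_len(L) %in% baseSnps)) {
    warning(sum(degenerate), " SNP(s) with zero variance after projection; p_l set to 0")
    pPost[degenerate] <- 0
  }
  if (length(baseSnps)) pPost[baseSnps] <- NA_real_

  sel <- bayesianFdrSelect(pPost, q0)
  new("ScreeningResult",
      pPost = pPost, pvals = pvals, prior = prior,
      candidates = sel$candidates, fdrCurve = sel$fdrCurve, q0 = q0,
      baseSnps = baseSnps)
}

#' Bayesian FDR selection of candidate SNPs
#'
#' Ranks SNPs by decreasing posterior probability (ties broken by ascending
#' index) and computes the posterior expected FDR of flagging the top d,
#' \eqn{\widehat{FDR}_d = \sum_{l \le d} (1 - p_{(l)}) / d}. All SNPs in the
#' largest prefix with \eqn{\widehat{FDR}_d < q_0} (strict inequality) are
#' flagged.
#'
#' @param pPost posterior probabilities in [0, 1]; NA entries (e.g. base
#'   model SNPs) are ignored.
#' @param q0 nominal FDR level in (0, 1); default 0.05.
#' @return list with \code{candidates} (integer indices, ranked) and
#'   \code{fdrCurve} (the \eqn{\widehat{FDR}_d} sequence over ranked SNPs).
#' @examples
#' bayesianFdrSelect(c(1, 1, 1, 0.2), 0.05)$candidates  # first three
#' @export
bayesianFdrSelect <- function(pPost, q0 = 0.05) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must be in (0, 1)")
  ok <- which(!is.na(pPost))
  if (!length(ok)) return(list(candidates = integer(0), fdrCurve = numeric(0)))
  ord <- ok[order(-pPost[ok], ok)]
  fdr <- cumsum(1 - pPost[ord]) / seq_along(ord)
  d <- which(fdr < q0)
  d <- if (length(d)) max(d) else 0L
  list(candidates = ord[seq_len(d)], fdrCurve = fdr)
}
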