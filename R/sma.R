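#' @include AllClasses.R
NULL

## Rotate phenotype/covariates/genotypes once; shared by the SMA methods.
.smaRotate <- function(data, spectral = NULL) {
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  U <- spectral$vectors
  list(yr = drop(crossprod(U, data@Y)),
       Xr = crossprod(U, data@X),
       Gr = crossprod(U, data@G),
       lambda = spectral$values)
}

## Per-SNP profile log-likelihoods at one tau for ALL SNPs at once, via
## weighted Frisch-Waugh: sweep the covariates out of y and every genotype
## column, then the single-SNP RSS is a closed form.
.smaProfileAll <- function(rot, tau) {
  sw <- 1 / sqrt(1 + tau * rot$lambda)
  qrw <- qr(rot$Xr * sw)
  ry <- qr.resid(qrw, rot$yr * sw)
  RG <- qr.resid(qrw, rot$Gr * sw)
  xx <- colSums(RG^2)
  xy <- drop(crossprod(RG, ry))
  yy <- sum(ry^2)
  mono <- xx < 1e-12 * max(xx, 1)
  rss <- yy - ifelse(mono, 0, xy^2 / pmax(xx, .Machine$double.xmin))
  n <- length(rot$yr)
  ll <- -0.5 * n * log(2 * pi * rss / n) - 0.5 * sum(log1p(tau * rot$lambda)) - 0.5 * n
  list(ll = ll, xx = xx, xy = xy, yy = yy, mono = mono)
}

## Wald statistics for every SNP at (possibly per-SNP) tau values.
.smaWald <- function(rot, tauVec) {
  n <- length(rot$yr)
  p <- ncol(rot$Xr)
  L <- ncol(rot$Gr)
  betas <- ses <- pvals <- numeric(L)
  for (tau in unique(tauVec)) {
    j <- which(tauVec == tau)
    sw <- 1 / sqrt(1 + tau * rot$lambda)
    qrw <- qr(rot$Xr * sw)
    ry <- qr.resid(qrw, rot$yr * sw)
    RG <- qr.resid(qrw, rot$Gr[, j, drop = FALSE] * sw)
    xx <- colSums(RG^2)
    xy <- drop(crossprod(RG, ry))
    yy <- sum(ry^2)
    mono <- xx < 1e-12 * max(xx, 1)
    xxs <- ifelse(mono, 1, xx)
    b <- xy / xxs
    rss <- pmax(yy - xy^2 / xxs, .Machine$double.xmin)
    df <- n - p - 1
    s2 <- rss / df
    se <- sqrt(s2 / xxs)
    tstat <- b / se
    pv <- 2 * stats::pt(-abs(tstat), df = df)
    b[mono] <- 0; se[mono] <- NA_real_; pv[mono] <- 1
    betas[j] <- b; ses[j] <- se; pvals[j] <- pv
  }
  list(betas = betas, ses = ses, pvals = pvals)
}

.smaResult <- function(w, tau, method, L, alpha = 0.05) {
  sig <- which(w$pvals < alpha / L)
  if (any(is.na(w$pvals))) w$pvals[is.na(w$pvals)] <- 1
  new("SMAResult", pvals = w$pvals, betas = w$betas, ses = w$ses,
      significant = as.integer(sig), method = method, tau = tau)
}

#' Single marker analysis with per-SNP variance components (EMMA-like)
#'
#' For each SNP fits the kinship LMM with design [covariates | SNP],
#' re-maximizing the tau profile likelihood per SNP through the spectral
#' decomposition: a coarse log-grid profile is evaluated for all SNPs
#' simultaneously, then each SNP's optimum is refined by Brent search in its
#' best bracket. Reports the Wald p-value of the SNP coefficient;
#' significance is Bonferroni at family level \code{alpha} (p < alpha / L).
#'
#' @param data a [GWASData-class] object.
#' @param spectral optional precomputed [eigenRotate()] result.
#' @param nGrid grid size for the shared tau profile (default 50; each SNP
#'   is then refined individually).
#' @param alpha family-wise level for the Bonferroni rule (default 0.05).
#' @return an [SMAResult-class] object; \code{tau} holds the per-SNP
#'   estimates.
#' @export
smaExact <- function(data, spectral = NULL, nGrid = 50L, alpha = 0.05) {
  rot <- .smaRotate(data, spectral)
  L <- ncol(rot$Gr)
  grid <- exp(seq(log(1e-6), log(1e6), length.out = nGrid))
  llMat <- vapply(grid, function(tau) .smaProfileAll(rot, tau)$ll, numeric(L))
  bestIdx <- max.col(llMat, ties.method = "first")
  tauVec <- numeric(L)
  for (l in seq_len(L)) {
    i <- bestIdx[l]
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(nGrid, i + 1L)]
    xl <- rot$Gr[, l]
    obj <- function(lt) {
      tau <- exp(lt)
      sw <- 1 / sqrt(1 + tau * rot$lambda)
      qrw <- qr(cbind(rot$Xr, xl) * sw)
      rss <- sum(qr.resid(qrw, rot$yr * sw)^2)
      .mlProfile(length(rot$yr), rss, tau, rot$lambda)
    }
    opt <- stats::optimize(obj, lower = log(lo), upper = log(hi),
                           maximum = TRUE, tol = 1e-6)
    tauVec[l] <- if (opt$objective > llMat[l, i]) exp(opt$maximum) else grid[i]
  }
  w <- .smaWald(rot, round(tauVec, 10))
  .smaResult(w, tauVec, "exact", L, alpha)
}

#' Single marker analysis with null-model variance components (EMMAX-like)
#'
#' Estimates tau once from the model with no SNPs, then performs per-SNP
#' generalized least squares at that fixed tau with Wald p-values and
#' Bonferroni correction. Orders of magnitude faster than [smaExact()] and
#' nearly identical in practice.
#'
#' @inheritParams smaExact
#' @return an [SMAResult-class]; \code{tau} holds the single null-model
#'   estimate.
#' @export
smaApprox <- function(data, spectral = NULL, alpha = 0.05) {
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  tau0 <- fitLMM(data, integer(0), spectral = spectral)@tau
  rot <- .smaRotate(data, spectral)
  w <- .smaWald(rot, rep(tau0, ncol(rot$Gr)))
  .smaResult(w, tau0, "approx", ncol(rot$Gr), alpha)
}

#' Single marker analysis by simple linear regression
#'
#' Classic per-SNP simple linear regression with intercept (plus any
#' covariates) and t-test p-values, ignoring kinship; the baseline for data
#' without population structure.
#'
#' @inheritParams smaExact
#' @return an [SMAResult-class].
#' @export
smaOLS <- function(data, alpha = 0.05) {
  rot <- list(yr = data@Y, Xr = data@X, Gr = data@G,
              lambda = rep(0, length(data@Y)))
  w <- .smaWald(rot, rep(0, ncol(data@G)))
  .smaResult(w, NA_real_, "ols", ncol(data@G), alpha)
}
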