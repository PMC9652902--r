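#' @include AllClasses.R
NULL

#' Construct a validated GWASData object
#'
#' Assembles phenotype, genotype dosages, covariates, incidence and kinship
#' into a [GWASData-class] object, checking dimensional consistency, that Z
#' is a proper incidence matrix and that K is symmetric and positive
#' semi-definite (minimum eigenvalue >= -1e-8 times the maximum).
#'
#' @param Y numeric phenotype vector, length n.
#' @param G n x L genotype matrix with dosages in \{0, 1, 2\}.
#' @param X optional n x c covariate matrix; an all-ones intercept column is
#'   prepended when absent. Default: intercept only.
#' @param Z optional n x t incidence matrix; default identity.
#' @param K optional t x t kinship matrix; computed from G with
#'   [buildKinship()] when absent.
#' @param snpInfo optional data.frame with columns snp, chrom, pos.
#' @param checkPSD check positive semi-definiteness of K via an eigenvalue
#'   sweep (O(t^3); default TRUE).
#' @return a [GWASData-class] object.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
#' d <- GWASData(Y = rnorm(50), G = G)
#' nSamples(d); nSNPs(d)
#' @export
GWASData <- function(Y, G, X = NULL, Z = NULL, K = NULL, snpInfo = NULL,
                     checkPSD = TRUE) {
  Y <- as.numeric(Y)
  n <- length(Y)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (!all(X[, 1] == 1)) X <- cbind(`(Intercept)` = 1, X)
  }
  if (is.null(Z)) Z <- diag(n)
  Z <- as.matrix(Z)
  if (is.null(K)) K <- buildKinship(G)
  K <- as.matrix(K)
  if (anyNA(K)) stop("K contains missing values")
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  K <- (K + t(K)) / 2
  if (checkPSD) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("K is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
  }
  if (is.null(snpInfo)) {
    ids <- colnames(G)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
    snpInfo <- data.frame(snp = ids, chrom = NA_character_,
                          pos = seq_len(ncol(G)), stringsAsFactors = FALSE)
  }
  cv <- apply(G, 2, stats::var)
  if (any(cv == 0))
    warning(sum(cv == 0), " constant genotype column(s); apply a MAF filter before analysis")
  new("GWASData", Y = Y, G = G, X = X, Z = Z, K = K, snpInfo = snpInfo)
}

#' Spectral basis of the kinship-induced covariance
#'
#' Eigen-decomposes \eqn{\tilde K = Z K Z^\top} so that for every tau the
#' phenotype covariance factorizes as
#' \eqn{\mathrm{Var}(Y) = \sigma^2 U \,\mathrm{diag}(1 + \tau\lambda)\, U^\top}.
#' Rotating data by \eqn{U^\top} turns every LMM fit into a weighted least
#' squares problem, so the tau profile likelihood is cheap to evaluate on a
#' grid (the EMMA device).
#'
#' @param Z n x t incidence matrix.
#' @param K t x t symmetric PSD kinship matrix.
#' @return list with \code{values} (eigenvalues, clipped at 0),
#'   \code{vectors} (orthonormal U) and \code{Kt} (= Z K Z').
#' @export
eigenRotate <- function(Z, K) {
  if (anyNA(K) || any(!is.finite(K))) stop("K contains non-finite values")
  if (!isSymmetric(unname(as.matrix(K)), tol = 1e-8)) stop("K must be symmetric")
  Kt <- Z %*% ((K + t(K)) / 2) %*% t(Z)
  Kt <- (Kt + t(Kt)) / 2
  e <- eigen(Kt, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors, Kt = Kt)
}

## default tau profile grid: 100 log-spaced points on [1e-6, 1e6]
.tauGrid <- function(nGrid = 100L) exp(seq(log(1e-6), log(1e6), length.out = nGrid))

## weighted LS pieces at one tau on rotated data; returns rss (+qr on request)
.wls <- function(yr, Xr, lambda, tau, want = c("rss", "fit")) {
  want <- match.arg(want)
  sw <- 1 / sqrt(1 + tau * lambda)
  qrw <- qr(Xr * sw)
  yw <- yr * sw
  res <- qr.resid(qrw, yw)
  if (want == "rss") return(sum(res^2))
  list(rss = sum(res^2), beta = qr.coef(qrw, yw), qr = qrw)
}

.mlProfile <- function(n, rss, tau, lambda) {
  -0.5 * n * log(2 * pi * rss / n) - 0.5 * sum(log1p(tau * lambda)) - 0.5 * n
}

.remlProfile <- function(n, p, rss, tau, lambda, qrw) {
  ldXX <- sum(log(abs(diag(qr.R(qrw)))^2))
  -0.5 * (n - p) * log(2 * pi * rss / (n - p)) - 0.5 * sum(log1p(tau * lambda)) -
    0.5 * ldXX - 0.5 * (n - p)
}

## profile the tau likelihood on a log grid, refine by Brent in the best
## bracket; ties between grid optima break toward smaller tau
.profileTau <- function(yr, Xr, lambda, reml = FALSE, nGrid = 100L) {
  n <- length(yr)
  p <- ncol(Xr)
  grid <- .tauGrid(nGrid)
  obj <- function(tau) {
    if (reml) {
      f <- .wls(yr, Xr, lambda, tau, "fit")
      .remlProfile(n, p, f$rss, tau, lambda, f$qr)
    } else {
      .mlProfile(n, .wls(yr, Xr, lambda, tau), tau, lambda)
    }
  }
  ll <- vapply(grid, obj, numeric(1))
  # ties (within numerical tolerance, e.g. an exactly flat profile when
  # K = I) break toward the smallest tau for parsimony
  i <- which(ll >= max(ll) - 1e-8)[1]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(lt) obj(exp(lt)), lower = log(lo),
                         upper = log(hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective > ll[i] + 1e-10) {
    list(tau = exp(opt$maximum), loglik = opt$objective)
  } else {
    list(tau = grid[i], loglik = ll[i])
  }
}

#' Fit the kinship linear mixed model by maximum likelihood
#'
#' Fits \eqn{Y = X\beta + Zu + \epsilon} with
#' \eqn{u \sim N(0, \sigma^2\tau K)} for the design made of the covariate
#' columns plus the requested SNPs. The tau profile likelihood is maximized
#' over \eqn{[10^{-6}, 10^6]} on a 100-point log grid refined by Brent search
#' in the best bracket; \eqn{\hat\beta} and \eqn{\hat\sigma^2} are the
#' closed-form GLS/ML estimates at \eqn{\hat\tau}. BIC uses
#' d = (design columns) + 2 (for \eqn{\sigma^2} and \eqn{\tau}).
#'
#' @param data a [GWASData-class] object.
#' @param modelSnps integer indices of SNPs to include as fixed effects.
#' @param tauFixed optional tau value; when given, no profiling is done
#'   (P3D-style fits).
#' @param reml use REML instead of ML for the tau profile (off by default;
#'   the BIC is defined through the ML fit).
#' @param spectral optional precomputed [eigenRotate()] result, reused across
#'   many fits on the same data.
#' @return an [LMMFit-class] object.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(40 * 5, 2, 0.4), 40, 5)
#' d <- GWASData(rnorm(40), G, K = diag(40))
#' fitLMM(d, modelSnps = c(2L, 4L))
#' @export
fitLMM <- function(data, modelSnps = integer(0), tauFixed = NULL,
                   reml = FALSE, spectral = NULL) {
  stopifnot(is(data, "GWASData"))
  if (any(!is.finite(data@Y))) stop("non-finite phenotype")
  modelSnps <- sort(unique(as.integer(modelSnps)))
  X <- cbind(data@X, data@G[, modelSnps, drop = FALSE])
  if (length(modelSnps))
    colnames(X) <- c(colnames(data@X), data@snpInfo$snp[modelSnps])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[-qx$pivot[seq_len(qx$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "),
         " (resolve perfectly-correlated SNPs via their alias groups)")
  }
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  U <- spectral$vectors
  lambda <- spectral$values
  yr <- drop(crossprod(U, data@Y))
  Xr <- crossprod(U, X)
  n <- length(yr)
  p <- ncol(X)

  if (is.null(tauFixed)) {
    prof <- .profileTau(yr, Xr, lambda, reml = reml)
    tau <- prof$tau
  } else {
    if (tauFixed < 0) stop("tauFixed must be >= 0")
    tau <- tauFixed
  }
  f <- .wls(yr, Xr, lambda, tau, "fit")
  sigma2 <- f$rss / n
  loglik <- .mlProfile(n, f$rss, tau, lambda)
  beta <- f$beta
  names(beta) <- colnames(X)
  d <- p + 2
  new("LMMFit",
      modelSnps = modelSnps, beta = beta, sigma2 = sigma2, tau = tau,
      loglik = loglik, df = as.numeric(d), bic = -2 * loglik + d * log(n),
      n = n, method = if (reml) "REML" else "ML",
      tauProfiled = is.null(tauFixed))
}

#' Fixed-effect residuals and their singular covariance
#'
#' Returns \eqn{\hat Y = Y - X\hat\beta} (the random effect is not
#' subtracted) together with an eigen-factorization of the exact covariance
#' of that residual under the fitted base model,
#' \deqn{\Sigma(\hat\tau) = V - X (X^\top V^{-1} X)^{-1} X^\top,\qquad
#'       V = I + \hat\tau Z K Z^\top,}
#' the GLS projection of V off the fixed-effect space. Sigma is singular
#' with rank n - rank(X); eigenvalues below 1e-10 times the largest are
#' treated as zero, and single-SNP screening regressions are fitted in the
#' retained eigenbasis (a proper density on the column space of Sigma).
#'
#' @param data a [GWASData-class] object.
#' @param fit the [LMMFit-class] of the base model on the same data.
#' @param spectral optional precomputed [eigenRotate()] result.
#' @return list with \code{yhat}, eigen-\code{vectors} and \code{values} of
#'   the retained subspace, \code{rank}, \code{tau}, \code{X}.
#' @export
residualize <- function(data, fit, spectral = NULL) {
  stopifnot(is(data, "GWASData"), is(fit, "LMMFit"))
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  X <- cbind(data@X, data@G[, fit@modelSnps, drop = FALSE])
  if (ncol(X) != length(fit@beta)) stop("fit/data design mismatch")
  U <- spectral$vectors
  lambda <- spectral$values
  tau <- fit@tau
  yhat <- data@Y - drop(X %*% fit@beta)
  w <- 1 / (1 + tau * lambda)
  Xr <- crossprod(U, X)
  A <- solve(crossprod(Xr, Xr * w))          # (X' V^-1 X)^-1
  V <- U %*% (t(U) * (1 + tau * lambda))     # U diag(1+tau*lambda) U'
  Sigma <- V - X %*% A %*% t(X)
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  list(yhat = yhat, vectors = e$vectors[, keep, drop = FALSE],
       values = e$values[keep], rank = sum(keep), tau = tau, X = X)
}
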