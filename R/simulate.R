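#' @include AllClasses.R
NULL

#' Causal-effect pattern for the simulation studies
#'
#' Ten causal effects in which seven coefficients are fixed at 0.4 and the
#' remaining three (positions 1, 5 and 9) share a common value
#' \code{beta1}, producing settings that range from three small effects
#' (beta1 = 0.05) to three dominant ones (beta1 = 1.6).
#'
#' @param beta1 the shared value of the three varying coefficients.
#' @return numeric vector of length 10.
#' @examples
#' betaPattern(1.6)
#' @export
betaPattern <- function(beta1) {
  b <- rep(0.4, 10)
  b[c(1, 5, 9)] <- beta1
  b
}

## causal positions default to the block centers, mirroring the placement
## of causal SNPs at the center of each LD block
.blockCenters <- function(L, nBlocks) {
  bs <- L %/% nBlocks
  as.integer(bs %/% 2 + bs * (seq_len(nBlocks) - 1))
}

#' Construct simulation settings
#'
#' Validated constructor for [SimSettings-class]. Defaults encode the study
#' conditions the method targets: n = 328 individuals (one observation per
#' strain, Z = I), L = 60000 SNPs in 10 LD blocks of 6000, adjacent-SNP
#' latent correlation rho = 0.9, minimum MAF 0.01, 10 causal SNPs at the
#' block centers with effects [betaPattern()](0.4), intercept alpha = 1,
#' tau = 0.1 and sigma2 = 0.2 under the mixed model. Pass smaller n/L (and
#' rho = 0 for independent SNPs) for quick experiments.
#'
#' @param n,L individuals and SNPs.
#' @param nBlocks number of LD blocks (must divide L).
#' @param blockSize SNPs per block; derived from L/nBlocks when missing.
#' @param rho within-block latent AR(1) correlation in [0, 1).
#' @param mafMin minimum minor-allele frequency.
#' @param causal causal SNP indices; default block centers (10 SNPs).
#' @param beta causal effects; default \code{betaPattern(0.4)} trimmed to
#'   \code{length(causal)}.
#' @param alpha intercept. @param tau kinship dependence.
#' @param sigma2 error variance.
#' @param model "mixed", "null" or "linear".
#' @param seed integer seed.
#' @return a [SimSettings-class] object.
#' @export
SimSettings <- function(n = 328, L = 60000, nBlocks = 10,
                        blockSize = L %/% nBlocks, rho = 0.9, mafMin = 0.01,
                        causal = .blockCenters(L, nBlocks),
                        beta = betaPattern(0.4)[seq_along(causal)],
                        alpha = 1, tau = 0.1, sigma2 = 0.2,
                        model = c("mixed", "null", "linear"), seed = 1) {
  model <- match.arg(model)
  if (model == "null") { causal <- integer(0); beta <- numeric(0) }
  new("SimSettings",
      n = as.integer(n), L = as.integer(L), nBlocks = as.integer(nBlocks),
      blockSize = as.integer(blockSize), rho = rho, mafMin = mafMin,
      causal = as.integer(causal), beta = as.numeric(beta),
      alpha = alpha, tau = tau, sigma2 = sigma2, model = model,
      seed = as.integer(seed))
}

## latent AR(1) block, thresholded to Hardy-Weinberg dosages at drawn MAFs
.genotypeBlock <- function(n, B, rho, mafMin) {
  maf <- stats::runif(B, mafMin, 0.5)
  E <- matrix(stats::rnorm(n * B), n, B)
  Zl <- E
  if (rho > 0 && B > 1) {
    for (j in 2:B) Zl[, j] <- rho * Zl[, j - 1] + sqrt(1 - rho^2) * E[, j]
  }
  q0 <- stats::qnorm((1 - maf)^2)
  q1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  G <- (Zl > rep(q0, each = n)) + (Zl > rep(q1, each = n))
  ## regenerate columns whose realized (folded) MAF dropped below the floor
  for (j in seq_len(B)) {
    tries <- 0L
    repeat {
      m <- mean(G[, j]) / 2
      if (min(m, 1 - m) >= mafMin && stats::var(G[, j]) > 0) break
      tries <- tries + 1L
      if (tries > 100L) stop("cannot reach the MAF floor at this sample size")
      p <- stats::runif(1, max(mafMin, 0.05), 0.5)
      z <- stats::rnorm(n)
      G[, j] <- (z > stats::qnorm((1 - p)^2)) +
        (z > stats::qnorm((1 - p)^2 + 2 * p * (1 - p)))
    }
  }
  storage.mode(G) <- "double"
  G
}

#' Simulate LD-block-structured genotypes
#'
#' Generates biallelic dosages in blocks: within each block a latent
#' Gaussian AR(1) process with correlation \code{rho} is thresholded to
#' Hardy-Weinberg genotype frequencies at a MAF drawn uniformly from
#' [mafMin, 0.5]; blocks are mutually independent. Columns whose realized
#' minor-allele frequency falls below the floor are redrawn (independently,
#' so regenerated columns carry no LD).
#'
#' @param settings a [SimSettings-class] object.
#' @param seed RNG seed; defaults to \code{settings@seed}. Pass NULL to use
#'   the current RNG state.
#' @return n x L dosage matrix with columns named snp1..snpL.
#' @export
simulateGenotypes <- function(settings, seed = settings@seed) {
  if (settings@rho >= 1) stop("rho must be < 1")
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(settings@nBlocks), function(b)
    .genotypeBlock(settings@n, settings@blockSize, settings@rho,
                   settings@mafMin))
  G <- do.call(cbind, blocks)
  colnames(G) <- paste0("snp", seq_len(ncol(G)))
  G
}

#' VanRaden realized-relationship (kinship) matrix
#'
#' Centers each genotype column by twice its allele frequency and scales the
#' cross-product by the total heterozygosity:
#' \deqn{K = \frac{W W^\top}{2 \sum_j \bar p_j (1 - \bar p_j)},\qquad
#'       W = G - 2\bar p,}
#' the standard realized-relationship estimator (the A.mat construction).
#' Monomorphic columns carry no information and are excluded with a warning.
#'
#' @param G n x L dosage matrix, entries 0/1/2.
#' @return n x n symmetric PSD kinship matrix.
#' @export
buildKinship <- function(G) {
  p <- colMeans(G) / 2
  mono <- p == 0 | p == 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic column(s) excluded from the kinship")
    G <- G[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (!ncol(G)) stop("no polymorphic SNPs to build a kinship from")
  W <- sweep(G, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  (K + t(K)) / 2
}

#' Simulate phenotypes under the mixed, null or linear model
#'
#' Draws \eqn{Y = \alpha 1 + G\beta + Zu + \epsilon} with
#' \eqn{u \sim N(0, \sigma^2\tau K)} and
#' \eqn{\epsilon \sim N(0, \sigma^2 I)}; the "null" model omits the genetic
#' effects \eqn{G\beta} and the "linear" model omits the random effect u.
#' Z is the identity (one observation per strain), matching the simulation
#' design.
#'
#' @param G n x L dosage matrix.
#' @param K n x n kinship matrix.
#' @param settings a [SimSettings-class] object.
#' @param seed RNG seed; NULL to use the current RNG state.
#' @return list with \code{Y} (numeric vector) and \code{truth}
#'   ([SimTruth-class]).
#' @export
simulatePhenotype <- function(G, K, settings, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G)
  L <- ncol(G)
  betaFull <- numeric(L)
  betaFull[settings@causal] <- settings@beta
  mu <- settings@alpha +
    if (settings@model == "null") 0 else drop(G %*% betaFull)
  if (settings@model %in% c("mixed", "null")) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    u <- sqrt(settings@sigma2 * settings@tau) *
      drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * stats::rnorm(n)))
  } else {
    u <- numeric(0)
  }
  eps <- stats::rnorm(n, 0, sqrt(settings@sigma2))
  Y <- mu + (if (length(u)) u else 0) + eps
  ind <- integer(L)
  ind[settings@causal] <- 1L
  truth <- new("SimTruth", causalIndicator = ind, betaTrue = betaFull,
               u = u, kinship = K)
  list(Y = Y, truth = truth)
}

#' Simulate a complete synthetic GWAS dataset
#'
#' Seeds the RNG once from \code{settings@seed}, then draws genotypes,
#' builds the realized-relationship kinship from them, and draws the
#' phenotype; identical settings give bit-identical output.
#'
#' @param settings a [SimSettings-class] object.
#' @return list with \code{data} ([GWASData-class]), \code{truth}
#'   ([SimTruth-class]) and \code{settings}.
#' @examples
#' sim <- simulateGWAS(SimSettings(n = 100, L = 200, nBlocks = 10, seed = 3))
#' sim$data
#' @export
simulateGWAS <- function(settings) {
  set.seed(settings@seed)
  G <- simulateGenotypes(settings, seed = NULL)
  K <- buildKinship(G)
  ph <- simulatePhenotype(G, K, settings, seed = NULL)
  info <- data.frame(snp = colnames(G),
                     chrom = as.character(rep(seq_len(settings@nBlocks),
                                              each = settings@blockSize)),
                     pos = rep(seq_len(settings@blockSize),
                               settings@nBlocks),
                     stringsAsFactors = FALSE)
  data <- GWASData(Y = ph$Y, G = G, K = K, snpInfo = info, checkPSD = FALSE)
  list(data = data, truth = ph$truth, settings = settings)
}
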