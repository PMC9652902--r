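#' @include AllClasses.R
NULL

#' Iterative conditional Bayesian GWAS search
#'
#' Runs the full iterative procedure. Starting from a base model with no
#' SNPs, each outer iteration (i) fits the base kinship LMM by maximum
#' likelihood, (ii) screens every remaining SNP against the base-model
#' residuals and flags candidates by posterior-expected FDR control at
#' \code{q0}, and (iii) performs Bayesian model selection over every
#' combination of base and candidate SNPs -- complete enumeration when the
#' union has at most 15 SNPs, genetic-algorithm search otherwise -- at a tau
#' fixed once from the full model (P3D). The best model becomes the next
#' base model; the loop stops at a fixed point (best model equals its base
#' model), when a previously-visited base model recurs (cycle), or after
#' \code{maxOuter} iterations.
#'
#' pi0 is re-estimated from the screening Wald p-values at every iteration,
#' but every model-selection step reuses the pi0 frozen at the first
#' screening, which keeps first-iteration SNPs competitive in later
#' selections. Perfectly correlated SNPs within a search space are collapsed
#' to the lowest-index representative; dropped columns are reported as
#' aliases.
#'
#' @param data a [GWASData-class] object (MAF-filtered).
#' @param q0 nominal Bayesian FDR level for the screening step (default
#'   0.05).
#' @param gaConfig a [GAConfig-class] for the stochastic search.
#' @param maxOuter maximum outer iterations (default 50).
#' @param seed optional integer seed; fixes the GA randomness so reruns are
#'   bit-identical.
#' @param verbose print per-iteration progress.
#' @return a [BicossRun-class] object.
#' @examples
#' sim <- simulateGWAS(SimSettings(n = 150, L = 300, nBlocks = 10, rho = 0,
#'                                 causal = c(50L, 250L), beta = c(1.5, 1.2),
#'                                 seed = 7))
#' run <- runBicoss(sim$data, seed = 1)
#' finalModel(run)
#' @export
runBicoss <- function(data, q0 = 0.05, gaConfig = GAConfig(), maxOuter = 50,
                      seed = NULL, verbose = FALSE) {
  stopifnot(is(data, "GWASData"))
  if (!is.null(seed)) set.seed(seed)
  spectral <- eigenRotate(data@Z, data@K)
  base <- integer(0)
  frozenPrior <- NULL
  visited <- character(0)
  iterations <- list()
  firstSeen <- new.env(parent = emptyenv())
  aliases <- data.frame(kept = integer(0), dropped = integer(0))
  stopReason <- "max_iter"
  converged <- FALSE

  for (iter in seq_len(maxOuter)) {
    visited <- c(visited, paste(base, collapse = "."))
    fit <- fitLMM(data, base, spectral = spectral)
    resid <- residualize(data, fit, spectral = spectral)
    scr <- screenSNPs(data, resid, baseSnps = base, prior = NULL, q0 = q0)
    if (is.null(frozenPrior)) frozenPrior <- scr@prior
    cand <- scr@candidates
    for (sn in cand) {
      key <- as.character(sn)
      if (is.null(get0(key, envir = firstSeen, inherits = FALSE)))
        assign(key, iter, envir = firstSeen)
    }

    res <- .resolveAliases(data@G, c(base, cand))
    if (nrow(res$aliases)) {
      newAl <- res$aliases[!res$aliases$dropped %in% aliases$dropped, , drop = FALSE]
      aliases <- rbind(aliases, newAl)
    }
    unionSnps <- res$keep

    if (!length(unionSnps)) {
      best <- new("SNPModel", snps = integer(0), bic = fit@bic, logBF = 0,
                  logPrior = priorModelProb(frozenPrior, 0,
                                            s = max(frozenPrior@s, 1)),
                  posterior = 1)
      search <- NULL
      tau <- fit@tau
    } else {
      tau <- p3dTau(data, unionSnps, spectral = spectral, baseSnps = base)
      search <- if (length(unionSnps) <= 15) {
        enumerateModels(data, base, setdiff(unionSnps, base), frozenPrior,
                        tau, spectral = spectral)
      } else {
        post <- scr@pPost
        gaSearch(data, base, setdiff(unionSnps, base), frozenPrior, tau,
                 config = gaConfig, spectral = spectral, screenPost = post)
      }
      best <- search@best
    }

    iterations[[iter]] <- list(
      base = base, candidates = cand, best = best@snps,
      tau = fit@tau, tauP3D = tau, pi0 = scr@prior@pi0,
      method = if (is.null(search)) "none" else search@method,
      posterior = best@posterior)
    if (verbose)
      message(sprintf("iter %d: base {%s} -> %d candidate(s) -> best {%s}",
                      iter, paste(base, collapse = ","), length(cand),
                      paste(best@snps, collapse = ",")))

    if (setequal(best@snps, base)) {
      converged <- TRUE
      stopReason <- "fixed_point"
      break
    }
    key <- paste(sort(best@snps), collapse = ".")
    if (key %in% visited) {
      stopReason <- "cycle"
      ## return the best-scoring model among the visited base models,
      ## compared by prior-adjusted BIC with tau re-profiled per model
      seen <- unique(c(visited, key))
      cmp <- vapply(seen, function(k) {
        snps <- if (nzchar(k)) as.integer(strsplit(k, ".", fixed = TRUE)[[1]]) else integer(0)
        f <- fitLMM(data, snps, spectral = spectral)
        f@bic - 2 * priorModelProb(frozenPrior, length(snps),
                                   s = max(frozenPrior@s, 1))
      }, numeric(1))
      bk <- seen[which.min(cmp)]
      bsnps <- if (nzchar(bk)) as.integer(strsplit(bk, ".", fixed = TRUE)[[1]]) else integer(0)
      best <- new("SNPModel", snps = bsnps, bic = fitLMM(data, bsnps,
                  spectral = spectral)@bic, logBF = NA_real_,
                  logPrior = priorModelProb(frozenPrior, length(bsnps),
                                            s = max(frozenPrior@s, 1)),
                  posterior = NA_real_)
      break
    }
    base <- sort(best@snps)
  }

  finalFit <- fitLMM(data, best@snps, spectral = spectral)
  prov <- data.frame(
    snp = best@snps,
    iterationFound = vapply(best@snps, function(sn) {
      v <- get0(as.character(sn), envir = firstSeen, inherits = FALSE)
      if (is.null(v)) NA_integer_ else as.integer(v)
    }, integer(1)))
  new("BicossRun",
      iterations = iterations, finalModel = best, finalFit = finalFit,
      converged = converged, stopReason = stopReason,
      provenance = prov, aliases = aliases,
      pi0First = if (is.null(frozenPrior)) NA_real_ else frozenPrior@pi0)
}
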