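#' @include AllClasses.R
NULL

## canonical archive key of a model (sorted union-relative indices)
.modelKey <- function(bits) paste0("m", paste(which(bits), collapse = "."))

## Detect perfectly correlated columns among G[, idx]; keep the
## lowest-index SNP of each group and report the rest as aliases.
.resolveAliases <- function(G, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 2)
    return(list(keep = idx, aliases = data.frame(kept = integer(0),
                                                 dropped = integer(0))))
  cc <- suppressWarnings(stats::cor(G[, idx, drop = FALSE]))
  cc[!is.finite(cc)] <- 0
  keep <- logical(length(idx))
  rep_of <- integer(length(idx))
  for (j in seq_along(idx)) {
    earlier <- which(keep[seq_len(j - 1)] & abs(cc[seq_len(j - 1), j]) > 1 - 1e-10)
    if (j > 1 && length(earlier)) {
      rep_of[j] <- idx[earlier[1]]
    } else {
      keep[j] <- TRUE
    }
  }
  list(keep = idx[keep],
       aliases = data.frame(kept = rep_of[!keep], dropped = idx[!keep]))
}

#' P3D estimate of the kinship dependence parameter
#'
#' Estimates tau once by maximum likelihood from the full model containing
#' all base and candidate SNPs; every model fit in the subsequent selection
#' step holds tau fixed at this value ("population parameters previously
#' determined"). If the full design is too large (rank > n - 2), tau falls
#' back to the base-model estimate.
#'
#' @param data a [GWASData-class] object.
#' @param unionSnps indices of base plus candidate SNPs.
#' @param spectral optional precomputed [eigenRotate()] result.
#' @param baseSnps base-model SNPs, used for the fallback fit.
#' @return the tau estimate (scalar).
#' @export
p3dTau <- function(data, unionSnps, spectral = NULL, baseSnps = integer(0)) {
  unionSnps <- sort(unique(as.integer(unionSnps)))
  n <- length(data@Y)
  if (ncol(data@X) + length(unionSnps) > n - 2) {
    warning("full model larger than n - 2; tau taken from the base model")
    return(fitLMM(data, baseSnps, spectral = spectral)@tau)
  }
  fitLMM(data, unionSnps, spectral = spectral)@tau
}

## Build a fast model scorer over the union SNPs at fixed tau. Uses the
## weighted Gram matrix so each model costs one small Cholesky solve,
## independent of n. Returns closures sharing a cache environment.
.makeScorer <- function(data, unionSnps, tau, spectral, prior,
                        priorAdjusted = TRUE) {
  U <- spectral$vectors
  lambda <- spectral$values
  sw <- 1 / sqrt(1 + tau * lambda)
  Xall <- cbind(data@X, data@G[, unionSnps, drop = FALSE])
  Xw <- crossprod(U, Xall) * sw
  yw <- drop(crossprod(U, data@Y)) * sw
  C <- crossprod(Xw)
  b <- drop(crossprod(Xw, yw))
  yy <- sum(yw^2)
  ldet <- sum(log1p(tau * lambda))
  n <- length(yw)
  cc <- ncol(data@X)
  s <- length(unionSnps)
  localPrior <- new("ModelPrior", pi0 = prior@pi0, s = as.integer(s),
                    source = prior@source)
  cache <- new.env(parent = emptyenv())
  nEval <- 0L
  cacheHits <- 0L

  score <- function(bits) {
    key <- .modelKey(bits)
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) {
      cacheHits <<- cacheHits + 1L
      return(hit)
    }
    idx <- c(seq_len(cc), cc + which(bits))
    Ci <- C[idx, idx, drop = FALSE]
    bi <- b[idx]
    ch <- tryCatch(chol(Ci), error = function(e) NULL)
    rec <- if (is.null(ch)) {
      list(key = key, ok = FALSE, bic = Inf, loglik = -Inf,
           logPrior = -Inf, objective = Inf, nsnps = sum(bits))
    } else {
      beta <- backsolve(ch, forwardsolve(t(ch), bi))
      rss <- max(yy - sum(bi * beta), .Machine$double.xmin)
      ll <- -0.5 * n * log(2 * pi * rss / n) - 0.5 * ldet - 0.5 * n
      d <- length(idx) + 2
      bic <- -2 * ll + d * log(n)
      lp <- priorModelProb(localPrior, sum(bits))
      list(key = key, ok = TRUE, bic = bic, loglik = ll, logPrior = lp,
           objective = if (priorAdjusted) bic - 2 * lp else bic,
           nsnps = sum(bits))
    }
    nEval <<- nEval + 1L
    assign(key, rec, envir = cache)
    rec
  }
  list(score = score,
       stats = function() list(nEval = nEval, cacheHits = cacheHits),
       archive = function() {
         recs <- mget(ls(cache), envir = cache)
         data.frame(key = vapply(recs, `[[`, "", "key"),
                    nsnps = vapply(recs, `[[`, 0, "nsnps"),
                    bic = vapply(recs, `[[`, 0, "bic"),
                    logPrior = vapply(recs, `[[`, 0, "logPrior"),
                    row.names = NULL, stringsAsFactors = FALSE)
       },
       prior = localPrior, n = n)
}

## posterior over an archive; returns data.frame with posterior column and
## the best row index (min prior-adjusted score; ties -> fewer SNPs, then
## lexicographically smallest key)
.archivePosterior <- function(arch) {
  logw <- ifelse(is.finite(arch$bic), arch$logPrior - 0.5 * arch$bic, -Inf)
  arch$posterior <- .normalizeLog(logw)
  sc <- -logw
  best <- which(sc <= min(sc) + 1e-9)
  if (length(best) > 1) {
    best <- best[order(arch$nsnps[best], arch$key[best])]
  }
  list(arch = arch, best = best[1])
}

.bitsFromKey <- function(key, s) {
  key <- sub("^m", "", key)
  bits <- logical(s)
  if (nzchar(key)) bits[as.integer(strsplit(key, ".", fixed = TRUE)[[1]])] <- TRUE
  bits
}

.buildSearchResult <- function(scorer, unionSnps, baseSnps, method,
                               tau, generations, trace = numeric(0)) {
  baseBic <- scorer$score(unionSnps %in% baseSnps)$bic
  arch <- scorer$archive()
  ap <- .archivePosterior(arch)
  arch <- ap$arch
  bi <- ap$best
  bestBits <- .bitsFromKey(arch$key[bi], length(unionSnps))
  st <- scorer$stats()
  best <- new("SNPModel",
              snps = unionSnps[bestBits],
              bic = arch$bic[bi],
              logBF = bayesFactorApprox(arch$bic[bi], baseBic, log = TRUE),
              logPrior = arch$logPrior[bi],
              posterior = arch$posterior[bi])
  new("SearchResult", best = best, models = arch, method = method,
      tauP3D = tau, nEval = st$nEval, cacheHits = st$cacheHits,
      generations = as.integer(generations), trace = trace)
}

#' Complete enumeration of the SNP model space
#'
#' Scores every subset of the union of base and candidate SNPs (base SNPs
#' may be dropped) at the P3D-fixed tau and returns the highest-posterior
#' model. Refuses spaces with more than 15 SNPs, where the genetic algorithm
#' takes over.
#'
#' @param data a [GWASData-class] object.
#' @param baseSnps,candidateSnps SNP index sets; their union (at most 15
#'   SNPs) defines the space.
#' @param prior a [ModelPrior-class]; its pi0 parameterizes the Bernoulli
#'   prior over this space.
#' @param tauP3D fixed kinship dependence parameter from [p3dTau()].
#' @param spectral optional precomputed [eigenRotate()] result.
#' @return a [SearchResult-class] object.
#' @export
enumerateModels <- function(data, baseSnps, candidateSnps, prior, tauP3D,
                            spectral = NULL) {
  unionSnps <- sort(unique(c(as.integer(baseSnps), as.integer(candidateSnps))))
  s <- length(unionSnps)
  if (s > 15) stop("model space with ", s, " SNPs; use gaSearch() for 16 or more")
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  scorer <- .makeScorer(data, unionSnps, tauP3D, spectral, prior)
  if (s == 0) {
    scorer$score(logical(0))
  } else {
    pow <- 2^(seq_len(s) - 1)
    for (m in 0:(2^s - 1)) scorer$score(bitwAnd(m, pow) > 0)
  }
  .buildSearchResult(scorer, unionSnps, as.integer(baseSnps), "enumeration",
                     tauP3D, 0L)
}

#' Genetic-algorithm search of the SNP model space
#'
#' Stochastic search over binary inclusion chromosomes of length s (the
#' union of base and candidate SNPs). The initial population holds the
#' intercept-only model, one-SNP models for up to 99 SNPs ranked by
#' screening posterior, and random models for any remaining slots. Each
#' generation applies fitness-proportional selection with probabilities
#' proportional to \eqn{\exp(-0.5\,score_i)} (score = BIC, prior-adjusted by
#' default; log-sum-exp normalized), single-point crossover, single-bit
#' mutation, and elitism (the best model always survives). Every evaluated
#' model is cached by canonical key so each BIC is computed once. Stops
#' after \code{maxIter} generations or \code{runStop} consecutive
#' generations with an unchanged best model.
#'
#' @inheritParams enumerateModels
#' @param config a [GAConfig-class].
#' @param screenPost optional screening posteriors used to rank the one-SNP
#'   models of the initial population (base SNPs rank first).
#' @return a [SearchResult-class] object.
#' @export
gaSearch <- function(data, baseSnps, candidateSnps, prior, tauP3D,
                     config = GAConfig(), spectral = NULL, screenPost = NULL) {
  baseSnps <- sort(unique(as.integer(baseSnps)))
  unionSnps <- sort(unique(c(baseSnps, as.integer(candidateSnps))))
  s <- length(unionSnps)
  if (s == 0) stop("empty model space")
  if (is.null(spectral)) spectral <- eigenRotate(data@Z, data@K)
  scorer <- .makeScorer(data, unionSnps, tauP3D, spectral, prior,
                        priorAdjusted = config@priorAdjusted)
  np <- config@popSize

  ## initial population: intercept-only, top single-SNP models, random rest
  rank <- if (is.null(screenPost)) {
    seq_len(s)
  } else {
    post <- screenPost[unionSnps]
    post[unionSnps %in% baseSnps] <- Inf   # base SNPs are ranked first
    order(-post)
  }
  pop <- vector("list", np)
  pop[[1]] <- logical(s)
  nOne <- min(s, 99L, np - 1L)
  for (i in seq_len(nOne)) {
    bits <- logical(s)
    bits[rank[i]] <- TRUE
    pop[[i + 1L]] <- bits
  }
  for (i in seq_len(np - 1L - nOne))
    pop[[1L + nOne + i]] <- stats::runif(s) < 0.5

  evalPop <- function(pop) vapply(pop, function(b) scorer$score(b)$objective,
                                  numeric(1))
  obj <- evalPop(pop)
  bestIdx <- which.min(obj)
  bestBits <- pop[[bestIdx]]
  bestObj <- obj[bestIdx]
  bestKey <- .modelKey(bestBits)
  stable <- 0L
  gen <- 0L
  trace <- numeric(0)

  while (gen < config@maxIter && stable < config@runStop) {
    gen <- gen + 1L
    probs <- .normalizeLog(-0.5 * obj)
    idx <- sample.int(np, np, replace = TRUE, prob = probs)
    newPop <- pop[idx]
    ## single-point crossover on consecutive pairs
    for (k in seq_len(np %/% 2)) {
      if (s > 1 && stats::runif(1) < config@pCrossover) {
        a <- 2 * k - 1
        cp <- sample.int(s - 1, 1)
        tailA <- newPop[[a]][(cp + 1):s]
        newPop[[a]][(cp + 1):s] <- newPop[[a + 1]][(cp + 1):s]
        newPop[[a + 1]][(cp + 1):s] <- tailA
      }
    }
    ## mutation: flip the status of one SNP
    for (k in seq_len(np)) {
      if (stats::runif(1) < config@pMutation) {
        j <- sample.int(s, 1)
        newPop[[k]][j] <- !newPop[[k]][j]
      }
    }
    ## elitism: best-so-far always survives
    newPop[[1]] <- bestBits
    pop <- newPop
    obj <- evalPop(pop)
    i <- which.min(obj)
    if (obj[i] < bestObj - 1e-12) {
      bestObj <- obj[i]
      bestBits <- pop[[i]]
      key <- .modelKey(bestBits)
      if (key != bestKey) { bestKey <- key; stable <- 0L } else stable <- stable + 1L
    } else {
      stable <- stable + 1L
    }
    trace <- c(trace, bestObj)
  }
  .buildSearchResult(scorer, unionSnps, baseSnps, "ga", tauP3D, gen, trace)
}
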