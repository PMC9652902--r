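#' @include AllClasses.R
NULL

#' Score a discovery set against the simulation truth
#'
#' Confusion counts of a found SNP set against the true causal indicator,
#' with the rates recall = TP/(TP+FN), FDR = FP/(TP+FP), FPR = FP/(FP+TN)
#' and F1 = TP/(TP + 0.5 (FP+FN)); 0/0 is reported as 0 (relevant for runs
#' with no discoveries or no causal SNPs). Truth is strictly positional: a
#' discovery in perfect LD with a causal SNP still counts as a false
#' positive unless it is the causal index itself. \code{window > 0} enables
#' an optional relaxed mode in which a discovery within \code{window}
#' positions of a causal SNP (same chromosome ordering assumed) counts as a
#' true positive; it is off by default.
#'
#' @param found integer indices of discovered SNPs.
#' @param truth a [SimTruth-class] object.
#' @param window non-negative integer; 0 (default) for strict positional
#'   matching.
#' @return one-row data.frame with tp, fp, fn, tn, recall, fdr, fpr, f1.
#' @examples
#' tr <- new("SimTruth", causalIndicator = c(1L, 0L, 0L, 1L),
#'           betaTrue = c(1, 0, 0, 1), u = numeric(0),
#'           kinship = matrix(0, 0, 0))
#' scoreDiscoveries(c(1L, 2L), tr)
#' @export
scoreDiscoveries <- function(found, truth, window = 0L) {
  L <- length(truth@causalIndicator)
  found <- unique(as.integer(found))
  if (length(found) && (min(found) < 1 || max(found) > L))
    stop("found indices outside 1..L")
  causal <- which(truth@causalIndicator == 1L)
  if (window > 0L && length(causal)) {
    isTP <- vapply(found, function(f) any(abs(f - causal) <= window), logical(1))
    tp <- length(unique(vapply(found[isTP], function(f)
      causal[which.min(abs(f - causal))], integer(1))))
    fp <- sum(!isTP)
  } else {
    tp <- sum(found %in% causal)
    fp <- sum(!found %in% causal)
  }
  fn <- length(causal) - tp
  tn <- L - length(causal) - fp
  div0 <- function(num, den) if (den == 0) 0 else num / den
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             recall = div0(tp, tp + fn),
             fdr = div0(fp, tp + fp),
             fpr = div0(fp, fp + tn),
             f1 = div0(tp, tp + 0.5 * (fp + fn)))
}

#' Run a replicated simulation experiment for one method
#'
#' Simulates \code{nRep} datasets from \code{settings} (replicate seeds are
#' derived deterministically from \code{seed}), analyzes each with the
#' requested method, scores the discoveries against the truth and averages
#' the metrics. For the "null" model only false-positive counts are
#' meaningful and recall is reported as 0.
#'
#' @param method one of "bicoss", "sma-exact", "sma-approx", "sma-ols".
#' @param settings a [SimSettings-class] object (its seed slot is ignored;
#'   replicate seeds come from \code{seed}).
#' @param nRep number of replicate datasets.
#' @param seed master seed.
#' @param q0 Bayesian FDR level for the iterative method (default 0.05).
#' @param gaConfig [GAConfig-class] for the stochastic search.
#' @param outDir optional directory; when given, per-replicate discoveries
#'   and the averaged metrics are written as CSV and JSON.
#' @return list with \code{perReplicate} (data.frame, one row per
#'   replicate) and \code{summary} (averaged metrics, one row).
#' @export
runExperiment <- function(method = c("bicoss", "sma-exact", "sma-approx",
                                     "sma-ols"),
                          settings, nRep = 10, seed = 1, q0 = 0.05,
                          gaConfig = GAConfig(), outDir = NULL) {
  method <- match.arg(method)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nRep)
  rows <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    s <- settings
    s@seed <- repSeeds[r]
    sim <- simulateGWAS(s)
    found <- switch(method,
      "bicoss" = finalModel(runBicoss(sim$data, q0 = q0, gaConfig = gaConfig,
                                      seed = repSeeds[r]))@snps,
      "sma-exact" = smaExact(sim$data)@significant,
      "sma-approx" = smaApprox(sim$data)@significant,
      "sma-ols" = smaOLS(sim$data)@significant)
    m <- scoreDiscoveries(found, sim$truth)
    rows[[r]] <- cbind(data.frame(replicate = r, seed = repSeeds[r],
                                  nFound = length(found),
                                  found = paste(found, collapse = ";")), m)
  }
  per <- do.call(rbind, rows)
  summary <- data.frame(
    method = method, model = settings@model, nDatasets = as.integer(nRep),
    tp = mean(per$tp), fp = mean(per$fp), fn = mean(per$fn), tn = mean(per$tn),
    recall = mean(per$recall), fdr = mean(per$fdr), fpr = mean(per$fpr),
    f1 = mean(per$f1))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per, file.path(outDir, paste0(method, "_replicates.csv")),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outDir, paste0(method, "_summary.csv")),
                     row.names = FALSE)
    jsonlite::write_json(as.list(summary),
                         file.path(outDir, paste0(method, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(perReplicate = per, summary = summary)
}
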