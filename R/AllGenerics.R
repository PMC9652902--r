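#' @include AllClasses.R
NULL

#' Accessors for GWASData and result objects
#'
#' Standard accessors: \code{phenotypes} returns the phenotype vector,
#' \code{genotypes} the dosage matrix, \code{covariates} the fixed-effect
#' design, \code{kinship} the relationship matrix, \code{incidence} the
#' strain-incidence matrix and \code{snpInfo} the SNP annotation table.
#' \code{nSamples} and \code{nSNPs} give the problem dimensions,
#' \code{candidates} the screening candidate set and \code{finalModel} the
#' converged model of a run.
#'
#' @param object a \linkS4class{GWASData}, \linkS4class{ScreeningResult} or
#'   \linkS4class{BicossRun}.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases phenotypes genotypes covariates kinship incidence snpInfo
#'   nSamples nSNPs candidates finalModel
NULL

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("kinship", function(object) standardGeneric("kinship"))
#' @rdname accessors
#' @export
setGeneric("incidence", function(object) standardGeneric("incidence"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nSNPs", function(object) standardGeneric("nSNPs"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("finalModel", function(object) standardGeneric("finalModel"))

#' @rdname accessors
setMethod("phenotypes", "GWASData", function(object) object@Y)
#' @rdname accessors
setMethod("genotypes", "GWASData", function(object) object@G)
#' @rdname accessors
setMethod("covariates", "GWASData", function(object) object@X)
#' @rdname accessors
setMethod("kinship", "GWASData", function(object) object@K)
#' @rdname accessors
setMethod("incidence", "GWASData", function(object) object@Z)
#' @rdname accessors
setMethod("snpInfo", "GWASData", function(object) object@snpInfo)
#' @rdname accessors
setMethod("nSamples", "GWASData", function(object) length(object@Y))
#' @rdname accessors
setMethod("nSNPs", "GWASData", function(object) ncol(object@G))
#' @rdname accessors
setMethod("candidates", "ScreeningResult", function(object) object@candidates)
#' @rdname accessors
setMethod("finalModel", "BicossRun", function(object) object@finalModel)

setMethod("show", "GWASData", function(object) {
  cat("GWASData:", length(object@Y), "samples,", ncol(object@G), "SNPs,",
      ncol(object@X), "covariate column(s),", ncol(object@Z), "strain(s)\n")
})

setMethod("show", "LMMFit", function(object) {
  cat(sprintf("LMMFit (%s): %d SNP(s), loglik = %.4f, BIC = %.4f\n",
              object@method, length(object@modelSnps), object@loglik, object@bic))
  cat(sprintf("  sigma2 = %.4g, tau = %.4g%s\n", object@sigma2, object@tau,
              if (object@tauProfiled) "" else " (fixed, P3D)"))
})

setMethod("show", "ModelPrior", function(object) {
  cat(sprintf("ModelPrior: pi0 = %.6f (%s), s = %d\n",
              object@pi0, object@source, object@s))
})

setMethod("show", "SNPModel", function(object) {
  cat(sprintf("SNPModel: {%s}, BIC = %.3f, posterior = %.4f\n",
              paste(object@snps, collapse = ", "), object@bic, object@posterior))
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: %d SNPs screened, %d candidate(s) at q0 = %g (pi0 = %.5f, %s)\n",
              sum(!is.na(object@pPost)), length(object@candidates), object@q0,
              object@prior@pi0, object@prior@source))
})

setMethod("show", "SearchResult", function(object) {
  cat(sprintf("SearchResult (%s): best model {%s}, posterior = %.4f, %d models scored\n",
              object@method, paste(object@best@snps, collapse = ", "),
              object@best@posterior, object@nEval))
})

setMethod("show", "BicossRun", function(object) {
  cat(sprintf("BicossRun: %d iteration(s), %s (%s)\n",
              length(object@iterations),
              if (object@converged) "converged" else "not converged",
              object@stopReason))
  cat(sprintf("  final model: {%s}, posterior = %.4f\n",
              paste(object@finalModel@snps, collapse = ", "),
              object@finalModel@posterior))
  if (nrow(object@aliases))
    cat(sprintf("  aliases: %d perfectly-correlated SNP(s) represented by kept columns\n",
                nrow(object@aliases)))
})

setMethod("show", "SMAResult", function(object) {
  cat(sprintf("SMAResult (%s): %d SNPs, %d significant under Bonferroni\n",
              object@method, length(object@pvals), length(object@significant)))
})

setMethod("show", "SimSettings", function(object) {
  cat(sprintf("SimSettings: n = %d, L = %d (%d blocks x %d, rho = %g), model = %s\n",
              object@n, object@L, object@nBlocks, object@blockSize, object@rho,
              object@model))
  cat(sprintf("  %d causal SNP(s), alpha = %g, tau = %g, sigma2 = %g, seed = %d\n",
              length(object@causal), object@alpha, object@tau, object@sigma2,
              object@seed))
})
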