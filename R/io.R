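#' @include AllClasses.R
NULL

## genotype CSV layout: header row of SNP ids, first column named ID with
## individual identifiers, remaining cells dosages 0/1/2 (blank/NA missing)
.readGenoCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  rownames(G) <- ids
  list(G = G,
       snpInfo = data.frame(snp = colnames(G), chrom = NA_character_,
                            pos = seq_len(ncol(G)), stringsAsFactors = FALSE),
       ids = ids)
}

#' Write a simulated dataset to disk
#'
#' Writes genotypes (CSV and/or PLINK BED/BIM/FAM), the phenotype as a
#' two-column TSV (ID, value), the kinship as CSV and the simulation truth
#' as JSON, so simulated studies can be re-analyzed from files.
#'
#' @param sim result of [simulateGWAS()].
#' @param dir output directory (created if needed).
#' @param format "csv", "bed" or both.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir, format = c("csv", "bed")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data <- sim$data
  n <- nSamples(data)
  ids <- paste0("ind", seq_len(n))
  if ("csv" %in% format) {
    df <- data.frame(ID = ids, genotypes(data), check.names = FALSE)
    utils::write.csv(df, file.path(dir, "genotypes.csv"), row.names = FALSE)
  }
  if ("bed" %in% format)
    writeBed(genotypes(data), file.path(dir, "genotypes"),
             snpInfo = snpInfo(data), ids = ids)
  utils::write.table(data.frame(ID = ids, value = phenotypes(data)),
                     file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(ID = ids, kinship(data), check.names = FALSE),
                   file.path(dir, "kinship.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(causal = which(sim$truth@causalIndicator == 1L),
         beta = sim$truth@betaTrue[sim$truth@causalIndicator == 1L],
         model = sim$settings@model, seed = sim$settings@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and align GWAS input files
#'
#' Reads genotypes (PLINK .bed or CSV), a phenotype TSV keyed by individual
#' ID, and optional covariate and kinship files; aligns everything to the
#' intersection of IDs in genotype-file order. Missing dosages are
#' mean-imputed per column (with a message); SNPs with minor allele
#' frequency <= \code{maf} or zero variance are removed, with counts
#' reported.
#'
#' @param geno path to a .bed file (with .bim/.fam siblings) or a genotype
#'   CSV (first column ID, then one column per SNP).
#' @param pheno path to a TSV with columns ID and value.
#' @param kinship optional kinship CSV (first column ID, then a square
#'   matrix block); computed from the filtered genotypes when absent.
#' @param covar optional covariate TSV (first column ID, then numeric
#'   columns).
#' @param maf minor-allele-frequency threshold; SNPs with MAF strictly
#'   greater than this are kept (default 0.01).
#' @param logPheno log-transform the phenotype (for right-skewed traits).
#' @return a [GWASData-class] object.
#' @export
readInputs <- function(geno, pheno, kinship = NULL, covar = NULL,
                       maf = 0.01, logPheno = FALSE) {
  gn <- if (grepl("\\.bed$", geno)) readBed(geno) else .readGenoCSV(geno)
  if (!all(gn$G %in% c(0, 1, 2) | is.na(gn$G)))
    stop("genotype codes outside {0, 1, 2, missing}")
  ph <- utils::read.delim(pheno, stringsAsFactors = FALSE)
  if (ncol(ph) < 2) stop("phenotype file needs ID and value columns")
  ids <- gn$ids[gn$ids %in% as.character(ph[[1]])]
  if (!length(ids)) stop("no overlapping IDs between genotype and phenotype files")
  G <- gn$G[match(ids, gn$ids), , drop = FALSE]
  Y <- as.numeric(ph[[2]])[match(ids, as.character(ph[[1]]))]
  if (logPheno) Y <- log(Y)

  nMiss <- sum(is.na(G))
  if (nMiss) {
    message(nMiss, " missing dosage(s) mean-imputed")
    for (j in which(colSums(is.na(G)) > 0)) {
      m <- mean(G[, j], na.rm = TRUE)
      G[is.na(G[, j]), j] <- m
    }
  }
  p <- colMeans(G) / 2
  keep <- pmin(p, 1 - p) > maf & apply(G, 2, stats::var) > 0
  message(sum(!keep), " SNP(s) removed by the MAF filter (> ", maf, "); ",
          sum(keep), " remain")
  G <- G[, keep, drop = FALSE]
  info <- gn$snpInfo[keep, , drop = FALSE]

  X <- NULL
  if (!is.null(covar)) {
    cv <- utils::read.delim(covar, stringsAsFactors = FALSE)
    X <- as.matrix(cv[match(ids, as.character(cv[[1]])), -1, drop = FALSE])
    storage.mode(X) <- "double"
    if (anyNA(X)) stop("missing covariate values after ID alignment")
  }
  K <- NULL
  if (!is.null(kinship)) {
    km <- utils::read.csv(kinship, check.names = FALSE,
                          stringsAsFactors = FALSE)
    km_ids <- as.character(km[[1]])
    K <- as.matrix(km[, -1, drop = FALSE])
    idx <- match(ids, km_ids)
    if (anyNA(idx)) stop("kinship file is missing some genotyped IDs")
    K <- K[idx, idx, drop = FALSE]
    storage.mode(K) <- "double"
  }
  GWASData(Y = Y, G = G, X = X, K = K, snpInfo = info)
}
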