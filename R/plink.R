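#' @include AllClasses.R
NULL

## PLINK 1 binary genotype files, SNP-major layout: three magic bytes
## 0x6c 0x1b 0x01, then ceiling(n/4) bytes per SNP, two bits per sample
## starting at the lowest-order bits. Codes (A1 = counted/minor allele):
## 00 = hom A1 (dosage 2), 10 = het (1), 11 = hom A2 (0), 01 = missing.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
.bedCodeFromDosage <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # NA -> 1L

#' Write genotypes as a PLINK BED/BIM/FAM file set
#'
#' Writes the SNP-major binary .bed plus its .bim (chromosome, SNP id, 0 cM,
#' position, alleles A/B) and .fam (family/individual ids, unknown parents
#' and sex, phenotype -9) companions. Dosages are counts of the A1 allele.
#'
#' @param G n x L dosage matrix (0/1/2, NA for missing).
#' @param prefix output path without extension.
#' @param snpInfo optional data.frame with snp/chrom/pos columns.
#' @param ids optional individual identifiers (default ind1..indn).
#' @return the prefix, invisibly.
#' @export
writeBed <- function(G, prefix, snpInfo = NULL, ids = NULL) {
  n <- nrow(G)
  L <- ncol(G)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(snp = if (is.null(colnames(G)))
      paste0("snp", seq_len(L)) else colnames(G),
      chrom = "1", pos = seq_len(L), stringsAsFactors = FALSE)
  }
  chrom <- snpInfo$chrom
  chrom[is.na(chrom)] <- "0"
  nBytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  pad <- 4 * nBytes - n
  for (j in seq_len(L)) {
    g <- G[, j]
    code <- ifelse(is.na(g), 1L, .bedCodeFromDosage[as.character(g)])
    code <- c(code, rep(0L, pad))
    m <- matrix(code, nrow = 4)
    bytes <- as.raw(m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L)
    writeBin(bytes, con)
  }
  utils::write.table(
    data.frame(chrom, snpInfo$snp, 0, snpInfo$pos, "A", "B"),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM file set
#'
#' Reads the SNP-major binary genotypes together with the .bim SNP table
#' and .fam individual ids. Missing genotypes become NA.
#'
#' @param prefix path without extension (a .bed path is also accepted).
#' @return list with \code{G} (n x L dosage matrix of the A1 allele, NA for
#'   missing), \code{snpInfo} (snp/chrom/pos) and \code{ids}.
#' @export
readBed <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  L <- nrow(bim)
  nBytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, .BED_MAGIC))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  raw <- readBin(con, "raw", nBytes * L)
  if (length(raw) < nBytes * L) stop("truncated .bed file")
  v <- as.integer(raw)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(codes) <- c(4 * nBytes, L)
  codes <- codes[seq_len(n), , drop = FALSE]
  G <- matrix(NA_real_, n, L)
  G[codes == 0L] <- 2
  G[codes == 2L] <- 1
  G[codes == 3L] <- 0
  colnames(G) <- bim$snp
  rownames(G) <- fam[[2]]
  list(G = G,
       snpInfo = data.frame(snp = bim$snp, chrom = as.character(bim$chrom),
                            pos = bim$pos, stringsAsFactors = FALSE),
       ids = as.character(fam[[2]]))
}
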