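#' Construct a genotype container from phased haplotype matrices
#'
#' @param sample_ids Character vector of n unique sample identifiers.
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, one row per biallelic SNP, sorted by (chrom, pos).
#' @param hap1,hap2 n x m integer matrices of alt-allele indicators (0/1) for
#'   the two phased haplotypes; `NA` where the genotype is missing.
#' @param phased Logical vector (length m): whether every call at the SNP was
#'   phased.  Unphased SNPs keep an arbitrary hap1/hap2 split and are only
#'   usable through dosages.
#' @param dosage Optional n x m dosage matrix; defaults to `hap1 + hap2`.
#'   Supply explicitly when missing calls were mean-imputed.
#' @return An object of class `genotype_data` with fields `sample_ids`,
#'   `variants`, `hap1`, `hap2`, `dosage`, `alt_freq`, `phased`,
#'   `complete` (no missing call at the SNP).
#' @export
genotype_data <- function(sample_ids, variants, hap1, hap2,
                          phased = rep(TRUE, ncol(hap1)), dosage = NULL) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  m <- nrow(variants)
  stopifnot(!anyDuplicated(sample_ids),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            identical(dim(hap1), c(n, m)), identical(dim(hap2), c(n, m)),
            length(phased) == m)
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_len(m))) {
    variants <- variants[ord, , drop = FALSE]
    hap1 <- hap1[, ord, drop = FALSE]
    hap2 <- hap2[, ord, drop = FALSE]
    phased <- phased[ord]
    if (!is.null(dosage)) dosage <- dosage[, ord, drop = FALSE]
  }
  complete <- !apply(is.na(hap1) | is.na(hap2), 2L, any)
  if (is.null(dosage)) {
    dosage <- hap1 + hap2
    if (anyNA(dosage))
      stop("missing genotype calls present; supply an imputed dosage matrix ",
           "or read with impute_mean = TRUE")
  }
  alt_freq <- colMeans(dosage) / 2
  rownames(variants) <- NULL
  gd <- list(sample_ids = sample_ids, variants = variants,
             hap1 = hap1, hap2 = hap2, dosage = dosage,
             alt_freq = as.numeric(alt_freq),
             phased = as.logical(phased), complete = complete)
  class(gd) <- "genotype_data"
  gd
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("<genotype_data> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " SNPs on ",
      length(unique(x$variants$chrom)), " chromosome(s); ",
      sum(!x$phased), " unphased, ", sum(!x$complete), " with missing calls\n",
      sep = "")
  invisible(x)
}

#' Number of samples / SNPs of a genotype container
#' @param gd A `genotype_data` object.
#' @return Integer count.
#' @export
n_samples <- function(gd) length(gd$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(gd) nrow(gd$variants)

#' Read phased genotypes from a VCF file
#'
#' Reads biallelic SNP records with a GT field into a [genotype_data()]
#' container.  Phasing is taken from the `|` separator per call; unphased
#' SNPs are flagged and excluded from haplotype analyses downstream.
#' Multiallelic records are an error (split them upstream, e.g. with
#' `bcftools norm -m-`).
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param impute_mean If `TRUE`, missing calls enter the dosage matrix as the
#'   SNP's mean dosage among observed calls; the SNP is then flagged
#'   incomplete and barred from haplotype blocks.  If `FALSE` (default), any
#'   missing call is an error.
#' @return A `genotype_data` object.
#' @export
read_genotypes <- function(path, impute_mean = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) not supported: ",
         paste(utils::head(fix$ID[multi], 5L), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  m <- nrow(gt)
  # calls are "a|b", "a/b" or "." / "./."
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  sep <- substr(gt, 2L, 2L)
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  bad <- !is.na(a1) & (a1 > 1L | (!is.na(a2) & a2 > 1L))
  if (any(bad))
    stop("allele index > 1 found (multiallelic GT): record ",
         fix$ID[(which(bad)[1L] - 1L) %% m + 1L])
  hap1 <- t(matrix(a1, nrow = m))
  hap2 <- t(matrix(a2, nrow = m))
  phased <- apply(matrix(sep == "|" | is.na(a1), nrow = m), 1L, all)
  miss <- is.na(hap1) | is.na(hap2)
  dosage <- NULL
  if (any(miss)) {
    if (!impute_mean)
      stop("missing GT calls at ", sum(apply(miss, 2L, any)),
           " SNP(s); re-read with impute_mean = TRUE to mean-impute dosages")
    dosage <- hap1 + hap2
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2L]]
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_data(samples, variants, hap1, hap2, phased = phased,
                dosage = dosage)
}

#' Subset a genotype container to a set of SNP columns
#' @param gd A `genotype_data` object.
#' @param keep Integer or logical index of SNPs to retain (order preserved).
#' @return A `genotype_data` object.
#' @export
subset_snps <- function(gd, keep) {
  genotype_data(gd$sample_ids, gd$variants[keep, , drop = FALSE],
                gd$hap1[, keep, drop = FALSE], gd$hap2[, keep, drop = FALSE],
                phased = gd$phased[keep],
                dosage = gd$dosage[, keep, drop = FALSE])
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency min(p, 1-p) is greater than or
#' equal to `threshold`; a SNP exactly at the threshold is kept.
#'
#' @param gd A `genotype_data` object.
#' @param threshold MAF threshold in \[0, 0.5).
#' @return A filtered `genotype_data` (SNP order preserved).
#' @export
filter_by_maf <- function(gd, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 0.5)
  maf <- pmin(gd$alt_freq, 1 - gd$alt_freq)
  keep <- maf >= threshold
  if (!any(keep)) stop("MAF filter at ", threshold, " removed all SNPs")
  if (all(keep)) return(gd)
  subset_snps(gd, keep)
}

#' Write a genotype container to a VCF file
#'
#' Plain-text VCFv4.2 with one GT FORMAT field; phased SNPs use `|`,
#' unphased ones `/`.  Used by the synthetic-data fixture writer; inverse of
#' [read_genotypes()] for complete data.
#'
#' @param gd A `genotype_data` object without missing calls.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gd, path) {
  if (any(!gd$complete)) stop("cannot write VCF with missing calls")
  n <- n_samples(gd)
  m <- n_snps(gd)
  sep <- ifelse(gd$phased, "|", "/")
  lines <- character(m)
  for (k in seq_len(m)) {
    gt <- paste0(gd$hap1[, k], sep[k], gd$hap2[, k])
    v <- gd$variants[k, ]
    lines[k] <- paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                        "GT", gt), collapse = "\t")
  }
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(gd$variants$chrom), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gd$sample_ids), collapse = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}
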