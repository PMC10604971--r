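#' Haplotype block definitions
#'
#' A block is a run of consecutive SNPs on one chromosome, treated downstream
#' as a multiallelic locus whose alleles are the observed phased haplotypes.
#' Three blocking schemes are provided: a fixed number of SNPs per block
#' ([blocks_by_count()]), fixed-width genomic windows ([blocks_by_window()]),
#' and gene/region-based blocks from a BED file ([blocks_from_regions()]).
#'
#' @param blocks Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive SNP indices into the genotype panel) and `label`.
#' @param scheme `"by_count"`, `"by_window"` or `"by_region"`.
#' @param parameter The scheme parameter (SNPs per block, window width in bp,
#'   or the region file path).
#' @return An object of class `block_definition`.
#' @export
block_definition <- function(blocks, scheme, parameter) {
  scheme <- match.arg(scheme, c("by_count", "by_window", "by_region"))
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(blocks)),
            all(blocks$end >= blocks$start))
  # non-overlap: SNP index ranges must be disjoint
  idx <- unlist(Map(seq, blocks$start, blocks$end))
  if (anyDuplicated(idx)) stop("blocks overlap in SNP indices")
  bd <- list(blocks = blocks, scheme = scheme, parameter = parameter)
  class(bd) <- "block_definition"
  bd
}

#' @export
print.block_definition <- function(x, ...) {
  sizes <- x$blocks$end - x$blocks$start + 1L
  cat("<block_definition> ", nrow(x$blocks), " blocks (", x$scheme,
      ", parameter ", format(x$parameter), "), ",
      sum(sizes), " SNPs, block sizes ", min(sizes), "-", max(sizes),
      "\n", sep = "")
  invisible(x)
}

#' @param gd A [genotype_data()].
#' @param k SNPs per block (>= 2); a trailing run shorter than `k` on a
#'   chromosome is kept as a smaller block.
#' @rdname block_definition
#' @export
blocks_by_count <- function(gd, k) {
  stopifnot(k >= 2)
  out <- list()
  for (ch in unique(gd$variants$chrom)) {
    idx <- which(gd$variants$chrom == ch)
    starts <- seq(1L, length(idx), by = k)
    for (s in starts) {
      e <- min(s + k - 1L, length(idx))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = idx[s], end = idx[e],
        label = paste0(ch, "_blk", length(out) + 1L))
    }
  }
  block_definition(do.call(rbind, out), "by_count", k)
}

#' @param width Window width in bp; windows are anchored at position 1 of
#'   each chromosome (window j covers positions (j-1)*width+1 .. j*width),
#'   so block boundaries do not depend on which SNPs are in the panel.
#'   Empty windows are dropped.
#' @rdname block_definition
#' @export
blocks_by_window <- function(gd, width) {
  stopifnot(width >= 1)
  out <- list()
  for (ch in unique(gd$variants$chrom)) {
    idx <- which(gd$variants$chrom == ch)
    win <- (gd$variants$pos[idx] - 1L) %/% width
    for (w in unique(win)) {
      sub <- idx[win == w]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sub), end = max(sub),
        label = paste0(ch, "_win", w + 1L))
    }
  }
  block_definition(do.call(rbind, out), "by_window", width)
}

#' @param bed_path BED file of regions (0-based half-open; converted to
#'   1-based closed on read).  Overlapping regions are merged.  Regions with
#'   fewer than two panel SNPs are dropped; SNPs outside every region are
#'   excluded from the haplotype component (they remain available to the
#'   SNP-level matrices).
#' @rdname block_definition
#' @export
blocks_from_regions <- function(gd, bed_path) {
  regions <- rtracklayer::import(bed_path, format = "BED")
  regions <- GenomicRanges::reduce(regions)
  snps <- GenomicRanges::GRanges(
    gd$variants$chrom,
    IRanges::IRanges(gd$variants$pos, gd$variants$pos))
  hit <- GenomicRanges::findOverlaps(snps, regions)
  out <- list()
  for (r in unique(S4Vectors::subjectHits(hit))) {
    idx <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == r]
    if (length(idx) < 2L) next
    ch <- unique(gd$variants$chrom[idx])
    if (length(ch) != 1L) stop("region ", r, " spans chromosomes")
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = min(idx), end = max(idx),
      label = paste0("region", r))
  }
  if (!length(out))
    stop("no region contains >= 2 panel SNPs; zero usable haplotype blocks")
  block_definition(do.call(rbind, out), "by_region", bed_path)
}

#' Enumerate haplotype alleles per block from phased genotypes
#'
#' Within each block, the distinct phased allele strings observed in the
#' sample become the alleles of one multiallelic locus; each individual
#' contributes its two gametes, so per-individual allele counts sum to 2.
#'
#' @param gd A [genotype_data()]; every SNP inside a block must be phased and
#'   complete.
#' @param bd A [block_definition()].
#' @param min_freq Alleles rarer than this are pooled into one `"rare"`
#'   allele per block (default 0: keep all).
#' @return An object of class `haplotype_allele_table`: list with `counts`
#'   (n x total-alleles matrix), `allele_block` (block label per column),
#'   `allele_seq` (haplotype string per column), `allele_freq`, `sample_ids`.
#' @export
enumerate_haplotypes <- function(gd, bd, min_freq = 0) {
  n <- n_samples(gd)
  count_cols <- list()
  blocks <- list()
  seqs <- list()
  for (b in seq_len(nrow(bd$blocks))) {
    rng <- bd$blocks$start[b]:bd$blocks$end[b]
    lab <- bd$blocks$label[b]
    if (any(!gd$phased[rng]) || any(!gd$complete[rng]))
      stop("block '", lab, "' contains unphased or incomplete SNP(s); ",
           "haplotype alleles are undefined there")
    h1 <- apply(gd$hap1[, rng, drop = FALSE], 1L, paste, collapse = "")
    h2 <- apply(gd$hap2[, rng, drop = FALSE], 1L, paste, collapse = "")
    alleles <- sort(unique(c(h1, h2)))
    cnt <- matrix(0, n, length(alleles), dimnames = list(NULL, alleles))
    cnt[cbind(seq_len(n), match(h1, alleles))] <-
      cnt[cbind(seq_len(n), match(h1, alleles))] + 1
    cnt[cbind(seq_len(n), match(h2, alleles))] <-
      cnt[cbind(seq_len(n), match(h2, alleles))] + 1
    freq <- colSums(cnt) / (2 * n)
    if (min_freq > 0 && any(freq < min_freq) && sum(freq < min_freq) > 1L) {
      rare <- freq < min_freq
      pooled <- rowSums(cnt[, rare, drop = FALSE])
      cnt <- cbind(cnt[, !rare, drop = FALSE], rare = pooled)
      alleles <- c(alleles[!rare], "rare")
      freq <- colSums(cnt) / (2 * n)
    }
    count_cols[[b]] <- cnt
    blocks[[b]] <- rep(lab, length(alleles))
    seqs[[b]] <- alleles
  }
  hat <- list(counts = do.call(cbind, count_cols),
              allele_block = unlist(blocks), allele_seq = unlist(seqs),
              allele_freq = colSums(do.call(cbind, count_cols)) / (2 * n),
              sample_ids = gd$sample_ids)
  class(hat) <- "haplotype_allele_table"
  hat
}

#' @export
print.haplotype_allele_table <- function(x, ...) {
  cat("<haplotype_allele_table> ", length(x$sample_ids), " individuals, ",
      length(unique(x$allele_block)), " blocks, ",
      ncol(x$counts), " alleles\n", sep = "")
  invisible(x)
}

#' Haplotype additive relationship matrix
#'
#' Each observed haplotype allele contributes one count column (0/1/2);
#' columns are centered on their sample means and the Gram matrix over all
#' blocks' alleles is scaled to mean diagonal 1.  Centering makes the result
#' invariant to dropping one reference allele per block, so all alleles are
#' kept.
#'
#' @param hat A [enumerate_haplotypes()] table.
#' @return A `grm` labelled `"H"` with `method = "haplotype"`.
#' @export
grm_haplotype <- function(hat) {
  Z <- scale(hat$counts, center = TRUE, scale = FALSE)
  if (max(abs(Z)) == 0)
    stop("all individuals carry identical haplotypes; zero relationship matrix")
  raw <- tcrossprod(Z)
  normalize_grm(grm("H", raw, hat$sample_ids, NA_real_, "haplotype"))
}
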