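two_chrom_gd <- function(n = 10, m1 = 12, m2 = 13, seed = 1) {
  withr::with_seed(seed, {
    m <- m1 + m2
    hap1 <- matrix(rbinom(n * m, 1, 0.5), n, m)
    hap2 <- matrix(rbinom(n * m, 1, 0.5), n, m)
    variants <- data.frame(
      chrom = rep(c("chr1", "chr2"), c(m1, m2)),
      pos = c(seq_len(m1), seq_len(m2)) * 1000L,
      id = paste0("s", seq_len(m)), ref = "A", alt = "G")
    genotype_data(paste0("i", seq_len(n)), variants, hap1, hap2)
  })
}

test_that("count-based blocks partition each chromosome in runs of k", {
  gd <- two_chrom_gd(m1 = 25, m2 = 12)
  bd <- blocks_by_count(gd, 12)
  sizes <- bd$blocks$end - bd$blocks$start + 1L
  expect_equal(sizes, c(12L, 12L, 1L, 12L)) # 25 = 12 + 12 + 1, then chr2
  expect_equal(unique(bd$blocks$chrom), c("chr1", "chr2"))
  # partition: every SNP in exactly one block
  covered <- unlist(Map(seq, bd$blocks$start, bd$blocks$end))
  expect_equal(sort(covered), seq_len(n_snps(gd)))
})

test_that("window blocks follow fixed windows anchored at position 1", {
  gd <- genotype_data(
    paste0("i", 1:4),
    data.frame(chrom = "chr1", pos = c(10000L, 50000L, 60000L),
               id = c("a", "b", "c"), ref = "A", alt = "G"),
    matrix(rbinom(12, 1, 0.5), 4, 3), matrix(rbinom(12, 1, 0.5), 4, 3))
  bd <- blocks_by_window(gd, 50000)
  # position 50000 belongs to window 1, position 60000 starts window 2
  expect_equal(nrow(bd$blocks), 2L)
  expect_equal(bd$blocks$start, c(1L, 3L))
  expect_equal(bd$blocks$end, c(2L, 3L))

  gd2 <- two_chrom_gd(m1 = 20, m2 = 0)
  expect_equal(nrow(blocks_by_window(gd2, 1e6)$blocks), 1L)
  # window index formula on random positions
  gd3 <- make_gd(n = 4, m = 30, seed = 9)
  gd3$variants$pos <- sort(sample.int(10000, 30))
  gd3 <- genotype_data(gd3$sample_ids, gd3$variants, gd3$hap1, gd3$hap2)
  bd3 <- blocks_by_window(gd3, 1000)
  win_of <- (gd3$variants$pos - 1L) %/% 1000L
  expect_equal(nrow(bd3$blocks), length(unique(win_of)))
})

test_that("region blocks merge overlaps and match a brute-force scan", {
  gd <- two_chrom_gd(m1 = 20, m2 = 10, seed = 3)
  bed <- withr::local_tempfile(fileext = ".bed")
  # two overlapping regions on chr1 (merge to 2500-8700) + one on chr2
  writeLines(c("chr1\t2500\t6000\tgeneA", "chr1\t5500\t8700\tgeneB",
               "chr2\t1500\t4200\tgeneC"), bed)
  bd <- blocks_from_regions(gd, bed)
  expect_equal(nrow(bd$blocks), 2L)
  # brute-force interval scan (BED is 0-based half-open)
  regions <- list(c("chr1", 2501, 8700), c("chr2", 1501, 4200))
  for (b in seq_len(nrow(bd$blocks))) {
    idx <- bd$blocks$start[b]:bd$blocks$end[b]
    r <- regions[[b]]
    inside <- which(gd$variants$chrom == r[1] &
                      gd$variants$pos >= as.numeric(r[2]) &
                      gd$variants$pos <= as.numeric(r[3]))
    expect_equal(idx, inside)
  }
  # regions with < 2 SNPs yield no block; zero usable blocks is an error
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t500\tempty", bed2)
  expect_error(blocks_from_regions(gd, bed2), "zero usable")
})

test_that("haplotype alleles are enumerated with per-individual counts", {
  # 2-SNP block over 3 individuals: haplotypes 00, 01, 11 observed
  hap1 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  hap2 <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 0L))
  gd <- genotype_data(paste0("i", 1:3),
                      data.frame(chrom = "chr1", pos = c(100L, 200L),
                                 id = c("a", "b"), ref = "A", alt = "G"),
                      hap1, hap2)
  bd <- blocks_by_count(gd, 2)
  hat <- enumerate_haplotypes(gd, bd)
  expect_equal(sort(hat$allele_seq), c("00", "01", "11"))
  expect_equal(unname(rowSums(hat$counts)), rep(2, 3))
  # individual 2 is 01|01: count 2 for allele "01"
  expect_equal(unname(hat$counts[2, hat$allele_seq == "01"]), 2)
  expect_equal(sum(hat$allele_freq), 1)

  # unphased SNP inside a block is an error naming the block
  gd$phased[1] <- FALSE
  expect_error(enumerate_haplotypes(gd, bd), "unphased")
})

test_that("enumerated alleles are a subset of the founder pool", {
  cfg <- sim_config(n = 60, n_blocks = 4, snps_per_block = 6,
                    n_founders = 8, switch_rate = 0, n_families = 0,
                    maf_min = 0, seed = 33)
  gd <- simulate_genotypes(cfg)
  bd <- blocks_by_window(gd, 1e6)
  hat <- enumerate_haplotypes(gd, bd)
  per_block <- table(hat$allele_block)
  expect_true(all(per_block <= 8)) # switch rate 0: gametes are founders
})

test_that("haplotype GRM reduces to the SNP GRM for biallelic blocks", {
  gd <- make_gd(n = 40, m = 2, seed = 10)
  bd <- blocks_by_count(gd, 2)
  # force a biallelic block: haplotype determined by first SNP
  gd$hap1[, 2] <- gd$hap1[, 1]; gd$hap2[, 2] <- gd$hap2[, 1]
  gd <- genotype_data(gd$sample_ids, gd$variants, gd$hap1, gd$hap2)
  hat <- enumerate_haplotypes(gd, bd)
  gH <- grm_haplotype(hat)
  gA <- grm_first_order(center_additive(subset_snps(gd, 1)))
  off <- upper.tri(gH$matrix)
  expect_gt(cor(gH$matrix[off], gA$matrix[off]), 0.999)

  # identical haplotypes for everyone: zero matrix
  hap <- matrix(1L, 5, 2)
  gd2 <- genotype_data(paste0("i", 1:5),
                       data.frame(chrom = "chr1", pos = c(1L, 2L),
                                  id = c("a", "b"), ref = "A", alt = "G"),
                       hap, hap)
  expect_error(grm_haplotype(enumerate_haplotypes(gd2, blocks_by_count(gd2, 2))),
               "identical haplotypes")
})

test_that("single-SNP blocks reproduce the additive GRM up to scale", {
  gd <- make_gd(n = 30, m = 5, seed = 12)
  bd <- block_definition(
    data.frame(chrom = "chr1", start = 1:5, end = 1:5,
               label = paste0("b", 1:5)), "by_region", "manual")
  hat <- enumerate_haplotypes(gd, bd)
  gH <- grm_haplotype(hat)
  gA <- grm_first_order(center_additive(gd))
  off <- upper.tri(gH$matrix)
  expect_gt(cor(gH$matrix[off], gA$matrix[off]), 0.999)
})

test_that("haplotype GRM is invariant to allele labeling order", {
  gd <- make_gd(n = 25, m = 6, seed = 14)
  bd <- blocks_by_count(gd, 3)
  hat <- enumerate_haplotypes(gd, bd)
  perm <- withr::with_seed(1, sample(ncol(hat$counts)))
  hat2 <- hat
  hat2$counts <- hat$counts[, perm]
  hat2$allele_block <- hat$allele_block[perm]
  hat2$allele_seq <- hat$allele_seq[perm]
  expect_equal(grm_haplotype(hat2)$matrix, grm_haplotype(hat)$matrix)
})
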