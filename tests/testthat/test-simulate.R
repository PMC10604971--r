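small_cfg <- function(...) {
  sim_config(n = 80, n_blocks = 6, snps_per_block = 8, n_families = 8,
             seed = 5, ...)
}

test_that("the generator is a pure function of its configuration", {
  cfg <- small_cfg()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$gd$hap1, d2$gd$hap1)
  expect_identical(d1$pt$y, d2$pt$y)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture(d1$gd, d1$pt, d1$truth, dir1)
  write_fixture(d2$gd, d2$pt, d2$truth, dir2)
  expect_identical(readLines(file.path(dir1, "genotypes.vcf")),
                   readLines(file.path(dir2, "genotypes.vcf")))
  d3 <- simulate_dataset(sim_config(n = 80, n_blocks = 6, snps_per_block = 8,
                                    n_families = 8, seed = 6))
  expect_false(identical(d1$pt$y, d3$pt$y))
})

test_that("zero switch rate copies founder haplotypes verbatim", {
  cfg <- sim_config(n = 50, n_blocks = 3, snps_per_block = 6, n_founders = 4,
                    switch_rate = 0, n_families = 0, maf_min = 0, seed = 2)
  gd <- simulate_genotypes(cfg)
  blk <- sim_block_index(gd)
  for (b in unique(blk)) {
    gametes <- rbind(gd$hap1[, blk == b], gd$hap2[, blk == b])
    expect_lte(nrow(unique(gametes)), 4)
  }
})

test_that("MAF-filtered SNPs are dropped and recorded", {
  cfg <- sim_config(n = 200, n_blocks = 5, snps_per_block = 10,
                    n_families = 0, maf_min = 0.2, seed = 3)
  gd <- simulate_genotypes(cfg)
  maf <- pmin(gd$alt_freq, 1 - gd$alt_freq)
  expect_true(all(maf >= 0.2))
  expect_equal(n_snps(gd) + attr(gd, "n_dropped_maf"), 50L)
})

test_that("unrelated cohorts are in Hardy-Weinberg proportions", {
  cfg <- sim_config(n = 1500, n_blocks = 8, snps_per_block = 10,
                    n_families = 0, seed = 7)
  gd <- simulate_genotypes(cfg)
  pvals <- vapply(seq_len(n_snps(gd)), function(k) {
    x <- gd$dosage[, k]
    p <- mean(x) / 2
    obs <- tabulate(x + 1, 3)
    expected <- 1500 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    suppressWarnings(chisq.test(obs, p = expected / sum(expected))$p.value)
  }, 0)
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("LD is concentrated within blocks", {
  cfg <- sim_config(n = 800, n_blocks = 6, snps_per_block = 10,
                    n_families = 0, seed = 9)
  gd <- simulate_genotypes(cfg)
  blk <- sim_block_index(gd)
  r2 <- cor(gd$dosage)^2
  within <- outer(blk, blk, "==") & upper.tri(r2)
  between <- !outer(blk, blk, "==") & upper.tri(r2)
  expect_gt(mean(r2[within]), 5 * mean(r2[between]))
})

test_that("family cohorts contain the expected relationship classes", {
  cfg <- sim_config(n = 400, n_blocks = 10, snps_per_block = 10, seed = 12)
  gd <- simulate_genotypes(cfg)
  gA <- grm_first_order(center_additive(gd))$matrix
  fam <- attr(gd, "family")
  role <- attr(gd, "role")
  # full sibs (the two gen-1 parents) cluster near 1/2
  sibs <- which(role == "p1" | role == "p2")
  fs_pairs <- outer(fam[sibs], fam[sibs], "==") & upper.tri(diag(length(sibs)))
  expect_equal(mean(gA[sibs, sibs][fs_pairs]), 0.5, tolerance = 0.1)
  # unrelated pairs (different families) center at ~0
  other <- outer(fam, fam, "!=")
  expect_lt(abs(mean(gA[other])), 0.05)
})

test_that("component variances match the configured fractions", {
  cfg <- sim_config(n = 600, n_blocks = 20, snps_per_block = 10, seed = 15,
                    var_frac = c(A = 0.3, D = 0.1, AA = 0.2))
  d <- simulate_dataset(cfg)
  expect_equal(unname(apply(d$truth$genetic_values, 2, var)),
               c(0.3, 0.1, 0.2), tolerance = 1e-10)
  expect_equal(unname(d$truth$realized_frac), c(0.3, 0.1, 0.2),
               tolerance = 1e-10)
})

test_that("residual-free and noise-only phenotypes behave as configured", {
  cfg0 <- sim_config(n = 150, n_blocks = 5, snps_per_block = 8, seed = 16,
                     var_frac = c(A = 0.999999), sex_effect = 0,
                     age_coef = 0)
  d0 <- simulate_dataset(cfg0)
  g <- rowSums(d0$truth$genetic_values)
  expect_gt(cor(d0$pt$y, g), 0.999)

  cfg1 <- sim_config(n = 500, n_blocks = 5, snps_per_block = 8, seed = 17,
                     var_frac = c(A = 1e-9))
  d1 <- simulate_dataset(cfg1)
  expect_lt(abs(cor(d1$pt$y - 0.01 * d1$pt$covars$age,
                    rowSums(d1$truth$genetic_values))), 0.15)
})

test_that("fixtures round-trip through the standard file formats", {
  cfg <- small_cfg()
  d <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(d$gd, d$pt, d$truth, dir)
  gd2 <- read_genotypes(paths[["vcf"]])
  expect_identical(gd2$hap1, unname(d$gd$hap1))
  expect_equal(gd2$sample_ids, d$gd$sample_ids)
  pt2 <- read_phenotypes(paths[["tsv"]], "trait", "sex", "age", gd = gd2)
  expect_equal(pt2$y, d$pt$y, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["json"]])
  expect_equal(sum(unlist(truth$var_frac)) + truth$residual, 1)
  bd <- blocks_from_regions(gd2, paths[["bed"]])
  expect_equal(nrow(bd$blocks), length(unique(sim_block_index(d$gd))))
})

test_that("local epistatic tuples stay within their blocks", {
  cfg <- sim_config(n = 100, n_blocks = 6, snps_per_block = 8, seed = 19,
                    var_frac = c(A = 0.2, LOCAL = 0.3), local_order = 3)
  d <- simulate_dataset(cfg)
  blk <- sim_block_index(d$gd)
  loci <- d$truth$causal$LOCAL$loci
  expect_equal(ncol(loci), 3L)
  for (r in seq_len(nrow(loci)))
    expect_length(unique(blk[loci[r, ]]), 1L)
})
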