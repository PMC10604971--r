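test_that("additive and dominance codes are centered per-locus codes", {
  gts1 <- rbind(c("0|0", "0|1", "1|1"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, gts1)
  gd <- read_genotypes(path)
  W <- center_additive(gd)
  expect_equal(drop(W$values), c(-1, 0, 1), ignore_attr = TRUE)
  H <- center_dominance(gd)
  expect_equal(drop(H$values), c(-1, 2, -1) / 3, ignore_attr = TRUE)

  # monomorphic SNP gives an all-zero column
  gd2 <- genotype_data("i1", data.frame(chrom = "chr1", pos = 1L, id = "s",
                                        ref = "A", alt = "G"),
                       matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(drop(center_additive(gd2)$values), 0, ignore_attr = TRUE)

  gd3 <- make_gd(n = 50, m = 20, seed = 5)
  expect_lt(max(abs(colMeans(center_additive(gd3)$values))), 1e-9)
  expect_lt(max(abs(colMeans(center_dominance(gd3)$values))), 1e-9)
})

test_that("heterozygosity frequency approaches 2pq under HWE", {
  gd <- make_gd(n = 4000, m = 30, seed = 11)
  het <- colMeans(gd$dosage == 1)
  p <- gd$alt_freq
  expect_lt(max(abs(het - 2 * p * (1 - p))), 0.05)
})

test_that("first-order GRM is the normalized Gram matrix of the codes", {
  n <- 3
  W <- code_matrix("additive",
                   scale(matrix(c(0, 1, 2, 2, 0, 1), n, 2), scale = FALSE),
                   c("s1", "s2"))
  g <- grm_first_order(W)
  raw <- tcrossprod(W$values)
  expect_equal(unname(g$matrix), raw / mean(diag(raw)), tolerance = 1e-12)
  expect_equal(g$normalizer, mean(diag(raw)))
  expect_equal(mean(diag(g$matrix)), 1)

  # identical individuals have identical GRM rows
  gd <- make_gd(n = 6, m = 8, seed = 2)
  gd$hap1[2, ] <- gd$hap1[1, ]; gd$hap2[2, ] <- gd$hap2[1, ]
  gd <- genotype_data(gd$sample_ids, gd$variants, gd$hap1, gd$hap2)
  g2 <- grm_first_order(center_additive(gd))
  expect_equal(unname(g2$matrix[1, ]), unname(g2$matrix[2, ]))

  g3 <- grm_first_order(center_additive(make_gd(n = 15, m = 25, seed = 3)))
  expect_no_error(check_psd(g3))
  expect_error(grm_first_order(code_matrix("additive",
                                           matrix(0, 3, 2), c("a", "b"))),
               "zero relationship")
})

test_that("normalize_grm scales to mean diagonal one and records it", {
  g <- grm("A", diag(3), paste0("i", 1:3), NA_real_, "first_order")
  gn <- normalize_grm(g)
  expect_equal(gn$matrix, g$matrix)
  expect_equal(gn$normalizer, 1)
  g2 <- normalize_grm(grm("A", 2 * diag(3), paste0("i", 1:3), NA_real_,
                          "first_order"))
  expect_equal(unname(g2$matrix), diag(3))
  expect_equal(g2$normalizer, 2)
  expect_error(normalize_grm(grm("A", matrix(0, 2, 2), c("a", "b"),
                                 NA_real_, "first_order")),
               "zero relationship")
})

test_that("Hadamard epistasis GRMs are elementwise products, renormalized", {
  cm <- make_codes(n = 8, m = 10, seed = 4)
  gA <- grm_first_order(cm$W)
  gD <- grm_first_order(cm$H)
  et <- effect_type("AD")
  g <- grm_epistasis_hadamard(et, gA, gD)
  raw <- gA$matrix * gD$matrix
  expect_equal(g$matrix, raw / mean(diag(raw)), tolerance = 1e-12)
  expect_no_error(check_psd(g)) # Schur product of PSDs is PSD
  gAA <- grm_epistasis_hadamard(effect_type("AA"), grm_A = gA)
  expect_equal(diag(gAA$matrix), diag(gA$matrix)^2 / mean(diag(gA$matrix)^2))
  expect_error(grm_epistasis_hadamard(effect_type("A"), gA, gD), "order")
})

test_that("exact epistasis equals the brute-force tuple enumeration", {
  for (seed in 1:5) {
    cm <- make_codes(n = 6, m = 5, seed = seed)
    for (et in effect_type_catalog(4)) {
      if (et$order < 2L) next
      ex <- grm_epistasis_exact(et, cm$W, cm$H)
      bf <- grm_epistasis_bruteforce(et, cm$W, cm$H)
      expect_lt(norm(ex$matrix - bf$matrix, "F") / norm(bf$matrix, "F"),
                1e-10)
    }
  }
})

test_that("exact method removes intra-locus terms that Hadamard keeps", {
  # one locus: no distinct pair exists, so the exact A x A matrix is zero
  W1 <- code_matrix("additive", matrix(c(-1, 0, 1), 3, 1), "s1")
  expect_warning(z <- grm_epistasis_exact(effect_type("AA"), W1),
                 "no distinct locus tuple")
  expect_equal(max(abs(z$matrix)), 0)
  # ... while the Hadamard approximation is not zero
  gA1 <- grm_first_order(W1)
  h1 <- grm_epistasis_hadamard(effect_type("AA"), grm_A = gA1)
  expect_gt(max(abs(h1$matrix)), 0)

  # algebraic identity at order 2:
  # exact AA  =  (WW')^2/2 - (W*W)(W*W)'/2, renormalized
  cm <- make_codes(n = 7, m = 6, seed = 9)
  Wv <- cm$W$values
  raw <- (tcrossprod(Wv)^2 - tcrossprod(Wv^2)) / 2
  ex <- grm_epistasis_exact(effect_type("AA"), cm$W)
  expect_equal(unname(ex$matrix), unname(raw / mean(diag(raw))), tolerance = 1e-10)
})

test_that("approximate and exact A x A converge as loci accumulate", {
  rel_diff <- function(m) {
    gd <- make_gd(n = 15, m = m, seed = 21)
    W <- center_additive(gd)
    gA <- grm_first_order(W)
    h <- grm_epistasis_hadamard(effect_type("AA"), grm_A = gA)
    e <- grm_epistasis_exact(effect_type("AA"), W)
    norm(h$matrix - e$matrix, "F") / norm(e$matrix, "F")
  }
  expect_lt(rel_diff(400), rel_diff(10))
})

test_that("brute-force oracle enumerates role assignments over distinct loci", {
  cm <- make_codes(n = 5, m = 3, seed = 6)
  # A x A over m = 3 has 3 pair columns; A x D over m = 2 has 2 columns
  bf <- grm_epistasis_bruteforce(effect_type("AA"), cm$W, cm$H)
  raw <- tcrossprod(cbind(cm$W$values[, 1] * cm$W$values[, 2],
                          cm$W$values[, 1] * cm$W$values[, 3],
                          cm$W$values[, 2] * cm$W$values[, 3]))
  expect_equal(unname(bf$matrix), unname(raw / mean(diag(raw))), tolerance = 1e-12)
  cm2 <- make_codes(n = 5, m = 2, seed = 8)
  bf2 <- grm_epistasis_bruteforce(effect_type("AD"), cm2$W, cm2$H)
  raw2 <- tcrossprod(cbind(cm2$W$values[, 1] * cm2$H$values[, 2],
                           cm2$W$values[, 2] * cm2$H$values[, 1]))
  expect_equal(unname(bf2$matrix), unname(raw2 / mean(diag(raw2))), tolerance = 1e-12)
  expect_no_error(check_psd(
    grm_epistasis_bruteforce(effect_type("AAD"), cm$W, cm$H)))
})
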