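# small in-code fixtures shared across tests

# random biallelic genotype panel in HWE, one chromosome, no families
make_gd <- function(n = 20, m = 10, seed = 1, maf_range = c(0.2, 0.8)) {
  withr::with_seed(seed, {
    p <- runif(m, maf_range[1], maf_range[2])
    hap1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
    hap2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
    variants <- data.frame(chrom = "chr1", pos = seq_len(m) * 100L,
                           id = paste0("s", seq_len(m)),
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
    genotype_data(paste0("i", seq_len(n)), variants, hap1, hap2)
  })
}

# centered code matrices with arbitrary continuous entries (for GRM algebra)
make_codes <- function(n = 8, m = 6, seed = 1) {
  withr::with_seed(seed, {
    W <- scale(matrix(rnorm(n * m), n, m), scale = FALSE)
    H <- scale(matrix(rnorm(n * m), n, m), scale = FALSE)
    rownames(W) <- rownames(H) <- paste0("i", seq_len(n))
    list(W = code_matrix("additive", W, paste0("s", seq_len(m))),
         H = code_matrix("dominance", H, paste0("s", seq_len(m))))
  })
}

# write a small VCF text file; gts is an m x n character matrix like "0|1"
write_test_vcf <- function(path, gts, chrom = "chr1",
                           pos = seq_len(nrow(gts)) * 100L,
                           alt = rep("G", nrow(gts))) {
  n <- ncol(gts)
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(chrom), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("i", seq_len(n))),
                    collapse = "\t"))
  rows <- vapply(seq_len(nrow(gts)), function(k)
    paste(c(chrom, pos[k], paste0("s", k), "A", alt[k], ".", "PASS", ".",
            "GT", gts[k, ]), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  path
}

# restricted log-likelihood via an explicit error-contrast projection —
# independent of the V-inverse formulation in the package
reml_loglik_contrast <- function(theta, y, X, S_list) {
  n <- length(y)
  f <- length(S_list)
  V <- diag(theta[f + 1], n)
  for (i in seq_len(f)) {
    M <- if (inherits(S_list[[i]], "grm")) S_list[[i]]$matrix else S_list[[i]]
    V <- V + theta[i] * M
  }
  K <- qr.Q(qr(X), complete = TRUE)[, (ncol(X) + 1):n, drop = FALSE]
  KVK <- crossprod(K, V %*% K)
  qf <- crossprod(K, y)
  -0.5 * (as.numeric(determinant(KVK)$modulus) +
            drop(t(qf) %*% solve(KVK, qf)))
}
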