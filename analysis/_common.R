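# Shared configuration of the analysis workflow.  Each numbered script
# sources this file; all computation lives in the epigblup package.
suppressMessages({
  if (!requireNamespace("epigblup", quietly = TRUE)) {
    # allow running from a source checkout without installation
    devtools::load_all(file.path(dirname(sub("--file=", "", grep("--file=",
      commandArgs(FALSE), value = TRUE)[1])), ".."), quiet = TRUE)
  } else library(epigblup)
})

RESULTS <- file.path("results")
COHORT_DIR <- file.path(RESULTS, "cohort")
GRM_DIR <- file.path(RESULTS, "grm")
TABLE_DIR <- file.path(RESULTS, "tables")
for (d in c(RESULTS, COHORT_DIR, GRM_DIR, TABLE_DIR))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)

SEED <- 20260926L
CV_SEED <- 17L

# Study cohort: a three-generation family study of 600 individuals on an
# LD-blocked panel of 30 blocks x 10 SNPs (16 founder haplotypes per block),
# with additive, dominance, global pairwise-epistatic and block-local
# three-locus genetic signal.  Sizes chosen so the whole workflow runs in a
# few minutes on a laptop.
cohort_config <- function() {
  sim_config(n = 600L, n_blocks = 30L, snps_per_block = 10L,
             n_founders = 16L,
             var_frac = c(A = 0.25, D = 0.05, AA = 0.15, LOCAL = 0.15),
             local_order = 3L, local_tuples_per_block = 3L,
             seed = SEED)
}

FIXTURE <- c(vcf = file.path(COHORT_DIR, "genotypes.vcf"),
             tsv = file.path(COHORT_DIR, "phenotypes.tsv"),
             bed = file.path(COHORT_DIR, "blocks.bed"),
             json = file.path(COHORT_DIR, "truth.json"))

load_cohort <- function() {
  gd <- read_genotypes(FIXTURE[["vcf"]])
  gd <- filter_by_maf(gd, 0.05)
  pt <- read_phenotypes(FIXTURE[["tsv"]], trait = "trait",
                        class_vars = "sex", covars = "age", gd = gd)
  list(gd = gd, pt = pt, X = build_design_matrix(pt)$X)
}
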