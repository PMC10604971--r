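#' Configuration of the synthetic genotype/phenotype generator
#'
#' The generator emulates the data shape the analysis assumes: a cohort of
#' unrelated diploid individuals genotyped on an LD-blocked biallelic SNP
#' panel (MAF >= 0.05), with one phenotype record per individual composed of
#' fixed effects (one two-level classification variable and one covariable),
#' additive, dominance, global epistatic and block-local high-order genetic
#' values, and a Gaussian residual.  Genotypes are founder-haplotype mosaics:
#' within each block every gamete copies one of a small pool of founder
#' haplotypes, switching founders between adjacent SNPs at `switch_rate`, so
#' within-block LD is strong, between-block LD is absent, and block alleles
#' are enumerable.  Gametes pair at random, so genotypes are in
#' Hardy-Weinberg proportions.
#'
#' By default the cohort is a multi-generation family study, as human cohort
#' studies with deep phenotyping typically are.  Each family unit spans three
#' generations: a founder couple, two of their children married to unrelated
#' spouses, and grandchildren from both couples; everyone is in the cohort,
#' so it contains parent-offspring, full-sib, grandparent-grandchild,
#' avuncular and first-cousin pairs alongside unrelated ones.  This matters
#' for estimation: the expected relationship of a pair under an epistatic
#' effect type is the corresponding power/product of its additive and
#' dominance relationships (full sibs: A = 1/2, D = 1/4, AxA = 1/4,
#' fourth-order = 1/16; parent-offspring: A = 1/2, D = 0; grandparent or
#' avuncular: A = 1/4; first cousins: A = 1/8), and only a cohort offering
#' several distinct relationship levels makes the higher-order variance
#' components separable from each other and from the residual at cohort
#' sizes of a few thousand.  A cohort of nominally unrelated individuals
#' (`n_families = 0`) leaves them essentially unidentifiable: every epistatic
#' relationship matrix then collapses towards a linear combination of the
#' lower-order ones and the identity.
#'
#' @param n Individuals (default 1000).
#' @param n_blocks Haplotype blocks (default 100).
#' @param snps_per_block SNPs per block (default 20).
#' @param n_founders Founder haplotypes per block (default 8).
#' @param switch_rate Per-SNP probability that a gamete's mosaic switches
#'   founder (default 0.05).
#' @param maf_min SNPs below this MAF in the generated cohort are dropped and
#'   recorded (default 0.05, the panel's inclusion rule).
#' @param n_families Number of three-generation family units (founder couple,
#'   two of their children with unrelated spouses, plus grandchildren);
#'   individuals are assigned to units as evenly as possible.  0 generates an
#'   unrelated cohort of mosaic individuals.  Default `round(n / 10)` (units
#'   of ~10: 6 adults, ~4 grandchildren).
#' @param crossover_rate Per-SNP probability of a within-block crossover
#'   during meiosis (default 0.001; blocks recombine freely).
#' @param var_frac Named fractions of phenotypic variance per genetic effect
#'   type; names are effect-type labels (`"A"`, `"D"`, `"AA"`, ...) plus
#'   optionally `"LOCAL"` for within-block high-order interactions.  The
#'   residual fraction is 1 - sum(var_frac) and must be positive.  Default
#'   `c(A = 0.3, D = 0.1, AA = 0.2)` (residual 0.4).
#' @param n_causal Named counts of causal loci (first-order types) or locus
#'   tuples (epistasis types); defaults: 1500 for `A`, 800 for `D`, 30000
#'   tuples for each epistasis type present (capped by availability).  Dense
#'   on purpose: complex phenotypes are polygenic, and dense architectures
#'   make each component's realized covariance match its relationship matrix.
#' @param local_order Number of interacting loci of the block-local term
#'   (default 3).
#' @param local_tuples_per_block Causal within-block tuples per block for the
#'   `LOCAL` term (default 2).
#' @param sex_effect Fixed effect of the second level of the classification
#'   variable, in phenotype SD units (default 0.3).
#' @param age_coef Covariable regression coefficient (default 0.01 per year;
#'   ages are drawn uniformly from 30-70).
#' @param intercept Model intercept (default 10).
#' @param seed Integer seed; every generated object is a pure function of
#'   the configuration including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 1000L, n_blocks = 100L, snps_per_block = 20L,
                       n_founders = 8L, switch_rate = 0.05, maf_min = 0.05,
                       n_families = round(n / 10), crossover_rate = 0.001,
                       var_frac = c(A = 0.3, D = 0.1, AA = 0.2),
                       n_causal = NULL, local_order = 3L,
                       local_tuples_per_block = 2L,
                       sex_effect = 0.3, age_coef = 0.01, intercept = 10,
                       seed = 1L) {
  stopifnot(n >= 2, n_blocks >= 1, snps_per_block >= 2, n_founders >= 2,
            switch_rate >= 0, switch_rate <= 1,
            n_families >= 0, crossover_rate >= 0, crossover_rate <= 1,
            all(var_frac >= 0), sum(var_frac) < 1,
            local_order >= 2, local_order <= 4)
  if (is.null(names(var_frac)) && length(var_frac))
    stop("var_frac must be named by effect-type label")
  cfg <- list(n = as.integer(n), n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              n_founders = as.integer(n_founders),
              switch_rate = switch_rate, maf_min = maf_min,
              n_families = as.integer(n_families),
              crossover_rate = crossover_rate,
              var_frac = var_frac, residual = 1 - sum(var_frac),
              n_causal = n_causal, local_order = as.integer(local_order),
              local_tuples_per_block = as.integer(local_tuples_per_block),
              sex_effect = sex_effect, age_coef = age_coef,
              intercept = intercept, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default causal counts, capped by availability.  Deliberately dense:
# complex human phenotypes are highly polygenic, and a dense architecture is
# also what makes the realized covariance of each simulated component match
# its relationship matrix (the GREML working model).
.n_causal_for <- function(cfg, label, available) {
  want <- if (!is.null(cfg$n_causal) && !is.null(cfg$n_causal[[label]]))
    cfg$n_causal[[label]]
  else if (label == "A") 1500L else if (label == "D") 800L else 30000L
  as.integer(min(want, available))
}

# block layout: 10 blocks per chromosome, each block inside its own 1 Mb
# window, SNPs every 1 kb
.block_layout <- function(cfg) {
  b <- seq_len(cfg$n_blocks)
  list(chrom = paste0("chr", (b - 1L) %/% 10L + 1L),
       offset = ((b - 1L) %% 10L) * 1e6)
}

#' Simulate phased LD-blocked genotypes
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_data()]; SNPs whose cohort MAF fell below
#'   `cfg$maf_min` are dropped and counted in `attr(, "n_dropped_maf")`.
#'   The SNP-to-block map is recoverable from positions (each block occupies
#'   its own 1 Mb window; see [sim_block_index()]).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n
    spb <- cfg$snps_per_block
    m <- cfg$n_blocks * spb
    lay <- .block_layout(cfg)
    # stage 1: unrelated mosaic individuals (the whole cohort, or the
    # founder couple + two married-in spouses of each family unit)
    n_mosaic <- if (cfg$n_families > 0L) 4L * cfg$n_families else n
    hap1 <- hap2 <- matrix(0L, n_mosaic, m)
    chroms <- character(m)
    pos <- integer(m)
    for (b in seq_len(cfg$n_blocks)) {
      p0 <- stats::runif(spb, 0.2, 0.8)
      founders <- matrix(stats::rbinom(cfg$n_founders * spb, 1L,
                                       rep(p0, each = cfg$n_founders)),
                         cfg$n_founders, spb)
      gametes <- matrix(0L, 2L * n_mosaic, spb)
      cur <- sample.int(cfg$n_founders, 2L * n_mosaic, replace = TRUE)
      for (k in seq_len(spb)) {
        if (k > 1L) {
          sw <- stats::runif(2L * n_mosaic) < cfg$switch_rate
          if (any(sw))
            cur[sw] <- sample.int(cfg$n_founders, sum(sw), replace = TRUE)
        }
        gametes[, k] <- founders[cbind(cur, k)]
      }
      cols <- (b - 1L) * spb + seq_len(spb)
      hap1[, cols] <- gametes[seq_len(n_mosaic), ]
      hap2[, cols] <- gametes[n_mosaic + seq_len(n_mosaic), ]
      chroms[cols] <- lay$chrom[b]
      pos[cols] <- as.integer(lay$offset[b] + seq_len(spb) * 1000L)
    }
    # stage 2: three-generation family cohort.  Mosaic pool per unit:
    # founder couple (gf, gm) + two married-in spouses (s1, s2).  Gen 1:
    # p1, p2 = full-sib children of gf x gm.  Gen 2: grandchildren of
    # p1 x s1 and p2 x s2 (full sibs within a couple, first cousins across).
    if (cfg$n_families > 0L) {
      block_id <- rep(seq_len(cfg$n_blocks), each = spb)
      bstart <- match(block_id, block_id) # index of first SNP of own block
      fam <- sort(rep_len(seq_len(cfg$n_families), n))
      roles6 <- c("gf", "gm", "s1", "s2", "p1", "p2")
      role <- unlist(lapply(split(seq_len(n), fam), function(members) {
        k <- length(members)
        r <- roles6[seq_len(min(k, 6L))]
        if (k > 6L) r <- c(r, rep_len(c("c1", "c2"), k - 6L))
        r
      }), use.names = FALSE)
      mei <- function(i)
        .meiosis(hap1[i, ], hap2[i, ], block_id, bstart, cfg$n_blocks,
                 cfg$crossover_rate)
      c1 <- c2 <- matrix(0L, n, m)
      for (fm in seq_len(cfg$n_families)) {
        members <- which(fam == fm)
        pool <- 4L * (fm - 1L) # gf, gm, s1, s2 rows follow this offset
        gen1 <- list() # haplotypes of p1, p2 (children of gf x gm)
        for (p in c("p1", "p2"))
          gen1[[p]] <- list(mei(pool + 1L), mei(pool + 2L))
        for (i in members) {
          h <- switch(role[i],
            gf = list(hap1[pool + 1L, ], hap2[pool + 1L, ]),
            gm = list(hap1[pool + 2L, ], hap2[pool + 2L, ]),
            s1 = list(hap1[pool + 3L, ], hap2[pool + 3L, ]),
            s2 = list(hap1[pool + 4L, ], hap2[pool + 4L, ]),
            p1 = gen1$p1,
            p2 = gen1$p2,
            c1 = list(.meiosis(gen1$p1[[1L]], gen1$p1[[2L]], block_id,
                               bstart, cfg$n_blocks, cfg$crossover_rate),
                      mei(pool + 3L)),
            c2 = list(.meiosis(gen1$p2[[1L]], gen1$p2[[2L]], block_id,
                               bstart, cfg$n_blocks, cfg$crossover_rate),
                      mei(pool + 4L)))
          c1[i, ] <- h[[1L]]
          c2[i, ] <- h[[2L]]
        }
      }
      hap1 <- c1
      hap2 <- c2
    } else {
      fam <- seq_len(n)
      role <- rep("founder", n)
    }
    variants <- data.frame(chrom = chroms, pos = pos,
                           id = paste0("snp", seq_along(pos)),
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
    gd <- genotype_data(sprintf("ind%04d", seq_len(n)), variants, hap1, hap2)
    maf <- pmin(gd$alt_freq, 1 - gd$alt_freq)
    drop <- maf < cfg$maf_min
    if (any(drop)) gd <- subset_snps(gd, !drop)
    attr(gd, "n_dropped_maf") <- sum(drop)
    attr(gd, "family") <- fam
    attr(gd, "role") <- role
    gd
  })
}

# one recombinant gamete: free recombination between blocks, within-block
# crossovers at `rate` per SNP
.meiosis <- function(h1, h2, block_id, bstart, n_blocks, rate) {
  m <- length(h1)
  sw <- stats::runif(m) < rate
  sw[bstart == seq_len(m)] <- FALSE
  cs <- cumsum(sw)
  base <- sample(0:1, n_blocks, replace = TRUE)
  state <- (base[block_id] + cs - cs[bstart]) %% 2L
  ifelse(state == 0L, h1, h2)
}

#' Block index of each SNP of a simulated panel
#'
#' Simulated blocks occupy disjoint 1 Mb windows, so the block of a SNP is a
#' pure function of its coordinates.
#'
#' @param gd A [simulate_genotypes()] panel (possibly MAF-filtered).
#' @return Integer block index per SNP.
#' @export
sim_block_index <- function(gd) {
  key <- paste(gd$variants$chrom, (gd$variants$pos - 1L) %/% 1e6)
  match(key, unique(key))
}

#' Draw the true genetic architecture and per-individual genetic values
#'
#' Causal loci (A, D), distinct-locus tuples (epistasis types) and
#' within-block tuples (`LOCAL`) are sampled; their effects are standard
#' Gaussian draws on the same centered codes the relationship matrices use,
#' and each component's value vector is rescaled so its in-sample variance
#' equals the configured fraction exactly.
#'
#' @param gd Genotypes from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return An object of class `simulation_truth`: `genetic_values` (n x
#'   components matrix), `causal` (per component: locus index matrix and
#'   effect sizes), `var_frac`, `residual`, plus the fixed-effect draws
#'   (`sex`, `age`) and coefficients.
#' @export
simulate_effects <- function(gd, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    n <- n_samples(gd)
    m <- n_snps(gd)
    W <- center_additive(gd)$values
    Hc <- center_dominance(gd)$values
    comps <- names(cfg$var_frac)[cfg$var_frac > 0]
    gv <- matrix(0, n, length(comps), dimnames = list(gd$sample_ids, comps))
    causal <- list()
    blk <- sim_block_index(gd)
    for (lab in comps) {
      if (lab == "LOCAL") {
        ord <- cfg$local_order
        tuples <- list()
        for (b in unique(blk)) {
          in_b <- which(blk == b)
          if (length(in_b) < ord) next
          for (t in seq_len(cfg$local_tuples_per_block))
            tuples[[length(tuples) + 1L]] <- sample(in_b, ord)
        }
        idx <- do.call(rbind, tuples)
        roles <- matrix("A", nrow(idx), ord)
      } else {
        et <- effect_type(lab)
        if (et$order == 1L) {
          k <- .n_causal_for(cfg, lab, m)
          idx <- matrix(sample.int(m, k), ncol = 1L)
          roles <- matrix(if (et$n_additive) "A" else "D", k, 1L)
        } else {
          k <- .n_causal_for(cfg, lab, choose(m, et$order))
          idx <- t(replicate(k, sample.int(m, et$order)))
          idx <- unique(t(apply(idx, 1L, sort)))
          roles <- matrix(rep(c(rep("A", et$n_additive),
                                rep("D", et$n_dominance)), each = nrow(idx)),
                          nrow(idx), et$order)
        }
      }
      if (is.null(idx) || nrow(idx) == 0L)
        stop("no causal tuples available for component ", lab)
      Z <- matrix(1, n, nrow(idx))
      for (j in seq_len(ncol(idx))) {
        codes <- ifelse(roles[, j] == "A", 1L, 2L)
        for (r in seq_len(nrow(idx)))
          Z[, r] <- Z[, r] *
            (if (codes[r] == 1L) W[, idx[r, j]] else Hc[, idx[r, j]])
      }
      beta <- stats::rnorm(nrow(idx))
      g <- drop(Z %*% beta)
      s <- stats::sd(g)
      if (s == 0) stop("degenerate genetic values for component ", lab)
      scale_to <- sqrt(cfg$var_frac[[lab]])
      g <- (g - mean(g)) / s * scale_to
      beta <- beta / s * scale_to
      gv[, lab] <- g
      causal[[lab]] <- list(loci = idx, roles = roles, effects = beta)
    }
    truth <- list(genetic_values = gv, causal = causal,
                  var_frac = cfg$var_frac, residual = cfg$residual,
                  sex = factor(sample(c("F", "M"), n, replace = TRUE)),
                  age = round(stats::runif(n, 30, 70), 1),
                  sex_effect = cfg$sex_effect, age_coef = cfg$age_coef,
                  intercept = cfg$intercept,
                  realized_frac = stats::setNames(
                    apply(gv, 2L, stats::var), comps))
    class(truth) <- "simulation_truth"
    truth
  })
}

#' Realize phenotypes from the simulated architecture
#'
#' y = intercept + classification effect + covariable x coefficient + total
#' genetic value + residual; the residual vector is rescaled so its in-sample
#' variance equals the configured residual fraction exactly.
#'
#' @param gd Genotypes (for the sample ids).
#' @param truth A [simulate_effects()] truth object.
#' @param cfg The same [sim_config()].
#' @return A [phenotype_table()] with `sex` (classification) and `age`
#'   (covariable).
#' @export
simulate_phenotypes <- function(gd, truth, cfg) {
  withr::with_seed(cfg$seed + 2L, {
    n <- n_samples(gd)
    e <- stats::rnorm(n)
    e <- (e - mean(e)) / stats::sd(e) * sqrt(cfg$residual)
    g_tot <- rowSums(truth$genetic_values)
    y <- cfg$intercept + (as.integer(truth$sex) - 1L) * cfg$sex_effect +
      truth$age * cfg$age_coef + g_tot + e
    phenotype_table(gd$sample_ids, y,
                    class_vars = data.frame(sex = truth$sex),
                    covars = data.frame(age = truth$age))
  })
}

#' Simulate a complete dataset
#'
#' @param cfg A [sim_config()].
#' @return List with `gd`, `truth`, `pt`.
#' @export
simulate_dataset <- function(cfg) {
  gd <- simulate_genotypes(cfg)
  truth <- simulate_effects(gd, cfg)
  pt <- simulate_phenotypes(gd, truth, cfg)
  list(gd = gd, truth = truth, pt = pt)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Phased VCF, phenotype TSV (`id`, `trait`, `sex`, `age`), BED of the
#' simulated blocks (as pseudo-gene regions, 0-based half-open) and a truth
#' JSON (variance fractions, causal loci, fixed-effect coefficients).
#' Byte-identical for identical configurations.
#'
#' @param gd,pt,truth A simulated dataset (see [simulate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Named vector of the four file paths, invisibly.
#' @export
write_fixture <- function(gd, pt, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             tsv = file.path(dir, "phenotypes.tsv"),
             bed = file.path(dir, "blocks.bed"),
             json = file.path(dir, "truth.json"))
  write_vcf(gd, paths["vcf"])
  utils::write.table(
    data.frame(id = pt$sample_ids, trait = pt$y,
               sex = pt$class_vars$sex, age = pt$covars$age),
    paths["tsv"], sep = "\t", row.names = FALSE, quote = FALSE)
  blk <- sim_block_index(gd)
  bed <- do.call(rbind, lapply(unique(blk), function(b) {
    in_b <- which(blk == b)
    data.frame(chrom = gd$variants$chrom[in_b[1L]],
               start = min(gd$variants$pos[in_b]) - 1L,
               end = max(gd$variants$pos[in_b]),
               name = paste0("gene", b))
  }))
  utils::write.table(bed, paths["bed"], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(var_frac = as.list(truth$var_frac), residual = truth$residual,
         realized_frac = as.list(truth$realized_frac),
         intercept = truth$intercept, sex_effect = truth$sex_effect,
         age_coef = truth$age_coef,
         causal = lapply(truth$causal, function(cc)
           list(loci = cc$loci, roles = cc$roles, effects = cc$effects))),
    paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
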