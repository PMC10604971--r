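---
title: "Multifactorial genomic prediction: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactorial genomic prediction: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the mixed model and
its assumptions, the construction of each relationship matrix, the REML and
prediction algorithms, the cross-validation and model-selection procedures,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## The model

Phenotypes of n individuals (one record each) are modelled as

$$ y = Xb + \sum_{i=1}^{f} u_i + e, \qquad
   \mathrm{Var}(u_i) = \sigma_i^2 S_i, \qquad
   \mathrm{Var}(e) = \sigma_e^2 I_n , $$

so the phenotypic covariance is $V = \sum_i \sigma_i^2 S_i + \sigma_e^2 I$.
$X$ holds an intercept, treatment-contrast indicators for each
classification variable (sex, treatment group, ...) and numeric covariables
(age, ...).  Each random term $u_i$ is the vector of genetic values of one
*effect type*, and $S_i$ its genomic relationship matrix (GRM).

The effect types are the compositions of additive (A) and dominance (D)
factors up to interaction order four — A, D, A×A, A×D, D×D, A×A×A, ...,
D×D×D×D, fourteen in all (`effect_type_catalog(4)`) — plus the haplotype
additive component H.  Repeated phenotype records, multiallelic variants and
interaction orders above four are out of scope.

## Codes and first-order matrices

The additive code of a SNP is its alt-allele dosage centered on the sample
mean (equivalently $x - 2p$ with $p$ estimated from the analyzed sample; no
external reference frequencies are ever used).  The dominance code is the
heterozygosity indicator centered on the observed heterozygote frequency.
Centering on observed means rather than Hardy–Weinberg expectations
($2pq$ for dominance) was chosen because it makes every code column exactly
orthogonal to the intercept in-sample; under HWE the two choices coincide
asymptotically.

A first-order GRM is the Gram matrix of the code columns.  **Every GRM in
the package is normalized to mean diagonal 1** (the applied divisor is
recorded in the object and in the file metadata).  The conventional
$2\sum p_k q_k$ denominator is only defined for the additive matrix; a
single normalization rule that works for all fifteen heterogeneous effect
types keeps the $\sigma_i^2$ on the phenotypic-variance scale, which is what
makes per-type heritabilities comparable and summable.  Heritability is
reported as $h_i^2 = \sigma_i^2 \bar d_i / (\sum_j \sigma_j^2 \bar d_j +
\sigma_e^2)$ with $\bar d_i$ the mean diagonal of $S_i$ ($\bar d_i = 1$ after
normalization; carrying it makes the estimates invariant to rescaling any
input matrix).

## Epistatic relationship matrices: approximate and exact

The classical approximate construction of an epistasis GRM is the Hadamard
(elementwise) product of first-order GRMs — e.g. $S_{A \times A} \propto
S_A \circ S_A$.  Expanding the product shows it contains terms in which two
or more interaction factors sit on the *same* locus; such intra-locus
"interactions" are not epistasis.  The exact construction keeps only
products over distinct loci: conceptually, one design column per unordered
choice of $a$ additive and $d$ dominance loci (all distinct), each column
the elementwise product of the chosen code columns, and the GRM is that
design's Gram matrix.

Materializing this design is infeasible (it has $\binom{m}{a}\binom{m-a}{d}$
columns), so the package computes the Gram matrix directly by
inclusion–exclusion over set partitions of the $a + d$ interaction slots:

$$ E = \frac{1}{a!\,d!} \sum_{\pi \vdash \text{slots}}
       (-1)^{o - |\pi|} \prod_{B \in \pi} (|B| - 1)!\;
       \big(W^{\circ r_B} \circ H^{\circ s_B}\big)
       \big(W^{\circ r_B} \circ H^{\circ s_B}\big)^{\!\top} $$

where $o = a + d$, the product over blocks is elementwise, and $r_B$, $s_B$
count the additive and dominance slots in block $B$.  For homogeneous
compositions (A×A×A, D×D×D×D, ...) this formula is exactly the Newton's
identity recursion for elementary symmetric polynomials in the per-locus
relationship contributions; one code path covers all twelve compositions of
order 2–4, rather than separate recursions for homogeneous and mixed cases.
A brute-force oracle (`grm_epistasis_bruteforce`, guarded to small panels)
enumerates the design explicitly, and the test suite checks the two agree to
1e-10 relative Frobenius error for every composition across many random
panels.  A one-locus panel is the sharpest contrast: the exact A×A matrix is
identically zero (no distinct pair exists) while the Hadamard product is
pure intra-locus signal.

## The haplotype component

A haplotype block is a run of consecutive SNPs on one chromosome treated as
a multiallelic locus whose alleles are the phased haplotypes observed in the
sample.  Three blocking schemes are provided: fixed SNP count per block,
fixed-bp windows (anchored at position 1 of each chromosome so block
boundaries do not depend on which SNPs happen to be in the panel), and
gene/region blocks from a BED file (0-based half-open intervals, merged when
overlapping; regions with fewer than two panel SNPs are dropped).  Trailing
partial blocks are kept in the count scheme — discarding them would silently
drop SNPs.

The haplotype GRM uses one centered count column (0/1/2 copies) per observed
allele, all alleles kept: after centering, the Gram matrix is invariant to
dropping any one reference allele per block, so keeping all is simplest and
symmetric.  Rare-allele pooling below a frequency threshold is available but
off by default.  SNPs with unphased or missing calls are excluded from
blocks (their phase is undefined) while remaining available to the SNP-level
matrices; missing dosages may be mean-imputed on request.

## REML and GBLUP

Variance components are estimated by average-information (AI) REML.  Each
iteration forms $V$, its Cholesky factorization, the projection
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$, the gradient
$-\tfrac12[\mathrm{tr}(PS_i) - y'PS_iPy]$ and the AI matrix
$\tfrac12\, y'PS_iPS_jPy$.  Three implementation details matter:

* **Damped AI steps.**  The raw AI step solves $AI \cdot \Delta = g$.  When
  several relationship matrices are nearly collinear (a standing feature of
  high-order epistatic GRMs, which are close to linear combinations of
  lower-order ones and the identity), the AI matrix is near-singular and raw
  steps jump arbitrarily far along flat directions, then satisfy the
  convergence test at an arbitrary ridge point.  The package therefore
  solves $(AI + \lambda\,\mathrm{diag}(AI))\Delta = g$ with $\lambda$
  decreased tenfold after every accepted step (floor $10^{-3}$) and
  increased tenfold on rejection — accepting only steps that do not decrease
  the restricted log-likelihood.
* **EM start and fallback.**  The first `em_start = 3` iterations use
  EM-REML updates ($\sigma_i^2 \leftarrow \sigma_i^2 + \sigma_i^4 (y'PS_iPy
  - \mathrm{tr}(PS_i))/n$), which are slow but monotone; EM is also the
  fallback whenever no damped AI step is acceptable.  Accepted iterations
  therefore never decrease the log-likelihood (asserted in the tests).
* **Boundary policy.**  Components driven to zero are clamped at
  $10^{-6}\,\mathrm{var}(y)$ and flagged; published heritability entries of
  0.000 correspond to such boundary solutions.  Starting values split
  var(y) equally across all components; convergence is
  $|\Delta \log L| < 10^{-6}$, at most 200 iterations, and non-convergence
  returns a flagged result rather than an error.  A component whose GRM is
  the identity is rejected up front: it is indistinguishable from the
  residual.

GBLUP uses the V-inverse formulation: on the training individuals,
$\hat b$ is the GLS estimate and $\hat u_i[\text{target}] = \sigma_i^2
S_i[\text{target}, \text{train}]\, V_\text{train}^{-1} (y - X\hat b)$.
Masked individuals never enter $V_\text{train}$, so the construction is
leak-free (asserted by a permutation test).  Predicted *genetic* values are
reported without adding fixed-effect terms — predictive ability correlates
genetic values with phenotypes, and adding $X\hat b$ would only shift and
rescale within a fold.  Henderson's mixed-model equations were not used
because the model routinely carries up to fifteen dense covariance
structures at moderate n; the tests verify the V-inverse path against the
MME solution on full-rank cases and against ridge-regression SNP-BLUP with
matched shrinkage.

## Cross-validation and model selection

`make_folds` shuffles individuals with a recorded seed; the first nine folds
have $\lfloor n/10 \rfloor$ individuals and the tenth takes the remainder
(7564 individuals split as nine folds of 756 and one of 760).  For each
fold, variance components are re-estimated on the training folds and the
validation individuals' total genetic values are predicted with phenotypes
masked.  Predictive ability is the arithmetic mean over folds of the Pearson
correlation between predicted genetic value and observed phenotype — the
mean of fold correlations, never the pooled correlation (the two are
asserted to differ on heterogeneous fixtures).  Folds with undefined
correlations are dropped from the mean with a warning.  One shared seeded
fold assignment is used when comparing models, so model contrasts are
paired.

Model selection is two-stage.  The initial stage fits the full model (all
fourteen SNP/epistasis types; the haplotype component enters later at the
integration stage) and keeps effect types with heritability strictly greater
than 1%.  The final stage cross-validates a candidate set and picks the
highest accuracy, breaking ties by fewest effect types, then by effect-type
subscript order, so selection is deterministic.  Candidates default to
subscript-ordered nested prefixes of the initial model (the structure of
published model-comparison tables; linear in the number of types), with an
exhaustive-subsets option for small models.  Accuracies are compared after
rounding — 3 decimals by default, matching the precision at which such
comparisons are conventionally published.  In the scaled-down studies of the
test suite, comparisons use 2 decimals: with fold-level standard errors
around 0.015 at a few hundred individuals, 0.01 is the same
precision-to-noise ratio that 0.001 is at cohort sizes in the thousands.

## The synthetic cohort generator

The generator emulates the data shape the analysis assumes — a deeply
phenotyped human family cohort genotyped on an LD-blocked SNP panel — while
staying fully self-contained and deterministic given its configuration.

* **Genotypes.**  Per block, a small pool of founder haplotypes is drawn
  (allele frequencies uniform on 0.2–0.8) and each gamete is a mosaic of
  founders with a per-SNP switch rate, so within-block LD is strong,
  between-block LD absent, and block alleles enumerable.  SNPs below the
  MAF threshold (default 0.05, the panel inclusion rule) are dropped and
  counted.
* **Pedigree.**  By default the cohort is a three-generation family study:
  per unit, a founder couple, two of their children married to unrelated
  spouses, and grandchildren from both couples — everyone in the cohort.
  This supplies parent-offspring, full-sib, grandparent, avuncular and
  first-cousin pairs.  The design matters: the expected relationship of a
  pair under an epistatic type is the matching power/product of its additive
  and dominance relationships, and only a cohort with several distinct
  relationship levels makes higher-order variance components separable from
  each other and from the residual at desk-scale n.  In a nominally
  unrelated cohort (`n_families = 0`, used for the Hardy–Weinberg test,
  since relatedness inflates the goodness-of-fit statistic) the epistatic
  GRMs collapse towards linear combinations of lower-order ones and the
  identity, and their components are unidentifiable — measured directly
  during development, and the reason family structure is the default.
* **Architecture.**  Causal sets are sampled per effect type — loci for A
  and D, distinct-locus tuples for the global epistasis types, within-block
  tuples for the block-local high-order term (`LOCAL`, order 3 by default) —
  with Gaussian effects on the same centered codes the GRMs use; each
  component's value vector is rescaled so its in-sample variance equals the
  configured fraction exactly, and the residual likewise.  Defaults are
  deliberately dense (1500 additive loci, 800 dominance loci, 30000 tuples
  per epistasis type): complex phenotypes are polygenic, and dense
  architectures are also what makes each component's realized covariance
  match its relationship matrix, the GREML working model.  Sparse
  architectures are available through `n_causal` and produce the expected
  model-misspecification noise.
* **What it does not emulate.**  Genotyping error, missingness mechanisms,
  ascertainment, population stratification, sex chromosomes, and trait
  non-normality (phenotypes are Gaussian by construction; the normality
  transformations applied to real lipid panels are upstream of this model).
  Passing tests on this generator therefore demonstrate correctness of the
  estimation and selection machinery under the model's own assumptions, not
  robustness to those realities.

## Problem sizes in the test suite

The statistical tests run at sizes chosen to finish in minutes while keeping
each effect measurable: parameter recovery on ten cohorts of n = 1000 with
100 blocks × 20 SNPs (truth A/D/A×A = 0.3/0.1/0.2); cross-validation null
and bound checks at n = 400 and n = 1000; the two-stage selection study on
twenty cohorts of n = 400 (16 blocks × 10 SNPs, truth A = 0.2, A×A = 0.4);
and the haplotype-versus-global-epistasis comparison on ten cohorts of
n = 500 (24 blocks × 8 SNPs, 16 founders, block-local three-locus fraction
0.45).

## Known limitations

* **Identifiability of high-order components at desk scale.**  A
  fourth-order epistatic GRM lies within a few thousandths (per entry) of
  the span of the lower-order matrices and the identity for any realistic
  human-pedigree cohort, so its variance component carries a per-replicate
  sampling spread of roughly 0.1–0.2 at n = 1000 regardless of optimizer:
  point estimates for a truth-zero fourth-order component are bimodal
  (boundary, or a ridge value up to ~0.5).  Means across replicates remain
  well-behaved, but a single fit's fourth-order estimate should not be read
  as resolved below a few hundredths.  Relatedly, the full fourteen-component
  model is overparameterized at a few hundred individuals on a few hundred
  SNPs — near-identity high-order GRMs can jointly absorb residual variance —
  which is why the pipeline's cross-validation stage, not the heritability
  threshold, is the effective guard against spurious effect types.
* Dense linear algebra throughout: memory and time scale as n² and n³, with
  n ≤ ~10⁴ assumed.  No sparse or low-rank shortcuts.
* Pearson correlation is the only accuracy measure; no per-individual
  reliabilities (PEV) are computed.
* The haplotype component models haplotype *additive* effects only; its
  advantage over SNP models requires blocks whose distinct-allele count
  exceeds the block's SNP count, otherwise SNP dosages span the same space.
* Standard errors of variance components come from the inverse AI matrix at
  convergence; no profile-likelihood intervals.
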