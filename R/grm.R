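#' Genomic relationship matrix container
#'
#' @param label Effect-type label (`"A"`, `"AA"`, ..., `"H"`).
#' @param matrix n x n symmetric numeric matrix.
#' @param sample_ids Sample identifiers (length n).
#' @param normalizer Scalar the raw Gram matrix was divided by (its mean
#'   diagonal), or `NA` for an unnormalized matrix.
#' @param method One of `"first_order"`, `"hadamard_approx"`, `"exact"`,
#'   `"haplotype"`, `"bruteforce"`.
#' @return An object of class `grm`.
#' @export
grm <- function(label, matrix, sample_ids, normalizer, method) {
  method <- match.arg(method, c("first_order", "hadamard_approx", "exact",
                                "haplotype", "bruteforce"))
  matrix <- as.matrix(matrix)
  n <- length(sample_ids)
  stopifnot(nrow(matrix) == n, ncol(matrix) == n)
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-12 * max(1, max(abs(matrix))))
    stop("GRM is not symmetric (max asymmetry ", format(asym), ")")
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- list(sample_ids, sample_ids)
  g <- list(label = label, matrix = matrix,
            sample_ids = as.character(sample_ids),
            normalizer = normalizer, method = method)
  class(g) <- "grm"
  g
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", x$label, " (", x$method, "), ", nrow(x$matrix), " x ",
      ncol(x$matrix), ", mean diagonal ",
      format(mean(diag(x$matrix)), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Scale a relationship matrix to mean diagonal 1
#'
#' All relationship matrices in this package are normalized by their mean
#' diagonal so that variance components of heterogeneous effect types are on
#' the phenotypic-variance scale and heritabilities are directly comparable.
#'
#' @param g A `grm` (or a plain symmetric matrix).
#' @return A `grm` with mean diagonal 1 and the applied `normalizer` recorded.
#' @export
normalize_grm <- function(g) {
  if (!inherits(g, "grm"))
    stop("normalize_grm expects a 'grm' object")
  d <- mean(diag(g$matrix))
  if (!is.finite(d) || d <= 0)
    stop("cannot normalize GRM '", g$label, "': mean diagonal is ",
         format(d), " (zero relationship matrix?)")
  prev <- if (is.na(g$normalizer)) 1 else g$normalizer
  grm(g$label, g$matrix / d, g$sample_ids, normalizer = prev * d,
      method = g$method)
}

.ids_of <- function(cm) {
  ids <- rownames(cm$values)
  if (is.null(ids)) paste0("S", seq_len(nrow(cm$values))) else ids
}

#' First-order (additive or dominance) relationship matrix
#'
#' Gram matrix of the centered code columns, scaled to mean diagonal 1.
#'
#' @param cm A [code_matrix()] (additive or dominance).
#' @return A `grm` labelled `"A"` or `"D"`.
#' @export
grm_first_order <- function(cm) {
  stopifnot(inherits(cm, "code_matrix"), ncol(cm$values) >= 1L)
  raw <- tcrossprod(cm$values)
  label <- if (cm$kind == "additive") "A" else "D"
  normalize_grm(grm(label, raw, .ids_of(cm), NA_real_, "first_order"))
}

#' Approximate (Hadamard-product) epistasis relationship matrix
#'
#' The classical construction: the relationship matrix of an interaction of
#' `a` additive and `d` dominance factors is approximated by the elementwise
#' product of `a` copies of the additive and `d` copies of the dominance
#' relationship matrix, then rescaled to mean diagonal 1.  The product
#' retains same-locus (intra-locus) terms that a true multi-locus interaction
#' does not have; see [grm_epistasis_exact()] for the corrected construction.
#'
#' @param et An [effect_type()] of order 2-4.
#' @param grm_A,grm_D First-order `grm`s on the same samples (either may be
#'   omitted when the composition does not use it).
#' @return A `grm` with `method = "hadamard_approx"`.
#' @export
grm_epistasis_hadamard <- function(et, grm_A = NULL, grm_D = NULL) {
  stopifnot(inherits(et, "effect_type"), !et$is_haplotype)
  if (et$order < 2L || et$order > 4L)
    stop("epistasis order must be 2-4, got ", et$order)
  if (et$n_additive > 0L && is.null(grm_A)) stop("grm_A required for ", et$label)
  if (et$n_dominance > 0L && is.null(grm_D)) stop("grm_D required for ", et$label)
  base <- if (!is.null(grm_A)) grm_A else grm_D
  M <- base$matrix^0 # all-ones, correct shape
  if (et$n_additive > 0L) M <- M * grm_A$matrix^et$n_additive
  if (et$n_dominance > 0L) M <- M * grm_D$matrix^et$n_dominance
  normalize_grm(grm(et$label, M, base$sample_ids, NA_real_, "hadamard_approx"))
}

# All set partitions of 1..k (k small), as lists of integer vectors.
.set_partitions <- function(k) {
  if (k == 1L) return(list(list(1L)))
  smaller <- .set_partitions(k - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], k)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(k))
  }
  out
}

#' Exact epistasis relationship matrix (intra-locus terms removed)
#'
#' Gram matrix of the implicit design whose columns are products of centered
#' codes over *distinct* loci only, one column per unordered choice of `a`
#' additive and `d` dominance loci (all distinct).  Computed without forming
#' that design, via an inclusion-exclusion over set partitions of the `a + d`
#' interaction slots: each partition contributes
#' `(-1)^(order - #blocks) * prod((|B|-1)!) * prod_B M_B / (a! d!)`,
#' where for a block with `r` additive and `s` dominance slots
#' `M_B = (W^r * H^s)(W^r * H^s)'` (elementwise powers/products of the code
#' matrices).  For homogeneous compositions this reduces to the Newton's
#' identity recursion for elementary symmetric polynomials in the per-locus
#' relationship contributions.  Unlike the Hadamard approximation, terms in
#' which two interaction factors sit on the same locus never appear.
#'
#' @param et An [effect_type()] of order 2-4.
#' @param W Additive [code_matrix()] (needed when the composition has
#'   additive factors).
#' @param H Dominance [code_matrix()] (needed for dominance factors).
#' @return A `grm` with `method = "exact"`, mean diagonal 1.  When the panel
#'   has fewer loci than the interaction order no distinct tuple exists; the
#'   all-zero unnormalized matrix is returned with a warning.
#' @export
grm_epistasis_exact <- function(et, W = NULL, H = NULL) {
  stopifnot(inherits(et, "effect_type"), !et$is_haplotype)
  if (et$order < 2L || et$order > 4L)
    stop("epistasis order must be 2-4, got ", et$order)
  a <- et$n_additive
  d <- et$n_dominance
  if (a > 0L && is.null(W)) stop("additive codes W required for ", et$label)
  if (d > 0L && is.null(H)) stop("dominance codes H required for ", et$label)
  cm <- if (a > 0L) W else H
  n <- nrow(cm$values)
  m <- ncol(cm$values)
  ids <- .ids_of(cm)
  if (m < et$order) {
    warning("panel has ", m, " loci < interaction order ", et$order,
            "; no distinct locus tuple exists, returning zero matrix")
    return(grm(et$label, matrix(0, n, n), ids, NA_real_, "exact"))
  }
  slots <- c(rep(1L, a), rep(0L, d)) # 1 = additive slot, 0 = dominance slot
  # cache of M_{r,s} = tcrossprod(W^r * H^s)
  cache <- new.env(parent = emptyenv())
  block_gram <- function(r, s) {
    key <- paste(r, s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    U <- matrix(1, n, m)
    if (r > 0L) U <- U * W$values^r
    if (s > 0L) U <- U * H$values^s
    cache[[key]] <- tcrossprod(U)
    cache[[key]]
  }
  E <- matrix(0, n, n)
  for (p in .set_partitions(et$order)) {
    term <- matrix(1, n, n)
    for (B in p) {
      r <- sum(slots[B])
      term <- term * block_gram(r, length(B) - r)
    }
    sign <- (-1)^(et$order - length(p))
    coef <- sign * prod(factorial(lengths(p) - 1L))
    E <- E + coef * term
  }
  E <- E / (factorial(a) * factorial(d))
  normalize_grm(grm(et$label, E, ids, NA_real_, "exact"))
}

#' Brute-force epistasis relationship matrix (verification oracle)
#'
#' Explicitly enumerates every unordered assignment of `a` additive and `d`
#' dominance factors to distinct loci, builds the corresponding design column
#' as the elementwise product of the chosen code columns, and returns the
#' normalized Gram matrix.  Exponential in panel size; guarded to m <= 30 and
#' order <= 4.  Exists to verify [grm_epistasis_exact()].
#'
#' @inheritParams grm_epistasis_exact
#' @return A `grm` with `method = "bruteforce"`.
#' @export
grm_epistasis_bruteforce <- function(et, W = NULL, H = NULL) {
  stopifnot(inherits(et, "effect_type"), !et$is_haplotype)
  if (et$order < 2L || et$order > 4L)
    stop("epistasis order must be 2-4, got ", et$order)
  a <- et$n_additive
  d <- et$n_dominance
  cm <- if (a > 0L) W else H
  n <- nrow(cm$values)
  m <- ncol(cm$values)
  if (m > 30L) stop("brute-force oracle guarded to m <= 30, got ", m)
  ids <- .ids_of(cm)
  if (m < et$order) {
    warning("panel has ", m, " loci < interaction order ", et$order,
            "; returning zero matrix")
    return(grm(et$label, matrix(0, n, n), ids, NA_real_, "bruteforce"))
  }
  a_sets <- if (a > 0L) utils::combn(m, a, simplify = FALSE) else list(integer())
  cols <- list()
  for (S in a_sets) {
    rest <- setdiff(seq_len(m), S)
    d_sets <- if (d > 0L) {
      if (length(rest) < d) next
      # combn(x, k) treats a scalar x as seq_len(x); guard that case
      if (length(rest) == d) list(rest) else
        utils::combn(rest, d, simplify = FALSE)
    } else list(integer())
    for (T_ in d_sets) {
      col <- rep(1, n)
      for (l in S) col <- col * W$values[, l]
      for (l in T_) col <- col * H$values[, l]
      cols[[length(cols) + 1L]] <- col
    }
  }
  Z <- do.call(cbind, cols)
  normalize_grm(grm(et$label, tcrossprod(Z), ids, NA_real_, "bruteforce"))
}

#' Verify positive semidefiniteness of a relationship matrix
#'
#' @param g A `grm`.
#' @param tol Relative tolerance: smallest eigenvalue must be
#'   >= -tol * largest.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_psd <- function(g, tol = 1e-8) {
  ev <- eigen(g$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev)))
    stop("GRM '", g$label, "' is not PSD: min eigenvalue ", format(min(ev)))
  invisible(TRUE)
}
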