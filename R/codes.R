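#' Centered per-locus code matrices
#'
#' The additive code of a SNP is the alt-allele dosage centered on its sample
#' mean (x - 2p when allele frequencies are taken from the sample); the
#' dominance code is the heterozygosity indicator centered on the observed
#' heterozygote frequency.  Every epistasis relationship matrix of this
#' package is built from products of these centered codes at distinct loci.
#'
#' @param gd A [genotype_data()] object.
#' @return An object of class `code_matrix`: list with `kind`
#'   (`"additive"` or `"dominance"`), `values` (n x m matrix, columns centered
#'   to mean 0) and `snp_ids`.
#' @export
center_additive <- function(gd) {
  v <- scale(gd$dosage, center = TRUE, scale = FALSE)
  attr(v, "scaled:center") <- NULL
  rownames(v) <- gd$sample_ids
  code_matrix("additive", v, gd$variants$id)
}

#' @rdname center_additive
#' @export
center_dominance <- function(gd) {
  het <- (gd$dosage == 1) * 1
  v <- scale(het, center = TRUE, scale = FALSE)
  attr(v, "scaled:center") <- NULL
  rownames(v) <- gd$sample_ids
  code_matrix("dominance", v, gd$variants$id)
}

#' @param kind `"additive"` or `"dominance"`.
#' @param values n x m matrix of centered codes.
#' @param snp_ids SNP identifiers (length m).
#' @rdname center_additive
#' @export
code_matrix <- function(kind, values, snp_ids) {
  kind <- match.arg(kind, c("additive", "dominance"))
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(snp_ids))
  if (ncol(values) && max(abs(colMeans(values))) > 1e-9)
    stop("code columns must be centered to mean 0")
  cm <- list(kind = kind, values = values, snp_ids = as.character(snp_ids))
  class(cm) <- "code_matrix"
  cm
}

#' @export
print.code_matrix <- function(x, ...) {
  cat("<code_matrix> ", x$kind, ", ", nrow(x$values), " x ", ncol(x$values),
      "\n", sep = "")
  invisible(x)
}
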