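#' Genetic effect types of the multifactorial model
#'
#' An effect type is a composition of additive (A) and dominance (D) factors,
#' e.g. `AA` is additive-by-additive pairwise epistasis and `AAD` is a
#' third-order interaction of two additive factors and one dominance factor,
#' or the haplotype additive component `H`.  Each SNP-level type carries the
#' conventional subscript used when writing the mixed model as
#' y = Xb + Z(u_1 + ... + u_f) + e: subscripts 1-14 are the SNP and epistasis
#' types in order of interaction order, 15 is the haplotype additive type.
#'
#' @param label Effect-type label such as `"A"`, `"D"`, `"AAD"` or `"H"`.
#' @return An object of class `effect_type` with fields `label`,
#'   `n_additive`, `n_dominance`, `order`, `is_haplotype` and `subscript`.
#' @examples
#' effect_type("AD")
#' effect_type("H")
#' @export
effect_type <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  label <- toupper(trimws(label))
  if (label == "H") {
    et <- list(label = "H", n_additive = 0L, n_dominance = 0L,
               order = NA_integer_, is_haplotype = TRUE, subscript = 15L)
    class(et) <- "effect_type"
    return(et)
  }
  chars <- strsplit(label, "")[[1]]
  if (length(chars) < 1L || length(chars) > 4L || !all(chars %in% c("A", "D")))
    stop("invalid effect type label: '", label, "'")
  # canonical spelling: all A factors before D factors
  n_add <- sum(chars == "A")
  n_dom <- sum(chars == "D")
  canonical <- paste0(strrep("A", n_add), strrep("D", n_dom))
  if (label != canonical)
    stop("effect type '", label, "' is not in canonical form '", canonical, "'")
  et <- list(label = canonical, n_additive = n_add, n_dominance = n_dom,
             order = n_add + n_dom, is_haplotype = FALSE,
             subscript = .effect_subscript(n_add, n_dom))
  class(et) <- "effect_type"
  et
}

# subscript in Table-1 order: within each order, A-rich compositions first
.effect_subscript <- function(n_add, n_dom) {
  ord <- n_add + n_dom
  # number of types of strictly lower order: sum over o < ord of (o + 1)
  before <- sum(seq_len(ord - 1L) + 1L)
  as.integer(before + (ord - n_add) + 1L)
}

#' @export
print.effect_type <- function(x, ...) {
  cat("<effect_type> ", x$label,
      if (x$is_haplotype) " (haplotype additive)" else
        sprintf(" (order %d: %d additive, %d dominance factors)",
                x$order, x$n_additive, x$n_dominance),
      ", subscript ", x$subscript, "\n", sep = "")
  invisible(x)
}

#' @export
format.effect_type <- function(x, ...) x$label

#' Catalogue of SNP and epistasis effect types up to a maximum order
#'
#' Enumerates all compositions of additive and dominance factors with
#' interaction order 1 to `max_order`, in the conventional order:
#' A, D, AA, AD, DD, AAA, ..., DDDD.  The haplotype component is not part of
#' this catalogue; it is added to a model explicitly via `"H"`.
#'
#' @param max_order Highest interaction order to include (1-4).
#' @return List of `effect_type` objects; 14 types for `max_order = 4`.
#' @examples
#' length(effect_type_catalog(4)) # 14
#' vapply(effect_type_catalog(2), format, "") # A D AA AD DD
#' @export
effect_type_catalog <- function(max_order = 4) {
  stopifnot(length(max_order) == 1L, max_order >= 1, max_order <= 4)
  out <- list()
  for (ord in seq_len(max_order))
    for (n_add in ord:0)
      out[[length(out) + 1L]] <-
        effect_type(paste0(strrep("A", n_add), strrep("D", ord - n_add)))
  out
}

#' Model specification: an ordered set of effect types
#'
#' @param types Character vector of effect-type labels or a model string such
#'   as `"A+D+AA+H"`.
#' @return An object of class `model_spec` holding the ordered unique
#'   `effect_type` list.
#' @examples
#' model_spec("A+D+AA+AD")
#' @export
model_spec <- function(types) {
  if (length(types) == 1L && grepl("+", types, fixed = TRUE))
    types <- strsplit(types, "+", fixed = TRUE)[[1]]
  ets <- lapply(trimws(types), effect_type)
  labels <- vapply(ets, format, "")
  if (anyDuplicated(labels))
    stop("duplicate effect types in model: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  if (length(ets) < 1L) stop("a model needs at least one effect type")
  ms <- list(effect_types = ets, labels = labels)
  class(ms) <- "model_spec"
  ms
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", paste(x$labels, collapse = " + "), "\n")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) paste(x$labels, collapse = "+")
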