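#' Construct a phenotype table
#'
#' One trait record per individual (repeated records are out of scope, so the
#' observation incidence matrix is the identity and N = n).
#'
#' @param sample_ids Character vector of unique individual ids.
#' @param y Numeric trait values, no missing entries.
#' @param class_vars Data frame of classification variables (factors), or NULL.
#' @param covars Data frame of numeric covariables, or NULL.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_ids, y, class_vars = NULL, covars = NULL) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  stopifnot(length(y) == n, !anyNA(y))
  if (!is.null(class_vars)) {
    stopifnot(nrow(class_vars) == n)
    class_vars[] <- lapply(class_vars, as.factor)
  }
  if (!is.null(covars)) {
    stopifnot(nrow(covars) == n, all(vapply(covars, is.numeric, TRUE)))
  }
  pt <- list(sample_ids = sample_ids, y = as.numeric(y),
             class_vars = class_vars, covars = covars)
  class(pt) <- "phenotype_table"
  pt
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("<phenotype_table> ", length(x$sample_ids), " individuals; ",
      if (is.null(x$class_vars)) 0L else ncol(x$class_vars),
      " classification variable(s), ",
      if (is.null(x$covars)) 0L else ncol(x$covars), " covariable(s)\n",
      sep = "")
  invisible(x)
}

#' Read a phenotype and fixed-effect table from a TSV file
#'
#' The file must have a header with an `id` column.  Rows are restricted to
#' samples present in `gd` (if given); samples dropped on either side are
#' reported via `message()`.
#'
#' @param path TSV path.
#' @param trait Name of the trait column.
#' @param class_vars Character vector of classification-variable columns.
#' @param covars Character vector of numeric covariable columns.
#' @param gd Optional [genotype_data()] to intersect samples with.
#' @return A `phenotype_table` whose rows follow the genotype sample order
#'   where `gd` is given.
#' @export
read_phenotypes <- function(path, trait, class_vars = character(),
                            covars = character(), gd = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", trait, class_vars, covars)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  tab <- tab[!is.na(tab[[trait]]), , drop = FALSE]
  if (!is.null(gd)) {
    keep <- tab$id %in% gd$sample_ids
    if (any(!keep))
      message(sum(!keep), " phenotyped sample(s) absent from genotypes; dropped")
    tab <- tab[keep, , drop = FALSE]
    tab <- tab[match(intersect(gd$sample_ids, tab$id), tab$id), , drop = FALSE]
  }
  phenotype_table(
    tab$id, tab[[trait]],
    class_vars = if (length(class_vars))
      tab[, class_vars, drop = FALSE] else NULL,
    covars = if (length(covars)) tab[, covars, drop = FALSE] else NULL)
}

#' Build the fixed-effect design matrix
#'
#' Intercept, plus (levels - 1) treatment-contrast indicator columns per
#' classification variable, plus one column per covariable; checked for full
#' column rank.
#'
#' @param pt A `phenotype_table`.
#' @return An object of class `design_matrix`: list with `X` (n x c numeric
#'   matrix) and `column_labels`.
#' @export
build_design_matrix <- function(pt) {
  n <- length(pt$sample_ids)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(pt$class_vars)) {
    for (nm in names(pt$class_vars)) {
      f <- pt$class_vars[[nm]]
      if (nlevels(f) < 2L)
        stop("classification variable '", nm, "' has a single level")
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(f)[-1L])
      X <- cbind(X, mm)
    }
  }
  if (!is.null(pt$covars)) {
    cv <- as.matrix(pt$covars)
    colnames(cv) <- names(pt$covars)
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dm <- list(X = X, column_labels = colnames(X))
  class(dm) <- "design_matrix"
  dm
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " x ", ncol(x$X), ": ",
      paste(x$column_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
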