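#' GBLUP of per-component and total genetic values
#'
#' Fixed effects are estimated by GLS on the training individuals; each
#' effect type's genetic values for the target individuals are
#' `sigma_i^2 S_i[target, train] V_train^-1 (y_train - X_train b_hat)`.
#' Target (validation) individuals' phenotypes never enter: V is built from
#' training rows/columns only, so masking is leak-free by construction.
#' Predictions are of genetic values only; fixed-effect terms are not added.
#'
#' @param y_train Training phenotypes, aligned with `train_ids`.
#' @param X_train Training fixed-effect design matrix.
#' @param S_list_full List of `grm` objects covering training and target
#'   individuals (built once on the full sample).
#' @param vce A [fit_greml()] estimate obtained on the training individuals.
#' @param train_ids,target_ids Sample identifiers (must exist in every GRM).
#'   `target_ids` may include training individuals.
#' @return An object of class `component_predictions`: `pred` (targets x
#'   effect types matrix of predicted genetic values), `fixed_effects`
#'   (named GLS estimates), `target_ids`.
#' @export
gblup_components <- function(y_train, X_train, S_list_full, vce,
                             train_ids, target_ids) {
  stopifnot(inherits(vce, "vc_estimate"),
            length(S_list_full) == length(vce$sigma2))
  S_mats <- .as_matrices(S_list_full)
  all_ids <- if (inherits(S_list_full[[1L]], "grm"))
    S_list_full[[1L]]$sample_ids else rownames(S_mats[[1L]])
  if (is.null(all_ids)) all_ids <- seq_len(nrow(S_mats[[1L]]))
  tr <- match(as.character(train_ids), as.character(all_ids))
  tg <- match(as.character(target_ids), as.character(all_ids))
  if (anyNA(tr)) stop("training id(s) missing from GRMs: ",
                      paste(train_ids[is.na(tr)], collapse = ", "))
  if (anyNA(tg)) stop("target id(s) missing from GRMs: ",
                      paste(target_ids[is.na(tg)], collapse = ", "))
  y_train <- as.numeric(y_train)
  X_train <- as.matrix(X_train)
  nt <- length(tr)
  stopifnot(length(y_train) == nt, nrow(X_train) == nt)
  f <- length(S_mats)
  V <- diag(vce$sigma2_e, nt)
  for (i in seq_len(f)) V <- V + vce$sigma2[i] * S_mats[[i]][tr, tr]
  R <- chol(V)
  Vinv <- chol2inv(R)
  VinvX <- Vinv %*% X_train
  bhat <- drop(solve(crossprod(X_train, VinvX), crossprod(VinvX, y_train)))
  names(bhat) <- colnames(X_train)
  r <- drop(Vinv %*% (y_train - X_train %*% bhat))
  pred <- matrix(0, length(tg), f,
                 dimnames = list(as.character(target_ids), vce$labels))
  for (i in seq_len(f))
    pred[, i] <- vce$sigma2[i] * drop(S_mats[[i]][tg, tr, drop = FALSE] %*% r)
  cp <- list(pred = pred, fixed_effects = bhat,
             target_ids = as.character(target_ids))
  class(cp) <- "component_predictions"
  cp
}

#' @export
print.component_predictions <- function(x, ...) {
  cat("<component_predictions> ", nrow(x$pred), " individuals x ",
      ncol(x$pred), " effect type(s): ",
      paste(colnames(x$pred), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total genetic value: sum of the per-component predictions
#'
#' @param cp A [gblup_components()] result.
#' @return Named numeric vector over the target individuals.
#' @export
total_genetic_value <- function(cp) {
  stopifnot(inherits(cp, "component_predictions"))
  out <- rowSums(cp$pred)
  names(out) <- cp$target_ids
  out
}
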