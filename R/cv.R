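#' Assign individuals to k validation folds
#'
#' Seeded uniform shuffle; the first k-1 folds have floor(n/k) individuals
#' each and the last fold takes the remainder (for n = 7564 and k = 10:
#' nine folds of 756 and a tenth of 760).
#'
#' @param ids Sample identifiers.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is a pure function of
#'   (ids, k, seed).
#' @return An object of class `fold_assignment`: `fold` (integer 1..k per
#'   individual, named by id), `fold_sizes`, `k`, `seed`.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  stopifnot(n >= k, k >= 2L)
  base <- n %/% k
  sizes <- c(rep(base, k - 1L), n - base * (k - 1L))
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  names(fold) <- as.character(ids)
  fa <- list(fold = fold, fold_sizes = sizes, k = k, seed = seed)
  class(fa) <- "fold_assignment"
  fa
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment> ", length(x$fold), " individuals in ", x$k,
      " folds (sizes ", paste(x$fold_sizes, collapse = ", "),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' k-fold cross-validated predictive ability
#'
#' For each fold: variance components are re-estimated on the training
#' individuals (the other k-1 folds), genetic values of the validation
#' individuals are predicted by GBLUP with their phenotypes masked, and the
#' Pearson correlation between total predicted genetic value and the observed
#' phenotypes in the fold is recorded.  The predictive ability is the
#' arithmetic mean of the per-fold correlations (not the pooled correlation);
#' its spread is the sample standard deviation across folds.
#'
#' @param y Phenotype vector over all individuals.
#' @param X Fixed-effect design matrix over all individuals.
#' @param S_list List of `grm`s over all individuals (one per effect type of
#'   the model).
#' @param folds A [make_folds()] assignment over the same individuals.
#' @param ids Sample identifiers (defaults to the GRM ids).
#' @param reml_opts List of options passed on to [fit_greml()] (e.g.
#'   `tol`, `max_iter`).
#' @return An object of class `prediction_result`: `fold_cor` (per-fold
#'   correlations, NA where undefined), `accuracy` (their mean over defined
#'   folds), `sd` (sample sd across folds), `predictions` (total genetic
#'   value per individual, each predicted exactly once), `fold_vce` (list of
#'   per-fold variance-component estimates), `mean_h2` (fold-averaged
#'   per-type heritabilities).
#' @export
cross_validate <- function(y, X, S_list, folds, ids = NULL,
                           reml_opts = list()) {
  if (is.null(ids))
    ids <- if (inherits(S_list[[1L]], "grm")) S_list[[1L]]$sample_ids
  else as.character(seq_along(y))
  ids <- as.character(ids)
  n <- length(y)
  stopifnot(length(ids) == n, identical(sort(names(folds$fold)), sort(ids)))
  fold <- folds$fold[ids]
  X <- as.matrix(X)
  fold_cor <- rep(NA_real_, folds$k)
  fold_vce <- vector("list", folds$k)
  predictions <- rep(NA_real_, n)
  names(predictions) <- ids
  for (kk in seq_len(folds$k)) {
    val <- which(fold == kk)
    trn <- which(fold != kk)
    S_train <- lapply(S_list, function(g) {
      if (inherits(g, "grm")) g$matrix[trn, trn] else g[trn, trn]
    })
    vce <- do.call(fit_greml, c(list(y = y[trn], X = X[trn, , drop = FALSE],
                                     S_list = S_train,
                                     labels = .grm_labels(S_list)),
                                reml_opts))
    fold_vce[[kk]] <- vce
    cp <- gblup_components(y[trn], X[trn, , drop = FALSE], S_list, vce,
                           train_ids = ids[trn], target_ids = ids[val])
    ghat <- total_genetic_value(cp)
    predictions[val] <- ghat
    if (stats::sd(ghat) > 0 && stats::sd(y[val]) > 0) {
      fold_cor[kk] <- stats::cor(ghat, y[val])
    } else {
      warning("fold ", kk, ": constant predictions or phenotypes; ",
              "correlation undefined, fold dropped from the average")
    }
  }
  pr <- list(fold_cor = fold_cor,
             accuracy = mean(fold_cor, na.rm = TRUE),
             sd = stats::sd(fold_cor, na.rm = TRUE),
             predictions = predictions,
             fold_vce = fold_vce,
             mean_h2 = .mean_fold_h2(fold_vce),
             k = folds$k)
  class(pr) <- "prediction_result"
  pr
}

.grm_labels <- function(S_list) {
  vapply(seq_along(S_list), function(i) {
    s <- S_list[[i]]
    if (inherits(s, "grm")) s$label else paste0("V", i)
  }, "")
}

.mean_fold_h2 <- function(fold_vce) {
  h <- do.call(rbind, lapply(fold_vce, function(v) v$heritability))
  colMeans(h)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result> ", x$k, "-fold predictive ability ",
      format(round(x$accuracy, 4)), " (sd ", format(round(x$sd, 4)), ")\n",
      sep = "")
  invisible(x)
}

#' Percent accuracy change of one model over a baseline
#'
#' @param r_model,r_base Predictive abilities (mean fold correlations).
#' @param digits Rounding for reporting (default 2, the convention for
#'   percent columns in accuracy tables).
#' @return `100 * (r_model - r_base) / r_base`, rounded.
#' @export
percent_change <- function(r_model, r_base, digits = 2) {
  if (any(r_base == 0)) stop("baseline accuracy is 0; percent change undefined")
  round(100 * (r_model - r_base) / r_base, digits)
}

#' Initial model selection by the heritability threshold
#'
#' From a full-model fit (all SNP and epistasis effect types to fourth
#' order), retain the effect types whose heritability estimate is strictly
#' greater than `threshold` (default 0.01, i.e. 1%).
#'
#' @param full_vce A `vc_estimate` from the full model, or a named numeric
#'   vector of per-type heritabilities.
#' @param threshold Strict lower bound on the heritability estimate.
#' @return A [model_spec()] of the retained effect types (in input order).
#' @export
initial_model_selection <- function(full_vce, threshold = 0.01) {
  h2 <- if (inherits(full_vce, "vc_estimate")) full_vce$heritability else {
    stopifnot(is.numeric(full_vce), !is.null(names(full_vce)))
    full_vce
  }
  keep <- names(h2)[h2 > threshold]
  if (!length(keep))
    stop("no effect type exceeds the ", threshold,
         " heritability threshold; empty model")
  model_spec(keep)
}

#' Final model selection by cross-validated accuracy
#'
#' Among candidate models evaluated under the same fold assignment, select
#' the one with the highest mean predictive ability; ties are broken by the
#' smallest number of effect types, then by earliest effect-type subscript
#' order (so the comparison is deterministic).
#'
#' @param candidates List of [model_spec()]s.
#' @param cv_results List of [cross_validate()] results, parallel to
#'   `candidates`.
#' @param digits Accuracies are compared after rounding to this many decimals
#'   (default 3, the reporting precision of prediction-accuracy tables); two
#'   models whose accuracies agree at that precision are treated as tied, and
#'   the smaller model wins.
#' @return The selected `model_spec`, with attributes `accuracy` and
#'   `candidate_index`.
#' @export
final_model_selection <- function(candidates, cv_results, digits = 3) {
  stopifnot(length(candidates) == length(cv_results), length(candidates) >= 1L)
  acc <- vapply(cv_results, function(r) r$accuracy, 0)
  sizes <- vapply(candidates, function(m) length(m$effect_types), 0L)
  subs <- vapply(candidates, function(m)
    paste(sprintf("%02d", vapply(m$effect_types, function(e) e$subscript, 0L)),
          collapse = ""), "")
  ord <- order(-round(acc, digits), sizes, subs)
  best <- ord[1L]
  out <- candidates[[best]]
  attr(out, "accuracy") <- acc[best]
  attr(out, "candidate_index") <- best
  out
}

#' Candidate models for the final selection stage
#'
#' The initial model's first-order types (A, D) are kept in every candidate;
#' the remaining (epistasis/haplotype) types are varied so the final stage
#' can discard effect types that passed the heritability threshold but do
#' not improve the cross-validated accuracy.  Two schemes:
#' `"prefix"` (default) nests candidates in effect-type subscript order —
#' the base model, then the base plus the first retained epistasis type, and
#' so on up to the full initial model (the structure of published
#' model-comparison tables, and linear in the number of types);
#' `"subsets"` enumerates every subset of the non-first-order types
#' (exhaustive, exponential — guarded).
#'
#' @param initial A [model_spec()] from [initial_model_selection()].
#' @param scheme `"prefix"` or `"subsets"`.
#' @param max_candidates Error guard on the subset explosion (default 64).
#' @return List of `model_spec`s ordered by size.
#' @export
candidate_models <- function(initial, scheme = c("prefix", "subsets"),
                             max_candidates = 64L) {
  stopifnot(inherits(initial, "model_spec"))
  scheme <- match.arg(scheme)
  first <- initial$labels[vapply(initial$effect_types,
                                 function(e) !e$is_haplotype && e$order == 1L,
                                 TRUE)]
  if (!length(first))
    stop("initial model has no first-order effect type")
  rest <- setdiff(initial$labels, first)
  subsets <- if (scheme == "prefix") {
    lapply(0:length(rest), function(k) rest[seq_len(k)])
  } else {
    if (length(rest) > log2(max_candidates))
      stop("too many candidate subsets (", 2^length(rest),
           "); use scheme = 'prefix' or prune the initial model")
    out <- list(character())
    for (r in rest) out <- c(out, lapply(out, function(s) c(s, r)))
    out
  }
  cands <- lapply(subsets, function(s)
    model_spec(intersect(initial$labels, c(first, s))))
  sizes <- vapply(cands, function(m) length(m$labels), 0L)
  cands[order(sizes)]
}

#' Build the relationship matrices a model needs
#'
#' Convenience constructor used by the cross-validation pipeline and the
#' analysis scripts: first-order, exact (or Hadamard) epistasis, and
#' haplotype GRMs for every effect type of `model`, from one genotype panel.
#'
#' @param model A [model_spec()].
#' @param gd A [genotype_data()].
#' @param blocks A [block_definition()]; required when the model contains
#'   `H`.
#' @param method `"exact"` (default) or `"hadamard"` for the epistasis types.
#' @return Named list of `grm`s in model order.
#' @export
build_model_grms <- function(model, gd, blocks = NULL,
                             method = c("exact", "hadamard")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "model_spec"))
  need_add <- any(vapply(model$effect_types,
                         function(e) !e$is_haplotype && e$n_additive > 0, TRUE))
  need_dom <- any(vapply(model$effect_types,
                         function(e) !e$is_haplotype && e$n_dominance > 0, TRUE))
  W <- if (need_add) center_additive(gd) else NULL
  H <- if (need_dom) center_dominance(gd) else NULL
  gA <- gD <- NULL
  if (method == "hadamard") {
    if (need_add) gA <- grm_first_order(W)
    if (need_dom) gD <- grm_first_order(H)
  }
  out <- list()
  for (et in model$effect_types) {
    g <- if (et$is_haplotype) {
      if (is.null(blocks)) stop("model contains H but no block definition given")
      grm_haplotype(enumerate_haplotypes(gd, blocks))
    } else if (et$order == 1L) {
      grm_first_order(if (et$n_additive == 1L) W else H)
    } else if (method == "exact") {
      grm_epistasis_exact(et, W, H)
    } else {
      grm_epistasis_hadamard(et, gA, gD)
    }
    out[[et$label]] <- g
  }
  out
}
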