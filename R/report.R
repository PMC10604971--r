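#' Assemble the standard report tables
#'
#' Produces the three conventional summaries of a multifactorial prediction
#' study: (1) full-model heritability partitioning with the initial model it
#' implies, (2) cross-validated accuracy per candidate model with percent
#' increase over a baseline (usually the SNP model `A+D`), and (3)
#' fold-averaged per-type heritabilities for each evaluated model.
#'
#' @param cv_results Named list of [cross_validate()] results; names are the
#'   model strings (e.g. `"A+D"`, `"A+D+AA"`).
#' @param full_vce Optional full-model `vc_estimate` for table (1).
#' @param base Name of the baseline model inside `cv_results` (default
#'   `"A+D"`); if absent the accuracy-increase column is omitted with a
#'   warning.
#' @param threshold Heritability threshold for the initial-model line.
#' @param out_dir Optional directory; when given, each table is written as a
#'   TSV (`heritability.tsv`, `accuracy.tsv`, `fold_heritability.tsv`).
#' @return List of data frames `heritability` (or NULL), `accuracy`,
#'   `fold_h2`.
#' @export
make_report <- function(cv_results, full_vce = NULL, base = "A+D",
                        threshold = 0.01, out_dir = NULL) {
  stopifnot(is.list(cv_results), !is.null(names(cv_results)))
  herit <- NULL
  if (!is.null(full_vce)) {
    herit <- heritability_table(full_vce)
    initial <- tryCatch(format(initial_model_selection(full_vce, threshold)),
                        error = function(e) "(none)")
    herit <- rbind(herit,
                   data.frame(effect_type = "Initial model", h2 = NA))
    attr(herit, "initial_model") <- initial
    herit$note <- c(rep("", nrow(herit) - 1L), initial)
  }
  acc <- data.frame(
    model = names(cv_results),
    accuracy = round(vapply(cv_results, function(r) r$accuracy, 0), 3),
    sd = round(vapply(cv_results, function(r) r$sd, 0), 3))
  if (base %in% names(cv_results)) {
    acc$increase_over_base_pct <-
      percent_change(acc$accuracy, acc$accuracy[acc$model == base])
  } else {
    warning("baseline model '", base,
            "' not among the results; increase column omitted")
  }
  fold_h2 <- do.call(rbind, lapply(names(cv_results), function(nm) {
    h <- cv_results[[nm]]$mean_h2
    data.frame(model = nm, effect_type = c(names(h), "Total"),
               h2 = round(c(h, sum(h)), 3))
  }))
  rownames(acc) <- rownames(fold_h2) <- NULL
  out <- list(heritability = herit, accuracy = acc, fold_h2 = fold_h2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(herit))
      utils::write.table(herit, file.path(out_dir, "heritability.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(acc, file.path(out_dir, "accuracy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fold_h2, file.path(out_dir, "fold_heritability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
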