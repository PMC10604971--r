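#!/usr/bin/env Rscript
# 10-fold cross-validation of the candidate epistasis models (nested prefixes
# of the initial model), accuracy relative to the SNP model, and final model
# selection.
source(file.path("analysis", "_common.R"))

ch <- load_cohort()
init <- model_spec(readLines(file.path(TABLE_DIR, "initial_model.txt")))
cands <- candidate_models(init)
# the SNP model A + D is the conventional baseline; prepend it if the
# initial model's first-order part differs
if (!any(vapply(cands, format, "") == "A+D"))
  cands <- c(list(model_spec("A+D")), cands)

labs_needed <- unique(unlist(lapply(cands, function(m) m$labels)))
grms <- lapply(labs_needed, function(l) read_grm(file.path(GRM_DIR, l)))
names(grms) <- labs_needed

folds <- make_folds(ch$gd$sample_ids, k = 10, seed = CV_SEED)
cat("Folds:", paste(folds$fold_sizes, collapse = ", "), "\n\n")

cv_results <- list()
for (m in cands) {
  key <- format(m)
  cat("cross-validating", key, "... ")
  warm <- fit_greml(ch$pt$y, ch$X, grms[m$labels], max_iter = 100)
  cv_results[[key]] <- cross_validate(
    ch$pt$y, ch$X, grms[m$labels], folds,
    reml_opts = list(start = pmax(c(warm$sigma2, warm$sigma2_e),
                                  1e-4 * var(ch$pt$y)),
                     max_iter = 50))
  cat(sprintf("accuracy %.3f (sd %.3f)\n",
              cv_results[[key]]$accuracy, cv_results[[key]]$sd))
}

final <- final_model_selection(cands, cv_results[vapply(cands, format, "")],
                               digits = 2)
cat("\nFinal epistasis model (highest accuracy, fewest types):",
    format(final), "\n")
writeLines(format(final), file.path(TABLE_DIR, "final_epistasis_model.txt"))

rep <- make_report(cv_results, base = "A+D", out_dir = TABLE_DIR)
cat("\nAccuracy table (written to", file.path(TABLE_DIR, "accuracy.tsv"),
    "):\n")
print(rep$accuracy, row.names = FALSE)
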