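test_that("fold assignment follows the floor(n/k) + remainder rule", {
  fa <- make_folds(paste0("i", 1:7564), k = 10, seed = 3)
  expect_equal(fa$fold_sizes, c(rep(756L, 9), 760L))
  expect_equal(sort(unique(fa$fold)), 1:10)
  expect_equal(as.integer(table(fa$fold)), fa$fold_sizes)

  fa2 <- make_folds(paste0("i", 1:10), k = 10, seed = 1)
  expect_equal(fa2$fold_sizes, rep(1L, 10))

  # seeded determinism
  fa3 <- make_folds(paste0("i", 1:100), seed = 11)
  fa4 <- make_folds(paste0("i", 1:100), seed = 11)
  fa5 <- make_folds(paste0("i", 1:100), seed = 12)
  expect_identical(fa3$fold, fa4$fold)
  expect_false(identical(fa3$fold, fa5$fold))
})

test_that("predictive ability is the mean of per-fold correlations", {
  withr::with_seed(21, {
    n <- 120
    gd <- make_gd(n = n, m = 60, seed = 22)
    gA <- grm_first_order(center_additive(gd))
    u <- drop(t(chol(gA$matrix + 1e-8 * diag(n))) %*% rnorm(n))
    y <- u + rnorm(n, 0, 0.5)
    X <- matrix(1, n, 1)
    folds <- make_folds(gd$sample_ids, k = 4, seed = 2)
    pr <- cross_validate(y, X, list(gA), folds)
    expect_equal(pr$accuracy, mean(pr$fold_cor))
    expect_equal(pr$sd, sd(pr$fold_cor))
    expect_false(anyNA(pr$predictions)) # everyone predicted exactly once
    # the pooled correlation is a different statistic on heterogeneous folds
    pooled <- cor(pr$predictions, y)
    expect_false(isTRUE(all.equal(pooled, pr$accuracy, tolerance = 1e-6)))
    expect_gt(pr$accuracy, 0)
  })
})

test_that("percent accuracy change reproduces published table arithmetic", {
  expect_equal(percent_change(0.297, 0.290), 2.41)
  expect_equal(percent_change(0.243, 0.234), 3.85)
  expect_equal(percent_change(0.208, 0.213), -2.35)
  expect_equal(percent_change(0.299, 0.290), 3.10)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_error(percent_change(0.1, 0), "undefined")
})

test_that("initial selection keeps effect types with heritability over 1%", {
  hdl <- c(A = 0.241, D = 0.055, AA = 0.356, AD = 0.111, DD = 0.001,
           AAA = 0.002, AAD = 0.002, ADD = 0, DDD = 0,
           AAAA = 0, AAAD = 0, AADD = 0, ADDD = 0, DDDD = 0)
  expect_equal(initial_model_selection(hdl)$labels, c("A", "D", "AA", "AD"))
  wt <- c(A = 0.424, D = 0.071, AA = 0.106, AD = 0.057, DD = 0.015,
          AAA = 0.017, AAD = 0.014, ADD = 0.008, DDD = 0.004,
          AAAA = 0.004, AAAD = 0.003, AADD = 0.002, ADDD = 0.001,
          DDDD = 0.001)
  expect_equal(initial_model_selection(wt)$labels,
               c("A", "D", "AA", "AD", "DD", "AAA", "AAD"))
  # the threshold is strict: exactly 0.01 is excluded
  expect_equal(initial_model_selection(c(A = 0.5, D = 0.01))$labels, "A")
  expect_error(initial_model_selection(c(A = 0.005, D = 0.005)), "empty")
})

test_that("final selection prefers accuracy, then fewer types, then order", {
  fake_cv <- function(acc) structure(list(accuracy = acc),
                                     class = "prediction_result")
  cands <- list(model_spec("A+D+AD"), model_spec("A+D+AD+DD"))
  best <- final_model_selection(cands, list(fake_cv(0.325), fake_cv(0.325)))
  expect_equal(format(best), "A+D+AD")

  expect_equal(format(final_model_selection(list(model_spec("A")),
                                            list(fake_cv(0.1)))), "A")
  # exact tie in accuracy and size: earlier subscript order wins
  cands2 <- list(model_spec("A+DD"), model_spec("A+AA"))
  best2 <- final_model_selection(cands2, list(fake_cv(0.2), fake_cv(0.2)))
  expect_equal(format(best2), "A+AA")
  # a real accuracy difference at the comparison precision dominates
  best3 <- final_model_selection(cands, list(fake_cv(0.320), fake_cv(0.325)))
  expect_equal(format(best3), "A+D+AD+DD")
})

test_that("candidate models nest the initial model's epistasis types", {
  init <- model_spec("A+D+AA+AD")
  cands <- candidate_models(init)
  expect_equal(vapply(cands, format, ""),
               c("A+D", "A+D+AA", "A+D+AA+AD"))
  subs <- candidate_models(init, scheme = "subsets")
  expect_length(subs, 4L)
  expect_true("A+D+AD" %in% vapply(subs, format, ""))
  expect_error(candidate_models(model_spec("AA")), "no first-order")
})

test_that("report tables have the published shapes", {
  fake_cv <- function(acc, h2) structure(
    list(accuracy = acc, sd = 0.01, mean_h2 = h2),
    class = "prediction_result")
  res <- list(
    "A+D" = fake_cv(0.290, c(A = 0.386, D = 0.124)),
    "A+D+AA+AD" = fake_cv(0.297, c(A = 0.243, D = 0.056, AA = 0.358,
                                   AD = 0.115)))
  rep <- make_report(res)
  expect_equal(rep$accuracy$increase_over_base_pct, c(0, 2.41))
  expect_equal(rep$fold_h2$h2[rep$fold_h2$model == "A+D" &
                                rep$fold_h2$effect_type == "Total"], 0.51)
  expect_warning(make_report(res, base = "A"), "not among")
  out <- withr::local_tempdir()
  rep2 <- make_report(res, out_dir = out)
  expect_true(file.exists(file.path(out, "accuracy.tsv")))
})
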