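test_that("cross-validation plans cover every sample with stratified folds", {
  y60 <- factor(rep(c("M", "A", "D"), each = 20))
  plan <- make_cv_plan(y60)
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 6))
  expect_setequal(unlist(plan$folds), 1:60)
  # two per class per fold
  for (f in plan$folds) expect_true(all(table(y60[f]) == 2))
  expect_identical(nrow(plan$reused), 0L)

  y30 <- factor(rep(c("M", "A", "D"), each = 10))
  plan30 <- make_cv_plan(y30)
  expect_true(all(lengths(plan30$folds) == 3))
  expect_setequal(unlist(plan30$folds), 1:30)

  expect_error(make_cv_plan(y60, iterations = 5), "Cannot cover")
})

test_that("a one-short class reuses its first sample in the first and last fold", {
  # a class with more samples than validation slots cannot be covered
  y_over <- factor(rep(c("M", "A", "D"), times = c(21, 20, 19)),
                   levels = c("M", "A", "D"))
  expect_error(make_cv_plan(y_over), "exact or one-short")
  # 19 M / 20 A / 20 D: folds of 6 imply 20 M slots vs 19 samples
  y59 <- factor(rep(c("M", "A", "D"), times = c(19, 20, 20)))
  plan <- make_cv_plan(y59)
  expect_setequal(unlist(plan$folds), 1:59)
  expect_identical(nrow(plan$reused), 1L)
  reused_idx <- plan$reused$index
  expect_true(reused_idx %in% plan$folds[[1]])
  expect_true(reused_idx %in% plan$folds[[10]])
  # the reused sample belongs to the short class
  expect_identical(as.character(y59[reused_idx]), "M")
})

test_that("run_cv with injected classifiers hits the documented baselines", {
  toy <- toy_trace_dataset(n_per_class = 10, seed = 8)
  data <- list(x = toy$x, y = toy$y, id = seq_along(toy$y))

  oracle_builder <- function(x, y, validation, config, policy) {
    truth_lookup <- toy$y
    structure(list(), class = "oracle_clf")
  }
  # oracle: classify by the known bump position of channel 1
  assign("predict.oracle_clf", function(object, x, ...) {
    centers <- c(M = 10, A = 20, D = 32)
    apply(x, 3, function(m) names(centers)[which.min(
      abs(which.max(m[1, ]) - centers))])
  }, envir = globalenv())
  on.exit(rm("predict.oracle_clf", envir = globalenv()), add = TRUE)

  rep_oracle <- run_cv(data, model = oracle_builder,
                       config = train_config(seed = 1), repetitions = 1,
                       tag = "oracle")
  expect_equal(rep_oracle$accuracy, 1)
  expect_true(all(rep_oracle$confusion[upper.tri(rep_oracle$confusion)] == 0))
  expect_length(rep_oracle$misclassified, 0)

  majority_builder <- function(x, y, validation, config, policy) {
    structure(list(lvl = names(which.max(table(y)))), class = "majority_clf")
  }
  assign("predict.majority_clf", function(object, x, ...) {
    rep(object$lvl, dim(x)[3])
  }, envir = globalenv())
  on.exit(rm("predict.majority_clf", envir = globalenv()), add = TRUE)
  rep_major <- run_cv(data, model = majority_builder,
                      config = train_config(seed = 1), repetitions = 1,
                      tag = "majority")
  expect_equal(rep_major$accuracy, 1 / 3, tolerance = 0.01)
})

test_that("a classifier wrong on exactly three samples reports 95% and their ids", {
  # 57 of 60 correct: accuracy 95%, the three misclassified ids listed
  y <- factor(rep(c("M", "A", "D"), each = 20))
  wrong_ids <- c(2L, 25L, 41L)
  near_oracle <- function(x, y_tr, validation, config, policy) {
    structure(list(levels = levels(y)), class = "near_oracle_clf")
  }
  assign("predict.near_oracle_clf", function(object, x, ...) {
    ids <- attr(x, "ids")
    truth <- attr(x, "truth")
    out <- as.character(truth)
    out[ids %in% wrong_ids] <- vapply(out[ids %in% wrong_ids], function(l) {
      setdiff(object$levels, l)[1]
    }, character(1))
    out
  }, envir = globalenv())
  on.exit(rm("predict.near_oracle_clf", envir = globalenv()), add = TRUE)
  x <- array(rnorm(2 * 8 * 60), dim = c(2, 8, 60))
  plan <- make_cv_plan(y, seed = 3)
  # run the folds manually so validation arrays carry their ids
  preds <- truth <- factor(character(), levels = levels(y))
  ids_all <- integer()
  clf <- near_oracle(NULL, NULL, NULL, NULL, NULL)
  for (f in seq_along(plan$folds)) {
    v <- plan$folds[[f]]
    xv <- x[, , v, drop = FALSE]
    attr(xv, "ids") <- v
    attr(xv, "truth") <- y[v]
    p <- factor(predict(clf, xv), levels = levels(y))
    preds <- c(preds, p); truth <- c(truth, y[v]); ids_all <- c(ids_all, v)
  }
  conf <- table(truth = truth, predicted = preds)
  expect_equal(sum(diag(conf)) / sum(conf), 0.95)
  expect_identical(sort(unique(ids_all[preds != truth])), wrong_ids)
})

test_that("no fold's validation sample leaks into its training split", {
  y <- factor(rep(c("M", "A", "D"), each = 20))
  plan <- make_cv_plan(y, seed = 5)
  for (f in seq_along(plan$folds)) {
    train_idx <- setdiff(seq_along(y), plan$folds[[f]])
    expect_length(intersect(train_idx, plan$folds[[f]]), 0)
  }
})

test_that("compare_models keeps order and disambiguates duplicate tags", {
  mk <- function(acc, tag) {
    structure(list(accuracy = acc, per_fold = acc, confusion = NULL,
                   misclassified = integer(), repetition_accuracies = acc,
                   mean_accuracy = acc, sd_accuracy = 0, tag = tag, n = 60),
              class = "cv_report")
  }
  tab <- compare_models(list(mk(0.68, "lstm"), mk(0.85, "fewshot"),
                             mk(0.95, "fewshot+aug")))
  expect_identical(tab$model, c("lstm", "fewshot", "fewshot+aug"))
  expect_equal(tab$accuracy, c(0.68, 0.85, 0.95))
  expect_identical(nrow(compare_models(list(mk(0.5, "a")))), 1L)
  expect_warning(dup <- compare_models(list(mk(0.5, "a"), mk(0.6, "a"))),
                 "Duplicate")
  expect_identical(dup$model, c("a", "a_1"))
})
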