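#' Assemble a classifier-ready feature dataset
#'
#' Runs the eight-trace feature stack over every recording of a dataset
#' and aligns each stack to a fixed-length channel matrix, yielding the
#' array consumed by both classifiers.
#'
#' @param dataset An `ssi_dataset` from [simulate_phoneme_dataset()] (or
#'   assembled from read recordings).
#' @param length_out Aligned trace length (default 128).
#' @param window Optional [window_spec()] for the correlation traces.
#' @param on `"envelope"` or `"raw"` correlation basis.
#' @return A `feature_dataset`: list with `x` (array traces x length x n),
#'   `y` (factor), `id`, `subject`.
#' @export
as_feature_dataset <- function(dataset, length_out = 128, window = NULL,
                               on = "envelope") {
  stopifnot(inherits(dataset, "ssi_dataset"))
  mats <- lapply(dataset$recordings, function(rec) {
    stack_matrix(phoneme_feature_stack(rec, window = window, on = on),
                 length_out = length_out)
  })
  x <- array(unlist(mats), dim = c(nrow(mats[[1]]), length_out, length(mats)))
  dimnames(x) <- list(rownames(mats[[1]]), NULL, NULL)
  structure(list(x = x, y = factor(dataset$index$label),
                 id = dataset$index$id, subject = dataset$index$subject),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples x %d traces x %d points\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2]))
  invisible(x)
}

#' Build a cross-validation plan
#'
#' Folds hold `round(fraction * n)` samples each, assembled stratified by
#' class; over the `iterations` folds every sample appears in at least one
#' validation fold. When a class has exactly one sample fewer than needed
#' for disjoint coverage, its first sample is reused in the first and
#' last fold and the reuse is recorded.
#'
#' @param y Factor of class labels (length n).
#' @param fraction Validation fraction per fold (default 0.10).
#' @param iterations Number of folds (default 10).
#' @param seed Shuffling seed.
#' @return A `cv_plan`: list with `folds` (list of index vectors),
#'   `fold_size`, `reused` (tibble of reused samples).
#' @export
#' @examples
#' plan <- make_cv_plan(factor(rep(c("M", "A", "D"), each = 20)))
#' lengths(plan$folds)  # ten folds of six
make_cv_plan <- function(y, fraction = 0.10, iterations = 10, seed = 1) {
  y <- as.factor(y)
  n <- length(y)
  fold_size <- as.integer(round(fraction * n))
  if (fold_size < 1L) abort("`fraction * n` must be at least 1.")
  if (fold_size * iterations < n) {
    abort(sprintf(
      "Cannot cover all %d samples with %d folds of %d: increase iterations.",
      n, iterations, fold_size))
  }
  counts <- table(y)
  per_fold <- round(fold_size * counts / n)
  if (sum(per_fold) != fold_size) {
    abort("Class proportions do not divide the fold size evenly.")
  }
  folds <- replicate(iterations, integer(), simplify = FALSE)
  reused <- list()
  with_seed(seed, {
    for (cl in levels(y)) {
      slots <- per_fold[[cl]] * iterations
      idx <- sample(which(y == cl))
      if (length(idx) == slots) {
        seq_idx <- idx
      } else if (length(idx) == slots - 1L) {
        seq_idx <- c(idx, idx[1])
        reused[[cl]] <- tibble::tibble(class = cl, index = idx[1],
                                       folds = list(c(1L, iterations)))
      } else {
        abort(sprintf(
          "Class '%s' has %d samples but %d validation slots; only exact or one-short coverage is supported.",
          cl, length(idx), slots))
      }
      for (f in seq_len(iterations)) {
        take <- seq_idx[((f - 1L) * per_fold[[cl]] + 1L):(f * per_fold[[cl]])]
        folds[[f]] <- c(folds[[f]], take)
      }
    }
  })
  structure(list(folds = lapply(folds, sort), fold_size = fold_size,
                 fraction = fraction, iterations = iterations,
                 n = n, reused = dplyr::bind_rows(reused), seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds of %d over %d samples%s\n",
              x$iterations, x$fold_size, x$n,
              if (nrow(x$reused)) sprintf(" (%d reused)", nrow(x$reused))
              else ""))
  invisible(x)
}

fit_and_predict <- function(model, x, y, train_idx, val_idx, config, policy,
                            spec, k, n_trials, trial_epochs) {
  xtr <- x[, , train_idx, drop = FALSE]
  ytr <- y[train_idx]
  xval <- x[, , val_idx, drop = FALSE]
  yval <- y[val_idx]
  validation <- list(x = xval, y = yval)
  if (is.function(model)) {
    fit <- model(xtr, ytr, validation, config, policy)
    pred <- predict(fit, xval)
  } else if (model == "fewshot") {
    spec <- spec %||% embedding_net_spec()
    refs <- select_references(xtr, ytr, k = k, n_trials = n_trials,
                              spec = spec, config = config,
                              trial_epochs = trial_epochs)
    fit <- train_few_shot(xtr, ytr, refs, spec = spec, config = config,
                          validation = validation, policy = policy,
                          quiet = TRUE)
    pred <- predict(fit, xval)
  } else if (model == "lstm") {
    spec <- spec %||% lstm_spec(n_classes = nlevels(y))
    fit <- train_lstm(xtr, ytr, spec = spec, config = config,
                      validation = validation, policy = policy)
    pred <- predict(fit, xval)
  } else {
    abort(sprintf("Unknown model '%s'.", model))
  }
  if (is.data.frame(pred)) pred <- pred$label
  factor(as.character(pred), levels = levels(y))
}

run_single_cv <- function(x, y, plan, model, config, policy, spec,
                          k, n_trials, trial_epochs, ids) {
  truth_all <- factor(character(), levels = levels(y))
  pred_all <- truth_all
  id_all <- integer()
  per_fold <- numeric(plan$iterations)
  for (f in seq_len(plan$iterations)) {
    val_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(y), val_idx)
    cfg <- config
    cfg$seed <- child_seed(config$seed, 500 + f)
    pred <- fit_and_predict(model, x, y, train_idx, val_idx, cfg, policy,
                            spec, k, n_trials, trial_epochs)
    truth <- y[val_idx]
    per_fold[f] <- mean(pred == truth)
    truth_all <- c(truth_all, truth)
    pred_all <- c(pred_all, pred)
    id_all <- c(id_all, ids[val_idx])
  }
  confusion <- table(truth = truth_all, predicted = pred_all)
  list(per_fold = per_fold,
       accuracy = sum(diag(confusion)) / sum(confusion),
       confusion = confusion,
       misclassified = sort(unique(id_all[pred_all != truth_all])))
}

#' Run the cross-validation protocol
#'
#' Trains a fresh model per fold (augmentation applied to the training
#' split only), pools validation predictions into an accuracy and a
#' confusion matrix, and repeats the whole procedure `repetitions` times
#' with reshuffled fold assignments (default 3), reporting the best
#' repetition alongside the mean and SD over repetitions.
#'
#' @param data A `feature_dataset` (or list with `x`, `y`, optional `id`).
#' @param model `"fewshot"`, `"lstm"`, or a builder
#'   `function(x, y, validation, config, policy)` returning an object with
#'   a `predict(object, x)` method.
#' @param config A [train_config()].
#' @param policy Optional [augmentation_policy()]; applied to training
#'   folds only.
#' @param spec Optional model spec ([embedding_net_spec()] or
#'   [lstm_spec()]).
#' @param plan Optional [make_cv_plan()]; built from `fraction` and
#'   `iterations` when omitted (and rebuilt, reshuffled, per repetition).
#' @param fraction,iterations Plan parameters when `plan` is omitted.
#' @param repetitions Shuffled repetitions of the whole CV (default 3).
#' @param k,n_trials,trial_epochs Few-shot reference-selection settings.
#' @param tag Model tag used in reports.
#' @return A `cv_report`: the best repetition's `accuracy`, `per_fold`,
#'   `confusion`, `misclassified`, plus `repetition_accuracies`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
run_cv <- function(data, model = "fewshot", config = train_config(),
                   policy = NULL, spec = NULL, plan = NULL,
                   fraction = 0.10, iterations = 10, repetitions = 3,
                   k = 3, n_trials = 4, trial_epochs = 30,
                   tag = if (is.function(model)) "custom" else model) {
  x <- data$x
  y <- as.factor(data$y)
  ids <- data$id %||% seq_along(y)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(y))
  reps <- lapply(seq_len(repetitions), function(r) {
    p <- plan %||% make_cv_plan(y, fraction = fraction,
                                iterations = iterations,
                                seed = child_seed(config$seed, 900 + r))
    cfg <- config
    cfg$seed <- child_seed(config$seed, 950 + r)
    run_single_cv(x, y, p, model, cfg, policy, spec, k, n_trials,
                  trial_epochs, ids)
  })
  accs <- vapply(reps, `[[`, numeric(1), "accuracy")
  best <- reps[[which.max(accs)]]
  structure(list(accuracy = best$accuracy, per_fold = best$per_fold,
                 confusion = best$confusion,
                 misclassified = best$misclassified,
                 repetition_accuracies = accs,
                 mean_accuracy = mean(accs), sd_accuracy = sd(accs),
                 tag = tag, n = length(y)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: best pooled accuracy %.1f%% (mean %.1f%% +/- %.1f%% over %d repetition(s))\n",
              x$tag, 100 * x$accuracy, 100 * x$mean_accuracy,
              100 * (x$sd_accuracy %||% 0), length(x$repetition_accuracies)))
  print(x$confusion)
  invisible(x)
}

#' @rdname tidy.ssi_fewshot_model
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$per_fold), accuracy = x$per_fold)
}

#' @rdname tidy.ssi_fewshot_model
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(model = x$tag, accuracy = x$accuracy,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy,
                 n = x$n, n_misclassified = length(x$misclassified))
}

#' Compare cross-validated models
#'
#' @param reports List of `cv_report` objects, in presentation order.
#' @return Tibble with one row per model: tag, best/mean/sd accuracy.
#'   Duplicate tags are suffixed with a warning.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 1L) abort("Need at least one report.")
  if (inherits(reports, "cv_report")) reports <- list(reports)
  tags <- vapply(reports, `[[`, character(1), "tag")
  if (anyDuplicated(tags)) {
    warn("Duplicate model tags; suffixing to keep rows distinct.")
    tags <- make.unique(tags, sep = "_")
  }
  purrr::map2_dfr(reports, tags, function(r, tg) {
    tibble::tibble(model = tg, accuracy = r$accuracy,
                   mean_accuracy = r$mean_accuracy,
                   sd_accuracy = r$sd_accuracy,
                   n_misclassified = length(r$misclassified))
  })
}

#' Plot per-fold cross-validation accuracies
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(tidy.cv_report(object),
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy", title = object$tag)
}

#' The package's scaled computational profile
#'
#' One place defining the problem sizes used by the worked examples, the
#' test suite and the acceptance script: the 500 Hz / 2 s low-rate
#' synthetic dataset, an 8 x 64 aligned feature stack, an embedding
#' network with a 64-point adaptive pooling stage and slim channels, an
#' LSTM sized to the 54-sample training folds (hidden 32, consuming the
#' full-length stack), and a shortened training schedule (Adam lr 1e-4 and
#' batch 16 as always; the full-scale defaults of [train_config()] and
#' [embedding_net_spec()] remain available for larger budgets). See the
#' methods vignette for the rationale behind each size.
#'
#' @param seed Seed threaded through data generation and training.
#' @return List with `synth` (a [phoneme_synth_config()]), `length_out`,
#'   `embedding` (an [embedding_net_spec()]), `lstm` (an [lstm_spec()]),
#'   `config` (a [train_config()]) and `trial_epochs`.
#' @export
scaled_profile <- function(seed = 1) {
  list(
    synth = phoneme_synth_config(seed = seed),
    length_out = 64L,
    embedding = embedding_net_spec(adaptive_pool_out = 64,
                                   channels = c(8, 8, 16, 16, 16, 16)),
    lstm = lstm_spec(hidden = 32, time_steps = NA),
    config = train_config(max_epochs = 120, patience = 40, seed = seed),
    trial_epochs = 6
  )
}
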