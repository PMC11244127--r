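test_that("the embedding network has nine blocks and length-invariant output", {
  spec <- tiny_embedding_spec()
  model <- build_embedding_net(spec, n_channels = 2, seed = 1)
  e1 <- embed_samples(model, matrix(rnorm(2 * 30), 2))
  e2 <- embed_samples(model, matrix(rnorm(2 * 75), 2))
  expect_identical(nrow(e1), spec$feature_dim)
  expect_identical(nrow(e2), spec$feature_dim)
  # identical seeds give identical initial parameters
  m2 <- build_embedding_net(spec, n_channels = 2, seed = 1)
  expect_identical(model$net$layers, m2$net$layers)
  # too-short input rejected at forward time
  expect_error(embed_samples(model, matrix(rnorm(2 * 2), 2)), "minimum")
  # an eight-block body spec is rejected
  expect_error(embedding_net_spec(kernels = rep(3, 5), channels = rep(4, 5)),
               "six blocks")
})

test_that("embedding length invariance holds over a 2x span of input lengths", {
  model <- build_embedding_net(tiny_embedding_spec(), n_channels = 2, seed = 3)
  for (len in c(40, 55, 80)) {
    expect_identical(dim(embed_samples(model, matrix(rnorm(2 * len), 2))),
                     c(4L, 1L))
  }
})

test_that("layer gradients match finite differences", {
  set.seed(42)
  spec <- tiny_embedding_spec()
  model <- build_embedding_net(spec, n_channels = 2, seed = 3)
  x <- array(rnorm(2 * 20 * 3), dim = c(2, 20, 3))
  Wt <- matrix(rnorm(spec$feature_dim * 3), spec$feature_dim, 3)
  loss_fn <- function(net) sum(silentspeech:::net_forward(net, x, TRUE)$out * Wt)
  fw <- silentspeech:::net_forward(model$net, x, TRUE)
  net <- silentspeech:::net_backward(fw$net, Wt)$net
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (length(l$params) == 0) next
    for (nm in names(l$params)) {
      p <- l$params[[nm]]
      for (ii in sample(length(p), min(2, length(p)))) {
        eps <- 1e-5
        n2 <- net
        n2$layers[[li]]$params[[nm]][ii] <- p[ii] + eps
        lp <- loss_fn(n2)
        n2$layers[[li]]$params[[nm]][ii] <- p[ii] - eps
        lm <- loss_fn(n2)
        g_num <- (lp - lm) / (2 * eps)
        expect_equal(l$grads[[nm]][ii], g_num, tolerance = 1e-4)
      }
    }
  }
})

test_that("LSTM gradients match finite differences", {
  set.seed(7)
  spec <- lstm_spec(hidden = 5, n_classes = 3, time_steps = NA)
  model <- silentspeech:::build_lstm(spec, d_in = 4, seed = 2)
  x <- array(rnorm(4 * 6 * 3), dim = c(4, 6, 3))
  y1 <- matrix(0, 3, 3); y1[cbind(1:3, 1:3)] <- 1
  loss_fn <- function(m) {
    silentspeech:::cross_entropy(silentspeech:::lstm_forward(m, x)$probs, y1)
  }
  fw <- silentspeech:::lstm_forward(model, x)
  grads <- silentspeech:::lstm_backward(model, fw, y1)
  for (blk in names(model$params)) {
    for (nm in names(model$params[[blk]])) {
      p <- model$params[[blk]][[nm]]
      for (ii in sample(length(p), min(3, length(p)))) {
        eps <- 1e-5
        m2 <- model
        m2$params[[blk]][[nm]][ii] <- p[ii] + eps
        lp <- loss_fn(m2)
        m2$params[[blk]][[nm]][ii] <- p[ii] - eps
        lm <- loss_fn(m2)
        expect_equal(grads[[blk]][[nm]][ii], (lp - lm) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("cosine similarity meets its axioms", {
  u <- c(1, 2, -3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), u[1:2]), "zero vector")
  expect_error(cosine_similarity(1:2, 1:3), "equal length")
})

test_that("contrastive loss evaluates its documented formula", {
  # optimum: positives at 1, negatives at or below the margin
  expect_equal(contrastive_loss(c(1, 1, -0.2, 0), c(TRUE, TRUE, FALSE, FALSE)),
               0)
  # hand toy: (1 - 0.5) + max(0, 0.5 - 0) = 1
  expect_equal(contrastive_loss(c(0.5, 0.5), c(TRUE, FALSE)), 1)
  # monotonicity: raising a positive similarity lowers the loss
  l1 <- contrastive_loss(c(0.2, 0.5), c(TRUE, FALSE))
  l2 <- contrastive_loss(c(0.6, 0.5), c(TRUE, FALSE))
  expect_lt(l2, l1)
  # permutation invariance within a batch
  s <- c(0.3, -0.1, 0.8, 0.4); m <- c(TRUE, FALSE, TRUE, FALSE)
  p <- c(3, 1, 4, 2)
  expect_equal(contrastive_loss(s, m), contrastive_loss(s[p], m[p]))
  expect_error(contrastive_loss(numeric(), logical()), "No similarity")
  expect_warning(contrastive_loss(c(0.5), c(TRUE)), "push term")
})

test_that("reference selection is seeded, sized and validated", {
  toy <- toy_trace_dataset(n_per_class = 5, seed = 2)
  cfg <- train_config(learning_rate = 1e-3, seed = 9)
  refs <- select_references(toy$x, toy$y, k = 3, n_trials = 2,
                            spec = tiny_embedding_spec(), config = cfg,
                            trial_epochs = 3)
  expect_identical(lengths(refs$indices), c(M = 3L, A = 3L, D = 3L))
  refs2 <- select_references(toy$x, toy$y, k = 3, n_trials = 2,
                             spec = tiny_embedding_spec(), config = cfg,
                             trial_epochs = 3)
  expect_identical(refs$indices, refs2$indices)
  expect_error(select_references(toy$x, toy$y, k = 25,
                                 spec = tiny_embedding_spec()),
               "fewer than k")
})

test_that("few-shot training converges on separable toy data and is reproducible", {
  toy <- toy_trace_dataset(n_per_class = 6, seed = 3)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 8, patience = 200,
                      max_epochs = 120, seed = 1)
  refs <- structure(list(indices = list(M = 1:3, A = 7:9, D = 13:15), k = 3,
                         classes = c("M", "A", "D")),
                    class = "reference_set")
  successes <- 0L
  for (s in 1:3) {
    cfg$seed <- s
    fit <- train_few_shot(toy$x, toy$y, refs, spec = tiny_embedding_spec(),
                          config = cfg, quiet = TRUE)
    acc <- mean(predict(fit, toy$x)$label == toy$y)
    if (acc == 1) successes <- successes + 1L
  }
  expect_gte(successes, 2L)
  # identical seeds and data give identical loss histories
  cfg$seed <- 5
  f1 <- train_few_shot(toy$x, toy$y, refs, spec = tiny_embedding_spec(),
                       config = cfg, quiet = TRUE)
  f2 <- train_few_shot(toy$x, toy$y, refs, spec = tiny_embedding_spec(),
                       config = cfg, quiet = TRUE)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts after `patience` epochs without improvement", {
  toy <- toy_trace_dataset(n_per_class = 4, seed = 5)
  # a min_delta no real improvement can clear: loss "never improves"
  # after epoch 1, so patience = 1 must stop training at epoch 2
  cfg <- train_config(learning_rate = 1e-4, patience = 1, max_epochs = 50,
                      min_delta = 1e9, seed = 2)
  refs <- structure(list(indices = list(M = 1:3, A = 5:7, D = 9:11), k = 3,
                         classes = c("M", "A", "D")),
                    class = "reference_set")
  val <- list(x = toy$x[, , c(4, 8, 12), drop = FALSE], y = toy$y[c(4, 8, 12)])
  fit <- train_few_shot(toy$x, toy$y, refs, spec = tiny_embedding_spec(),
                        config = cfg, validation = val, quiet = TRUE)
  expect_identical(nrow(fit$history), 2L)
})

test_that("few-shot prediction scores match a brute-force reference loop", {
  toy <- toy_trace_dataset(n_per_class = 4, seed = 6)
  refs <- structure(list(indices = list(M = 1:2, A = 5:6, D = 9:10), k = 2,
                         classes = c("M", "A", "D")),
                    class = "reference_set")
  cfg <- train_config(learning_rate = 1e-3, patience = 5, max_epochs = 5,
                      seed = 3)
  fit <- train_few_shot(toy$x, toy$y, refs, spec = tiny_embedding_spec(),
                        config = cfg, quiet = TRUE)
  pred <- predict(fit, toy$x)
  expect_true(all(as.matrix(pred[, -1]) >= -1 & as.matrix(pred[, -1]) <= 1))
  Er <- embed_samples(fit$model, fit$ref_x)
  for (i in sample(dim(toy$x)[3], 5)) {
    e <- embed_samples(fit$model, toy$x[, , i])
    brute <- vapply(refs$classes, function(cl) {
      cols <- which(as.character(fit$ref_y) == cl)
      mean(vapply(cols, function(j) cosine_similarity(e[, 1], Er[, j]),
                  numeric(1)))
    }, numeric(1))
    expect_equal(unlist(pred[i, -1]), brute, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_identical(as.character(pred$label[i]),
                     names(which.max(brute)))
  }
})

test_that("LSTM training meets its output and reproducibility contracts", {
  toy <- toy_trace_dataset(n_per_class = 6, seed = 4)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 8, patience = 200,
                      max_epochs = 150, seed = 1)
  spec <- lstm_spec(hidden = 12, time_steps = 20)
  successes <- 0L
  for (s in 1:3) {
    cfg$seed <- s
    fit <- train_lstm(toy$x, toy$y, spec = spec, config = cfg)
    pred <- predict(fit, toy$x)
    probs <- as.matrix(pred[, -1])
    expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
                 tolerance = 1e-9)
    if (mean(pred$label == toy$y) >= 0.9) successes <- successes + 1L
  }
  expect_gte(successes, 2L)
  cfg$seed <- 11
  f1 <- train_lstm(toy$x, toy$y, spec = spec, config = cfg)
  f2 <- train_lstm(toy$x, toy$y, spec = spec, config = cfg)
  expect_identical(f1$history, f2$history)
})
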