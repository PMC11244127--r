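#' Specification of the nine-block embedding network
#'
#' The few-shot classifier embeds an 8-trace sample into a length-64
#' feature vector with a nine-block 1D CNN: six body blocks of
#' convolution + tanh + batch normalization + pooling (the first block ends
#' in adaptive average pooling to a static length so the network is
#' invariant to input length; the remaining five halve the length with max
#' pooling), and a three-block fully connected head reducing to the
#' embedding. Per-block kernels and channels are free parameters.
#'
#' @param kernels Odd convolution kernel sizes for the six body blocks.
#' @param channels Output channels for the six body blocks.
#' @param adaptive_pool_out Static length after block 1 (default 1024;
#'   must be divisible by 32 so the five max-pool halvings stay exact).
#' @param head_dims Widths of the first two head blocks.
#' @param feature_dim Embedding length (default 64).
#' @param min_input_length Shortest admissible input; shorter samples are
#'   rejected at forward time.
#' @return An `embedding_net_spec`.
#' @export
embedding_net_spec <- function(kernels = c(7, 7, 5, 5, 3, 3),
                               channels = c(8, 16, 32, 64, 64, 64),
                               adaptive_pool_out = 1024,
                               head_dims = c(256, 128),
                               feature_dim = 64,
                               min_input_length = 16) {
  if (length(kernels) != 6L || length(channels) != 6L) {
    abort("The network body has exactly six blocks: supply 6 kernels and 6 channel widths.")
  }
  if (length(head_dims) != 2L) {
    abort("The head has exactly three blocks: supply 2 hidden widths (the third is `feature_dim`).")
  }
  adaptive_pool_out <- check_count(adaptive_pool_out, "adaptive_pool_out",
                                   min = 32L)
  if (adaptive_pool_out %% 32 != 0) {
    abort("`adaptive_pool_out` must be divisible by 32 (five max-pool halvings).")
  }
  structure(list(n_body_blocks = 6L, n_head_blocks = 3L,
                 kernels = as.integer(kernels),
                 channels = as.integer(channels),
                 adaptive_pool_out = adaptive_pool_out,
                 head_dims = as.integer(head_dims),
                 feature_dim = check_count(feature_dim, "feature_dim"),
                 min_input_length = check_count(min_input_length,
                                                "min_input_length", 2L)),
            class = "embedding_net_spec")
}

#' Build the embedding network
#'
#' @param spec An [embedding_net_spec()].
#' @param n_channels Number of input traces per sample (8 for the phoneme
#'   feature stack).
#' @param seed Seed for parameter initialization.
#' @return An `ssi_embedding_net`.
#' @export
build_embedding_net <- function(spec, n_channels = 8, seed = 1) {
  stopifnot(inherits(spec, "embedding_net_spec"))
  n_channels <- check_count(n_channels, "n_channels")
  with_seed(seed, {
    ch <- c(n_channels, spec$channels)
    layers <- list()
    for (b in 1:6) {
      layers <- c(layers, list(
        layer_conv1d(ch[b], ch[b + 1], spec$kernels[b]),
        layer_tanh(),
        layer_batchnorm(ch[b + 1]),
        if (b == 1) layer_adaptive_avgpool(spec$adaptive_pool_out)
        else layer_maxpool()
      ))
    }
    l_final <- spec$adaptive_pool_out %/% 32L
    flat <- spec$channels[6] * l_final
    layers <- c(layers, list(
      layer_flatten(),
      layer_dense(flat, spec$head_dims[1]), layer_tanh(),
      layer_dense(spec$head_dims[1], spec$head_dims[2]), layer_tanh(),
      layer_dense(spec$head_dims[2], spec$feature_dim)
    ))
    structure(list(net = list(layers = layers, t = 0), spec = spec,
                   n_channels = n_channels, seed = as.integer(seed)),
              class = "ssi_embedding_net")
  })
}

#' @export
print.ssi_embedding_net <- function(x, ...) {
  cat(sprintf("<ssi_embedding_net> 9 blocks, %d input trace(s) -> %d-d embedding, %s parameters\n",
              x$n_channels, x$spec$feature_dim,
              format(net_param_count(x$net), big.mark = ",")))
  invisible(x)
}

as_input_array <- function(x, n_channels, min_len) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1))
  d <- dim(x)
  if (length(d) != 3L || d[1] != n_channels) {
    abort(sprintf("Input must be (%d x length) traces.", n_channels))
  }
  if (d[2] < min_len) {
    abort(sprintf("Input length %d below the network minimum (%d).",
                  d[2], min_len))
  }
  x
}

#' Embed samples
#'
#' @param model An `ssi_embedding_net`.
#' @param x A traces-by-length matrix, or an array
#'   (traces, length, batch).
#' @return Matrix (feature_dim x batch) of embeddings.
#' @export
embed_samples <- function(model, x) {
  x <- as_input_array(x, model$n_channels, model$spec$min_input_length)
  net_forward(model$net, x, training = FALSE)$out
}

#' Cosine similarity between two vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("Vectors must have equal length.")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("Cosine similarity is undefined for a zero vector.")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Contrastive loss over reference similarities
#'
#' `L = mean over matching pairs of (1 - s) + mean over non-matching pairs
#' of max(0, s - margin)`: samples are pulled toward references with their
#' own label and pushed away from the rest. The minimum 0 is attained when
#' every matching similarity is 1 and every non-matching similarity is at
#' or below the margin.
#'
#' @param similarities Numeric vector of cosine similarities.
#' @param matches Logical vector: does the pair share a label?
#' @param margin Similarity above which non-matching pairs are penalized
#'   (default 0).
#' @return Scalar loss >= 0.
#' @export
#' @examples
#' contrastive_loss(c(0.5, 0.5), c(TRUE, FALSE))  # (1-0.5) + max(0, 0.5) = 1
contrastive_loss <- function(similarities, matches, margin = 0) {
  if (length(similarities) == 0L) abort("No similarity pairs supplied.")
  if (length(similarities) != length(matches)) {
    abort("`similarities` and `matches` must have equal length.")
  }
  pos <- similarities[matches]
  neg <- similarities[!matches]
  if (length(pos) == 0L) warn("No positive pairs in batch; pull term skipped.")
  if (length(neg) == 0L) warn("No negative pairs in batch; push term skipped.")
  loss <- 0
  if (length(pos)) loss <- loss + mean(1 - pos)
  if (length(neg)) loss <- loss + mean(pmax(0, neg - margin))
  loss
}

# Similarity matrix (queries x refs) with gradient plumbing.
# E: (d, nq + nr) embeddings, queries first.
cosine_block <- function(Eq, Er) {
  nq <- sqrt(colSums(Eq^2))
  nr <- sqrt(colSums(Er^2))
  S <- t(Eq) %*% Er / outer(nq, nr)
  list(S = S, nq = nq, nr = nr)
}

#' Training configuration
#'
#' Both classifiers train with Adam at learning rate 1e-4, batch size 16,
#' and early stopping with a patience of 250 epochs (training stops when
#' the validation loss has not improved for `patience` epochs; the
#' checkpoint from the lowest-validation-loss epoch is kept).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Samples per gradient step.
#' @param patience Epochs without validation-loss improvement tolerated
#'   before stopping.
#' @param max_epochs Hard cap on epochs.
#' @param margin Contrastive-loss margin (few-shot only).
#' @param min_delta Smallest loss decrease counted as an improvement by
#'   the early-stopping rule (default 0: any strict decrease counts).
#' @param seed Seed for shuffling, initialization and augmentation.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16,
                         patience = 250, max_epochs = 5000,
                         margin = 0, min_delta = 0, seed = 1) {
  structure(list(learning_rate = check_number(learning_rate, "learning_rate",
                                              min = 0, strict = TRUE),
                 batch_size = check_count(batch_size, "batch_size"),
                 patience = check_count(patience, "patience"),
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 margin = check_number(margin, "margin", min = -1),
                 min_delta = check_number(min_delta, "min_delta", min = 0),
                 seed = as.integer(seed)),
            class = "train_config")
}

ref_label_vector <- function(refs, y_levels) {
  factor(rep(refs$classes, each = refs$k), levels = y_levels)
}

#' Select few-shot reference samples
#'
#' Draws `n_trials` random k-per-class reference sets, short-trains the
#' network with each, and keeps the set that yields the smallest final
#' training loss. Fully reproducible given the seed.
#'
#' @param x Array (traces, length, n) of feature stacks.
#' @param y Factor of class labels, length n.
#' @param k Shots per class (default 3).
#' @param n_trials Random selections to try (default 4).
#' @param spec Embedding net spec.
#' @param config A [train_config()]; its seed drives the selection.
#' @param trial_epochs Short-training budget per trial.
#' @return A `reference_set`: `indices` (named list per class), `k`,
#'   `classes`, `trial_losses`.
#' @export
select_references <- function(x, y, k = 3, n_trials = 4,
                              spec = embedding_net_spec(),
                              config = train_config(), trial_epochs = 50) {
  y <- as.factor(y)
  k <- check_count(k, "k")
  counts <- table(y)
  short <- names(counts)[counts < k]
  if (length(short)) {
    abort(sprintf("Class(es) %s have fewer than k = %d samples.",
                  paste(short, collapse = ", "), k))
  }
  trials <- lapply(seq_len(n_trials), function(j) {
    idx <- with_seed(child_seed(config$seed, 7000 + j), {
      lapply(levels(y), function(cl) sample(which(y == cl), k))
    })
    names(idx) <- levels(y)
    refs <- structure(list(indices = idx, k = k, classes = levels(y)),
                      class = "reference_set")
    fit <- train_few_shot(x, y, refs, spec = spec,
                          config = train_config(
                            learning_rate = config$learning_rate,
                            batch_size = config$batch_size,
                            patience = trial_epochs,
                            max_epochs = trial_epochs,
                            margin = config$margin,
                            seed = child_seed(config$seed, 7100 + j)),
                          validation = NULL, quiet = TRUE)
    list(refs = refs, loss = utils::tail(fit$history$train_loss, 1),
         model = fit$model)
  })
  losses <- vapply(trials, `[[`, numeric(1), "loss")
  winner <- trials[[which.min(losses)]]
  best <- winner$refs
  best$trial_losses <- losses
  # full training resumes from the winning trial's short-trained network
  best$warm_start <- winner$model
  best
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d-shot, classes: %s\n", x$k,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Train the few-shot contrastive network
#'
#' Each batch is embedded together with the reference samples; the
#' contrastive loss pulls batch embeddings toward same-class reference
#' embeddings and pushes them from the rest, with gradients flowing
#' through both. Training stops when the validation loss has not improved
#' for `patience` epochs; the returned model is the checkpoint from the
#' lowest-validation-loss epoch.
#'
#' @param x Array (traces, length, n) of feature stacks.
#' @param y Factor labels, length n.
#' @param refs A `reference_set` (see [select_references()]); reference
#'   samples are excluded from the training queries.
#' @param spec Embedding net spec.
#' @param config A [train_config()].
#' @param validation Optional list(x, y) held-out split (disjoint from the
#'   training split); when `NULL`, the training loss drives early stopping.
#' @param policy Optional [augmentation_policy()] applied to training
#'   queries only, freshly per access.
#' @param quiet Suppress batch warnings from degenerate batches.
#' @return An `ssi_fewshot_model` with elements `model`, `refs`,
#'   `ref_x`, `history` (tibble), `best_epoch`, `config`.
#' @export
train_few_shot <- function(x, y, refs, spec = embedding_net_spec(),
                           config = train_config(), validation = NULL,
                           policy = NULL, quiet = FALSE) {
  y <- as.factor(y)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(y))
  ref_idx <- unlist(refs$indices, use.names = FALSE)
  ref_x <- x[, , ref_idx, drop = FALSE]
  ref_y <- factor(rep(refs$classes, vapply(refs$indices, length, integer(1))),
                  levels = levels(y))
  query_idx <- setdiff(seq_along(y), ref_idx)
  if (length(query_idx) == 0L) abort("No non-reference training samples.")
  if (!is.null(validation) && length(validation$y) == 0L) {
    abort("Validation split is empty.")
  }

  model <- if (!is.null(refs$warm_start)) {
    refs$warm_start
  } else {
    build_embedding_net(spec, n_channels = dim(x)[1],
                        seed = child_seed(config$seed, 11))
  }
  net <- model$net
  nr <- length(ref_idx)
  match_mat_for <- function(qy) outer(as.character(qy), as.character(ref_y), "==")

  eval_loss <- function(net, ex, ey) {
    E <- net_forward(net, abind3(ref_x, ex), training = FALSE)$out
    Er <- E[, seq_len(nr), drop = FALSE]
    Eq <- E[, -seq_len(nr), drop = FALSE]
    cb <- cosine_block(Eq, Er)
    contrastive_loss(as.vector(cb$S), as.vector(match_mat_for(ey)),
                     margin = config$margin)
  }

  history <- list()
  best <- list(loss = Inf, net = net_strip(net), epoch = 0L)
  wait <- 0L
  with_seed(child_seed(config$seed, 12), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(query_idx)
      batch_losses <- numeric()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- x[, , bi, drop = FALSE]
        if (!is.null(policy) && isTRUE(policy$enabled)) {
          for (j in seq_along(bi)) {
            xb[, , j] <- augment_traces(xb[, , j], policy)
          }
        }
        nb <- length(bi)
        fw <- net_forward(net, abind3(ref_x, xb), training = TRUE)
        net <- fw$net
        Er <- fw$out[, seq_len(nr), drop = FALSE]
        Eq <- fw$out[, -seq_len(nr), drop = FALSE]
        cb <- cosine_block(Eq, Er)
        M <- match_mat_for(y[bi])
        loss <- if (quiet) {
          suppressWarnings(contrastive_loss(as.vector(cb$S), as.vector(M),
                                            margin = config$margin))
        } else {
          contrastive_loss(as.vector(cb$S), as.vector(M),
                           margin = config$margin)
        }
        batch_losses <- c(batch_losses, loss)
        dS <- matrix(0, nb, nr)
        npos <- sum(M)
        nneg <- sum(!M)
        if (npos > 0) dS[M] <- -1 / npos
        if (nneg > 0) dS[!M] <- (cb$S[!M] > config$margin) / nneg
        gb <- cosine_grads(Eq, Er, cb, dS)
        dE <- cbind(gb$dEr, gb$dEq)
        net <- net_backward(net, dE)$net
        net <- net_adam_step(net, config$learning_rate)
      }
      train_loss <- mean(batch_losses)
      val_loss <- if (is.null(validation)) train_loss else {
        eval_loss(net, validation$x, validation$y)
      }
      history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss)
      if (val_loss < best$loss - (config$min_delta %||% 0) &&
          val_loss < best$loss) {
        best <- list(loss = val_loss, net = net_strip(net), epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$net <- best$net
  structure(list(model = model, refs = refs, ref_x = ref_x, ref_y = ref_y,
                 history = tibble::as_tibble(do.call(rbind, history)),
                 best_epoch = best$epoch, best_loss = best$loss,
                 config = config, levels = levels(y)),
            class = "ssi_fewshot_model")
}

# Gradient of the similarity block: exact dEq/dEr for dS.
cosine_grads <- function(Eq, Er, cb, dS) {
  inv <- 1 / outer(cb$nq, cb$nr)
  A <- dS * inv
  dEq <- Er %*% t(A) -
    Eq * matrix(rowSums(dS * cb$S) / cb$nq^2, nrow = nrow(Eq),
                ncol = ncol(Eq), byrow = TRUE)
  dEr <- Eq %*% A -
    Er * matrix(colSums(dS * cb$S) / cb$nr^2, nrow = nrow(Er),
                ncol = ncol(Er), byrow = TRUE)
  list(dEq = dEq, dEr = dEr)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

#' @export
print.ssi_fewshot_model <- function(x, ...) {
  cat(sprintf("<ssi_fewshot_model> %d-shot, best epoch %d (val loss %.4f), %d epochs run\n",
              x$refs$k, x$best_epoch, x$best_loss, nrow(x$history)))
  invisible(x)
}

#' Predict phoneme classes with the few-shot model
#'
#' Per-class score is the mean cosine similarity between the sample's
#' embedding and that class's reference embeddings (`"max"` similarity
#' mode available); the label is the argmax, ties broken to the lowest
#' class index.
#'
#' @param object An `ssi_fewshot_model`.
#' @param x Array (traces, length, n) or single matrix.
#' @param mode `"mean"` (default) or `"max"` aggregation over references.
#' @param ... Unused.
#' @return Tibble with `label` and one score column per class.
#' @export
predict.ssi_fewshot_model <- function(object, x, mode = c("mean", "max"),
                                      ...) {
  mode <- match.arg(mode)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  Er <- embed_samples(object$model, object$ref_x)
  Eq <- embed_samples(object$model, x)
  S <- cosine_block(Eq, Er)$S
  classes <- object$refs$classes
  scores <- vapply(classes, function(cl) {
    cols <- which(as.character(object$ref_y) == cl)
    if (mode == "mean") rowMeans(S[, cols, drop = FALSE])
    else apply(S[, cols, drop = FALSE], 1, max)
  }, numeric(nrow(S)))
  scores <- matrix(scores, ncol = length(classes),
                   dimnames = list(NULL, classes))
  label <- factor(classes[apply(scores, 1, which.max)], levels = object$levels)
  out <- tibble::as_tibble(as.data.frame(scores))
  dplyr::bind_cols(tibble::tibble(label = label), out)
}

#' Training history tidiers
#' @param x A fitted `ssi_fewshot_model` or `ssi_lstm_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch loss history; `glance()`: a one-row
#'   summary with the best epoch and loss.
#' @method tidy ssi_fewshot_model
#' @export
tidy.ssi_fewshot_model <- function(x, ...) x$history

#' @rdname tidy.ssi_fewshot_model
#' @method glance ssi_fewshot_model
#' @export
glance.ssi_fewshot_model <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_loss = x$best_loss,
                 epochs_run = nrow(x$history), k = x$refs$k)
}
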