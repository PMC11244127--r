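#' Specification of the two-layer LSTM baseline
#'
#' The baseline sequence classifier: a first LSTM layer emitting its full
#' hidden-state sequence, a second LSTM layer emitting only its last step,
#' a fully connected layer reducing to one output per class, and a softmax
#' head trained with cross-entropy.
#'
#' @param hidden Hidden units per layer (default 64).
#' @param n_classes Number of output classes (default 3).
#' @param time_steps Sequence length the 8-trace input is average-pooled
#'   to before entering the recurrence (default 32); `NA` keeps the input
#'   length.
#' @return An `lstm_spec`.
#' @export
lstm_spec <- function(hidden = 64, n_classes = 3, time_steps = 32) {
  structure(list(n_layers = 2L, hidden = check_count(hidden, "hidden"),
                 n_classes = check_count(n_classes, "n_classes", min = 2L),
                 time_steps = if (is.na(time_steps)) NA_integer_
                              else check_count(time_steps, "time_steps", 2L)),
            class = "lstm_spec")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

init_lstm_layer <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  list(Wx = rand_matrix(4 * h, d_in, d_in + h),
       Wh = rand_matrix(4 * h, h, d_in + h),
       b = b)
}

build_lstm <- function(spec, d_in, seed) {
  with_seed(seed, {
    params <- list(
      l1 = init_lstm_layer(d_in, spec$hidden),
      l2 = init_lstm_layer(spec$hidden, spec$hidden),
      out = list(W = rand_matrix(spec$n_classes, spec$hidden, spec$hidden),
                 b = numeric(spec$n_classes))
    )
    list(params = params, spec = spec, d_in = d_in, t = 0, adam = NULL)
  })
}

# Forward one LSTM layer over x: list of T matrices (d_in, B).
# Returns hidden sequence and caches for BPTT. Gate order: i, f, g, o.
lstm_layer_forward <- function(p, xs, h) {
  T_ <- length(xs)
  B <- ncol(xs[[1]])
  hprev <- matrix(0, h, B)
  cprev <- matrix(0, h, B)
  cache <- vector("list", T_)
  hs <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- p$Wx %*% xs[[t]] + p$Wh %*% hprev + p$b
    i <- sigmoid(z[1:h, , drop = FALSE])
    f <- sigmoid(z[(h + 1):(2 * h), , drop = FALSE])
    g <- tanh(z[(2 * h + 1):(3 * h), , drop = FALSE])
    o <- sigmoid(z[(3 * h + 1):(4 * h), , drop = FALSE])
    c_ <- f * cprev + i * g
    tc <- tanh(c_)
    hcur <- o * tc
    cache[[t]] <- list(x = xs[[t]], hprev = hprev, cprev = cprev,
                       i = i, f = f, g = g, o = o, c = c_, tc = tc)
    hs[[t]] <- hcur
    hprev <- hcur
    cprev <- c_
  }
  list(hs = hs, cache = cache)
}

# BPTT through one layer. dhs: list of T gradients on the hidden sequence
# (zero matrices where unused). Returns param grads and gradients on inputs.
lstm_layer_backward <- function(p, cache, dhs, h) {
  T_ <- length(cache)
  B <- ncol(dhs[[T_]])
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dxs <- vector("list", T_)
  dh_next <- matrix(0, h, B)
  dc_next <- matrix(0, h, B)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc * cc$o * (1 - cc$o)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$cprev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dz <- rbind(di, df, dg, do_)
    dWx <- dWx + dz %*% t(cc$x)
    dWh <- dWh + dz %*% t(cc$hprev)
    db <- db + rowSums(dz)
    dxs[[t]] <- t(p$Wx) %*% dz
    dh_next <- t(p$Wh) %*% dz
    dc_next <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

# Full forward: x array (C, L, B) -> softmax probabilities (classes, B).
lstm_forward <- function(model, x, reduce = TRUE) {
  spec <- model$spec
  if (reduce && !is.na(spec$time_steps) && dim(x)[2] != spec$time_steps) {
    P <- pool_matrix(dim(x)[2], spec$time_steps)
    xp <- matrix(aperm(x, c(2, 1, 3)), nrow = dim(x)[2])
    x <- aperm(array(P %*% xp, dim = c(spec$time_steps, dim(x)[1], dim(x)[3])),
               c(2, 1, 3))
  }
  T_ <- dim(x)[2]
  xs <- lapply(seq_len(T_), function(t) {
    matrix(x[, t, , drop = FALSE], nrow = dim(x)[1])
  })
  l1 <- lstm_layer_forward(model$params$l1, xs, spec$hidden)
  l2 <- lstm_layer_forward(model$params$l2, l1$hs, spec$hidden)
  h_last <- l2$hs[[T_]]
  logits <- model$params$out$W %*% h_last + model$params$out$b
  probs <- softmax_cols(logits)
  list(probs = probs, xs = xs, l1 = l1, l2 = l2, h_last = h_last, T_ = T_)
}

# Cross-entropy loss + full backward; returns grads in params shape.
lstm_backward <- function(model, fw, y_onehot) {
  spec <- model$spec
  B <- ncol(y_onehot)
  dlogits <- (fw$probs - y_onehot) / B
  dW_out <- dlogits %*% t(fw$h_last)
  db_out <- rowSums(dlogits)
  dh_last <- t(model$params$out$W) %*% dlogits
  zero <- matrix(0, spec$hidden, B)
  dhs2 <- c(rep(list(zero), fw$T_ - 1), list(dh_last))
  b2 <- lstm_layer_backward(model$params$l2, fw$l2$cache, dhs2, spec$hidden)
  b1 <- lstm_layer_backward(model$params$l1, fw$l1$cache, b2$dxs, spec$hidden)
  list(l1 = list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
       l2 = list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db),
       out = list(W = dW_out, b = db_out))
}

lstm_adam_step <- function(model, grads, lr) {
  model$t <- model$t + 1
  if (is.null(model$adam)) {
    model$adam <- lapply(model$params, adam_init)
  }
  for (blk in names(model$params)) {
    for (nm in names(model$params[[blk]])) {
      r <- adam_step_param(model$params[[blk]][[nm]], grads[[blk]][[nm]],
                           model$adam[[blk]][[nm]], lr, model$t)
      model$params[[blk]][[nm]] <- r$p
      model$adam[[blk]][[nm]] <- r$state
    }
  }
  model
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(pmax(colSums(probs * y_onehot), 1e-12)))
}

#' Train the two-layer LSTM baseline
#'
#' Softmax cross-entropy on the last-step output of the second LSTM layer,
#' Adam optimizer, early stopping on validation loss with the configured
#' patience, and restoration of the lowest-validation-loss checkpoint.
#'
#' @param x Array (traces, length, n) of feature stacks.
#' @param y Factor labels, length n.
#' @param spec An [lstm_spec()].
#' @param config A [train_config()].
#' @param validation Optional list(x, y) held-out split.
#' @param policy Optional [augmentation_policy()] applied to training
#'   samples only.
#' @return An `ssi_lstm_model` with `model`, `history`, `best_epoch`,
#'   `config`.
#' @export
train_lstm <- function(x, y, spec = lstm_spec(), config = train_config(),
                       validation = NULL, policy = NULL) {
  y <- as.factor(y)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(y))
  if (!is.null(validation) && length(validation$y) == 0L) {
    abort("Validation split is empty.")
  }
  spec$n_classes <- max(spec$n_classes, nlevels(y))
  onehot <- function(yy) {
    m <- matrix(0, nlevels(y), length(yy))
    m[cbind(as.integer(yy), seq_along(yy))] <- 1
    m
  }
  model <- build_lstm(spec, d_in = dim(x)[1],
                      seed = child_seed(config$seed, 21))
  history <- list()
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  with_seed(child_seed(config$seed, 22), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(y))
      batch_losses <- numeric()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- x[, , bi, drop = FALSE]
        if (!is.null(policy) && isTRUE(policy$enabled)) {
          for (j in seq_along(bi)) {
            xb[, , j] <- augment_traces(xb[, , j], policy)
          }
        }
        fw <- lstm_forward(model, xb)
        yb <- onehot(y[bi])
        batch_losses <- c(batch_losses, cross_entropy(fw$probs, yb))
        grads <- lstm_backward(model, fw, yb)
        model <- lstm_adam_step(model, grads, config$learning_rate)
      }
      train_loss <- mean(batch_losses)
      val_loss <- if (is.null(validation)) train_loss else {
        fwv <- lstm_forward(model, validation$x)
        cross_entropy(fwv$probs, onehot(factor(validation$y,
                                               levels = levels(y))))
      }
      history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss)
      if (val_loss < best$loss - (config$min_delta %||% 0) &&
          val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$adam <- NULL
  structure(list(model = model, history = tibble::as_tibble(
                   do.call(rbind, history)),
                 best_epoch = best$epoch, best_loss = best$loss,
                 config = config, levels = levels(y)),
            class = "ssi_lstm_model")
}

#' @export
print.ssi_lstm_model <- function(x, ...) {
  cat(sprintf("<ssi_lstm_model> 2-layer LSTM(%d), best epoch %d (val loss %.4f)\n",
              x$model$spec$hidden, x$best_epoch, x$best_loss))
  invisible(x)
}

#' Predict with the LSTM baseline
#'
#' @param object An `ssi_lstm_model`.
#' @param x Array (traces, length, n) or single matrix.
#' @param ... Unused.
#' @return Tibble with `label` and per-class softmax probabilities
#'   (each row sums to 1).
#' @export
predict.ssi_lstm_model <- function(object, x, ...) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  probs <- t(lstm_forward(object$model, x)$probs)
  colnames(probs) <- object$levels
  label <- factor(object$levels[apply(probs, 1, which.max)],
                  levels = object$levels)
  dplyr::bind_cols(tibble::tibble(label = label),
                   tibble::as_tibble(as.data.frame(probs)))
}

#' @rdname tidy.ssi_fewshot_model
#' @method tidy ssi_lstm_model
#' @export
tidy.ssi_lstm_model <- function(x, ...) x$history

#' @rdname tidy.ssi_fewshot_model
#' @method glance ssi_lstm_model
#' @export
glance.ssi_lstm_model <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_loss = x$best_loss,
                 epochs_run = nrow(x$history),
                 hidden = x$model$spec$hidden)
}
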