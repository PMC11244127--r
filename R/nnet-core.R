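# Minimal 1D neural-network core.
#
# Tensors are arrays (channels, length, batch) for convolutional stages and
# matrices (features, batch) for dense stages. Layers are plain lists; the
# network carries parameter/gradient/Adam state functionally. Convolutions
# are evaluated as K tap-shifted matrix products so the inner loops run in
# BLAS; correctness is pinned by finite-difference gradient checks in the
# test suite.

rand_matrix <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(fan_in)), nr, nc)
}

layer_conv1d <- function(c_in, c_out, kernel) {
  if (kernel %% 2 != 1) abort("Convolution kernels must be odd (same padding).")
  W <- array(rnorm(c_out * c_in * kernel, sd = 1 / sqrt(c_in * kernel)),
             dim = c(c_out, c_in, kernel))
  list(type = "conv1d", params = list(W = W, b = numeric(c_out)),
       kernel = kernel, c_in = c_in, c_out = c_out)
}

layer_batchnorm <- function(c_chan, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm",
       params = list(gamma = rep(1, c_chan), beta = numeric(c_chan)),
       running_mean = numeric(c_chan), running_var = rep(1, c_chan),
       momentum = momentum, eps = eps)
}

layer_tanh <- function() list(type = "tanh", params = list())

layer_maxpool <- function() list(type = "maxpool", params = list())

layer_adaptive_avgpool <- function(l_out) {
  list(type = "adaptive_avgpool", params = list(), l_out = as.integer(l_out))
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(f_in, f_out) {
  list(type = "dense",
       params = list(W = rand_matrix(f_out, f_in, f_in), b = numeric(f_out)),
       f_in = f_in, f_out = f_out)
}

# Column indices selecting tap k of the padded (C, Lp, B) tensor flattened
# to a (C, Lp*B) matrix.
tap_index <- function(k, l_out, l_pad, batch) {
  as.vector(outer(k:(k + l_out - 1), (seq_len(batch) - 1) * l_pad, "+"))
}

pool_matrix <- function(l_in, l_out) {
  P <- matrix(0, l_out, l_in)
  for (i in seq_len(l_out)) {
    s <- floor((i - 1) * l_in / l_out) + 1
    e <- max(s, ceiling(i * l_in / l_out))
    P[i, s:e] <- 1 / (e - s + 1)
  }
  P
}

forward_layer <- function(layer, x, training) {
  switch(layer$type,
    conv1d = {
      W <- layer$params$W; K <- layer$kernel
      d <- dim(x); L <- d[2]; B <- d[3]
      P <- (K - 1) / 2
      Lp <- L + 2 * P
      xp <- array(0, dim = c(layer$c_in, Lp, B))
      xp[, P + seq_len(L), ] <- x
      xpm <- matrix(xp, nrow = layer$c_in)
      out <- matrix(layer$params$b, nrow = layer$c_out, ncol = L * B)
      idx <- vector("list", K)
      for (k in seq_len(K)) {
        idx[[k]] <- tap_index(k, L, Lp, B)
        out <- out + matrix(W[, , k], nrow = layer$c_out) %*% xpm[, idx[[k]], drop = FALSE]
      }
      layer$cache <- list(xpm = xpm, idx = idx, L = L, Lp = Lp, B = B)
      list(layer = layer, out = array(out, dim = c(layer$c_out, L, B)))
    },
    batchnorm = {
      d <- dim(x)
      xm <- matrix(x, nrow = d[1])
      if (training) {
        mu <- rowMeans(xm)
        v <- rowMeans((xm - mu)^2)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * v
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - mu) * inv_sd
      out <- layer$params$gamma * xhat + layer$params$beta
      layer$cache <- list(xhat = xhat, inv_sd = inv_sd, dims = d,
                          training = training)
      list(layer = layer, out = array(out, dim = d))
    },
    tanh = {
      out <- tanh(x)
      layer$cache <- list(out = out)
      list(layer = layer, out = out)
    },
    maxpool = {
      d <- dim(x); L <- d[2]
      L2 <- L %/% 2
      if (L2 < 1L) abort("Input too short for max pooling.")
      a <- x[, seq(1, 2 * L2, by = 2), , drop = FALSE]
      b <- x[, seq(2, 2 * L2, by = 2), , drop = FALSE]
      take_a <- a >= b
      out <- ifelse(take_a, a, b)
      layer$cache <- list(take_a = take_a, dims = d, L2 = L2)
      list(layer = layer, out = array(out, dim = c(d[1], L2, d[3])))
    },
    adaptive_avgpool = {
      d <- dim(x); L <- d[2]
      P <- pool_matrix(L, layer$l_out)
      xp <- matrix(aperm(x, c(2, 1, 3)), nrow = L)
      outp <- P %*% xp
      out <- aperm(array(outp, dim = c(layer$l_out, d[1], d[3])), c(2, 1, 3))
      layer$cache <- list(P = P, dims = d)
      list(layer = layer, out = out)
    },
    flatten = {
      d <- dim(x)
      layer$cache <- list(dims = d)
      list(layer = layer, out = matrix(x, nrow = d[1] * d[2], ncol = d[3]))
    },
    dense = {
      layer$cache <- list(x = x)
      list(layer = layer,
           out = layer$params$W %*% x + layer$params$b)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type))
  )
}

backward_layer <- function(layer, dout) {
  switch(layer$type,
    conv1d = {
      cc <- layer$cache
      K <- layer$kernel
      dm <- matrix(dout, nrow = layer$c_out)
      dW <- array(0, dim = dim(layer$params$W))
      dxpm <- matrix(0, nrow = layer$c_in, ncol = ncol(cc$xpm))
      for (k in seq_len(K)) {
        cols <- cc$idx[[k]]
        dW[, , k] <- dm %*% t(cc$xpm[, cols, drop = FALSE])
        dxpm[, cols] <- dxpm[, cols] +
          t(matrix(layer$params$W[, , k], nrow = layer$c_out)) %*% dm
      }
      layer$grads <- list(W = dW, b = rowSums(dm))
      P <- (K - 1) / 2
      dxp <- array(dxpm, dim = c(layer$c_in, cc$Lp, cc$B))
      list(layer = layer,
           dx = dxp[, P + seq_len(cc$L), , drop = FALSE])
    },
    batchnorm = {
      cc <- layer$cache
      d <- cc$dims
      dm <- matrix(dout, nrow = d[1])
      if (!cc$training) {
        layer$grads <- list(gamma = rowSums(dm * cc$xhat), beta = rowSums(dm))
        dx <- layer$params$gamma * cc$inv_sd * dm
        return(list(layer = layer, dx = array(dx, dim = d)))
      }
      N <- ncol(dm)
      dxhat <- dm * layer$params$gamma
      layer$grads <- list(gamma = rowSums(dm * cc$xhat), beta = rowSums(dm))
      dx <- (cc$inv_sd / N) *
        (N * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
      list(layer = layer, dx = array(dx, dim = d))
    },
    tanh = {
      list(layer = layer, dx = dout * (1 - layer$cache$out^2))
    },
    maxpool = {
      cc <- layer$cache
      d <- cc$dims
      dx <- array(0, dim = d)
      da <- dout * cc$take_a
      db <- dout * !cc$take_a
      dx[, seq(1, 2 * cc$L2, by = 2), ] <- da
      dx[, seq(2, 2 * cc$L2, by = 2), ] <- db
      list(layer = layer, dx = dx)
    },
    adaptive_avgpool = {
      cc <- layer$cache
      d <- cc$dims
      dp <- matrix(aperm(dout, c(2, 1, 3)), nrow = layer$l_out)
      dxp <- t(cc$P) %*% dp
      dx <- aperm(array(dxp, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
      list(layer = layer, dx = dx)
    },
    flatten = {
      list(layer = layer, dx = array(dout, dim = layer$cache$dims))
    },
    dense = {
      layer$grads <- list(W = dout %*% t(layer$cache$x), b = rowSums(dout))
      list(layer = layer, dx = t(layer$params$W) %*% dout)
    }
  )
}

net_forward <- function(net, x, training = TRUE) {
  for (i in seq_along(net$layers)) {
    r <- forward_layer(net$layers[[i]], x, training)
    net$layers[[i]] <- r$layer
    x <- r$out
  }
  list(net = net, out = x)
}

net_backward <- function(net, dout) {
  for (i in rev(seq_along(net$layers))) {
    r <- backward_layer(net$layers[[i]], dout)
    net$layers[[i]] <- r$layer
    dout <- r$dx
  }
  list(net = net, dx = dout)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step_param <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# One Adam update over every parameterized layer using stored grads.
net_adam_step <- function(net, lr) {
  net$t <- (net$t %||% 0) + 1
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (length(layer$params) == 0L || is.null(layer$grads)) next
    if (is.null(layer$adam)) layer$adam <- adam_init(layer$params)
    for (nm in names(layer$params)) {
      r <- adam_step_param(layer$params[[nm]], layer$grads[[nm]],
                           layer$adam[[nm]], lr, net$t)
      layer$params[[nm]] <- r$p
      layer$adam[[nm]] <- r$state
    }
    net$layers[[i]] <- layer
  }
  net
}

# Strip per-batch caches/grads so checkpoints stay light.
net_strip <- function(net) {
  net$layers <- lapply(net$layers, function(l) {
    l$cache <- NULL
    l$grads <- NULL
    l$adam <- NULL
    l
  })
  net
}

net_param_count <- function(net) {
  sum(vapply(net$layers, function(l) {
    sum(vapply(l$params, length, integer(1)))
  }, numeric(1)))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
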