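# Shared fixtures, generated in code. The low-rate profile (500 Hz) keeps
# filtering and training fast while leaving every band edge below Nyquist.

fast_rate <- 500

fast_synth_config <- function(seed = 1, ...) {
  synth_config(sampling_rate = fast_rate, duration = 20,
               event_times = c(5, 12), event_duration = 3, seed = seed, ...)
}

tone_recording <- function(freq, rate = fast_rate, secs = 2, roles = c("EEG", "EMG")) {
  t <- seq_len(rate * secs) / rate
  x <- sin(2 * pi * freq * t)
  new_recording(cbind(eeg = x, emg = x), channel_roles = roles,
                sampling_rate = rate)
}

# Small embedding spec used wherever a full-size network is unnecessary.
tiny_embedding_spec <- function() {
  embedding_net_spec(kernels = c(3, 3, 3, 3, 3, 3),
                     channels = c(2, 2, 3, 3, 4, 4),
                     adaptive_pool_out = 32, head_dims = c(12, 8),
                     feature_dim = 4, min_input_length = 4)
}

# Scaled profile used by the cross-validation tests (see the methods
# vignette for the problem sizes).
scaled_embedding_spec <- function() {
  embedding_net_spec(adaptive_pool_out = 64,
                     channels = c(8, 8, 16, 16, 16, 16))
}

# A tiny, well separated 3-class trace set for convergence checks:
# class-specific bump positions on 2 channels.
toy_trace_dataset <- function(n_per_class = 8, len = 40, seed = 1) {
  with_seed_local <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(expr)
  }
  with_seed_local(seed, {
    classes <- c("M", "A", "D")
    centers <- c(M = 10, A = 20, D = 32)
    n <- n_per_class * 3
    x <- array(0, dim = c(2, len, n))
    y <- factor(rep(classes, each = n_per_class), levels = classes)
    t <- seq_len(len)
    for (i in seq_len(n)) {
      c0 <- centers[[as.character(y[i])]] + rnorm(1, 0, 1)
      bump <- exp(-(t - c0)^2 / 18)
      x[1, , i] <- bump + rnorm(len, 0, 0.08)
      x[2, , i] <- 0.5 * bump + rnorm(len, 0, 0.08)
    }
    list(x = x, y = y)
  })
}
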