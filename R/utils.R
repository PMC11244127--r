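#' @importFrom rlang abort warn %||%
#' @importFrom stats var sd cor approx fft rnorm runif qf pf
NULL

# Deterministic fan-out of one user seed into independent child seeds.
# Keeps every derived seed inside the 32-bit signed range R requires.
child_seed <- function(seed, index) {
  a <- (as.double(seed) %% 2147483647) + 1
  b <- (as.double(index) %% 2147483647) + 1
  as.integer((a * 48271 + b * 69621 + a * b) %% 2147483629)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user RNG flow.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s, got %s.",
                  name, if (strict) ">" else ">=", format(min),
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Linear resampling of a trace to a fixed number of points.
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n == n_out) return(as.numeric(x))
  if (n == 1L) return(rep(as.numeric(x), n_out))
  approx(seq(0, 1, length.out = n), x, xout = seq(0, 1, length.out = n_out))$y
}

# Block-RMS downsampling: preserves envelope energy of oscillatory traces
# that point-interpolation would alias away.
resample_rms <- function(x, n_out) {
  n <- length(x)
  if (n <= n_out) return(resample_linear(x, n_out))
  edges <- floor(seq(0, n, length.out = n_out + 1))
  vapply(seq_len(n_out), function(i) {
    seg <- x[(edges[i] + 1):edges[i + 1]]
    sqrt(mean(seg^2))
  }, numeric(1))
}
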