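#' Amplitude envelope via the analytic signal
#'
#' Returns the magnitude of the analytic signal (signal + i * Hilbert
#' transform), computed in the frequency domain. Zero-mean narrowband
#' signals at disjoint frequencies have near-zero raw covariance, so
#' cross-band co-modulation is measured on envelopes; the raw-signal mode
#' of the windowed statistics remains available.
#'
#' @param x Numeric signal.
#' @return Non-negative envelope, same length as `x`.
#' @export
signal_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric())
  if (n == 1L) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Specify a moving analysis window
#'
#' The default is a 500 ms window, which at the native 4 kHz sampling rate
#' is 2000 samples; the stride defaults to a quarter window for smooth
#' traces.
#'
#' @param length_ms Window length in milliseconds.
#' @param rate Sampling rate in Hz.
#' @param stride_samples Hop between consecutive windows in samples;
#'   default `length_samples / 4` (at least 1).
#' @return A `window_spec` with derived `length_samples`.
#' @export
#' @examples
#' window_spec(500, 4000)  # 2000-sample windows
window_spec <- function(length_ms = 500, rate = 4000, stride_samples = NULL) {
  check_number(length_ms, "length_ms", min = 0, strict = TRUE)
  check_number(rate, "rate", min = 0, strict = TRUE)
  length_samples <- as.integer(round(length_ms * rate / 1000))
  if (length_samples < 2L) {
    abort("Window must span at least 2 samples at this rate.")
  }
  if (is.null(stride_samples)) {
    stride_samples <- max(1L, as.integer(length_samples / 4))
  }
  stride_samples <- check_count(stride_samples, "stride_samples")
  structure(list(length_ms = length_ms, rate = rate,
                 length_samples = length_samples,
                 stride_samples = stride_samples),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %g ms = %d samples @ %g Hz, stride %d\n",
              x$length_ms, x$length_samples, x$rate, x$stride_samples))
  invisible(x)
}

n_windows <- function(n, window) {
  w <- window$length_samples
  if (n < w) abort(sprintf("Signal (%d) shorter than window (%d).", n, w))
  as.integer(floor((n - w) / window$stride_samples) + 1)
}

window_starts <- function(n, window) {
  seq.int(1L, by = window$stride_samples, length.out = n_windows(n, window))
}

moving_stat <- function(x, y, window, kind) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  starts <- window_starts(length(x), window)
  w <- window$length_samples
  zero_var <- 0L
  values <- vapply(starts, function(s) {
    xi <- x[s:(s + w - 1)]
    yi <- y[s:(s + w - 1)]
    if (kind == "covariance") {
      sum((xi - mean(xi)) * (yi - mean(yi))) / (w - 1)
    } else {
      sx <- sd(xi); sy <- sd(yi)
      if (sx == 0 || sy == 0) {
        zero_var <<- zero_var + 1L
        0
      } else {
        sum((xi - mean(xi)) * (yi - mean(yi))) / ((w - 1) * sx * sy)
      }
    }
  }, numeric(1))
  if (kind == "correlation") values <- pmin(1, pmax(-1, values))
  if (zero_var > 0L) {
    warn(sprintf("%d window(s) had zero variance; correlation set to 0.",
                 zero_var))
  }
  list(values = values, starts = starts, zero_variance_windows = zero_var)
}

new_feature_trace <- function(values, kind, pair, window, starts) {
  structure(list(values = values, kind = kind, pair = pair,
                 window = window, starts = starts),
            class = "feature_trace")
}

#' Moving-window covariance between two signals
#'
#' Sample covariance (denominator n - 1) over a sliding window, yielding a
#' time-resolved co-modulation trace between two band signals.
#'
#' @param x,y Equal-length numeric signals, at least one window long.
#' @param window A [window_spec()].
#' @param pair Optional character pair of trace names for labelling.
#' @return A `feature_trace` with `kind = "covariance"`.
#' @export
moving_covariance <- function(x, y, window, pair = c("x", "y")) {
  st <- moving_stat(x, y, window, "covariance")
  new_feature_trace(st$values, "covariance", pair, window, st$starts)
}

#' Moving-window Pearson correlation between two signals
#'
#' Values lie in \[-1, 1\]; windows in which either input has zero variance
#' emit 0 and are counted in a warning rather than failing the trace.
#'
#' @inheritParams moving_covariance
#' @return A `feature_trace` with `kind = "correlation"`.
#' @export
moving_correlation <- function(x, y, window, pair = c("x", "y")) {
  st <- moving_stat(x, y, window, "correlation")
  tr <- new_feature_trace(st$values, "correlation", pair, window, st$starts)
  tr$zero_variance_windows <- st$zero_variance_windows
  tr
}

#' @export
print.feature_trace <- function(x, ...) {
  cat(sprintf("<feature_trace> %s(%s, %s): %d windows of %d samples\n",
              x$kind, x$pair[1], x$pair[2], length(x$values),
              x$window$length_samples))
  invisible(x)
}

#' Coerce a feature trace to a tibble
#' @param x A `feature_trace`.
#' @param ... Unused.
#' @return Tibble with window center `time` (s) and `value`.
#' @method as_tibble feature_trace
#' @export
as_tibble.feature_trace <- function(x, ...) {
  center <- (x$starts - 1 + x$window$length_samples / 2) / x$window$rate
  tibble::tibble(time = center, value = x$values,
                 kind = x$kind, pair = paste(x$pair, collapse = "~"))
}

#' Plot a feature trace
#' @param object A `feature_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_trace
#' @export
autoplot.feature_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble.feature_trace(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window center (s)",
                  y = paste("moving", object$kind),
                  title = paste(object$pair, collapse = " ~ "))
}

#' Build the eight-trace phoneme feature stack
#'
#' Extracts the eight signal sets used for phoneme classification from a
#' two-channel recording: the four band components (EMG < 25 Hz,
#' EMG > 25 Hz, EEG alpha+beta, EEG gamma) and the four moving-window
#' correlations between the pairs (emg_low, emg_high), (alpha_beta, gamma),
#' (emg_low, alpha_beta) and (emg_high, gamma). Correlations are computed
#' on amplitude envelopes by default (`on = "envelope"`).
#'
#' @param recording An `ssi_recording` with one EEG and one EMG channel.
#' @param window A [window_spec()]; defaults to 500 ms at the recording
#'   rate.
#' @param bands Band list, by default [phoneme_bands()].
#' @param on Compute windowed correlations on `"envelope"` (default) or
#'   `"raw"` band signals.
#' @return A `phoneme_sample`: list with `band_traces` (4 signals),
#'   `corr_traces` (4 `feature_trace`s), `label`, `subject`, and the
#'   window/band metadata.
#' @export
phoneme_feature_stack <- function(recording, window = NULL,
                                  bands = phoneme_bands(),
                                  on = c("envelope", "raw")) {
  on <- match.arg(on)
  if (!"EEG" %in% recording$channel_roles ||
      !"EMG" %in% recording$channel_roles) {
    abort("Phoneme feature stack needs one EEG and one EMG channel.")
  }
  if (is.null(window)) window <- window_spec(500, recording$sampling_rate)
  bs <- decompose_bands(recording, bands)
  nm <- names(bs$bands)
  if (length(nm) != 4L) abort("Phoneme band set must contain 4 bands.")
  basis <- if (on == "envelope") lapply(bs$bands, signal_envelope) else bs$bands
  pairs <- list(c(nm[1], nm[2]), c(nm[3], nm[4]),
                c(nm[1], nm[3]), c(nm[2], nm[4]))
  corr <- lapply(pairs, function(p) {
    moving_correlation(basis[[p[1]]], basis[[p[2]]], window, pair = p)
  })
  names(corr) <- vapply(pairs, paste, character(1), collapse = "~")
  structure(
    list(band_traces = bs$bands, corr_traces = corr,
         label = recording$label, subject = recording$subject,
         window = window, sampling_rate = recording$sampling_rate,
         on = on),
    class = "phoneme_sample"
  )
}

#' @export
print.phoneme_sample <- function(x, ...) {
  cat(sprintf("<phoneme_sample> label=%s subject=%s: 4 band + 4 correlation traces\n",
              x$label, x$subject))
  invisible(x)
}

#' Align a phoneme sample to a fixed-length channel matrix
#'
#' Classifier input preparation: the four band signals are reduced by
#' block-RMS (preserving their amplitude envelope without aliasing) and the
#' four correlation traces are linearly interpolated, all to a common
#' length, giving an 8 x `length_out` matrix.
#'
#' @param sample A `phoneme_sample`.
#' @param length_out Common trace length (default 128).
#' @return Numeric matrix, 8 rows (traces) x `length_out` columns.
#' @export
stack_matrix <- function(sample, length_out = 128) {
  length_out <- check_count(length_out, "length_out", min = 4L)
  band <- vapply(sample$band_traces, resample_rms, numeric(length_out),
                 n_out = length_out)
  corr <- vapply(sample$corr_traces,
                 function(tr) resample_linear(tr$values, length_out),
                 numeric(length_out))
  m <- t(cbind(band, corr))
  rownames(m) <- c(names(sample$band_traces), names(sample$corr_traces))
  m
}
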