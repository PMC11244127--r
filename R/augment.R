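#' Training-time augmentation policy
#'
#' The augmentation suite applied to training samples (never validation or
#' test samples, and never labels): whole-sample operations — random
#' slope, x-shift, y-shift, amplitude scaling — and windowed operations
#' applied to randomly drawn windows with low probability — hanging
#' datapoint (a held value mimicking a brief recording dropout), Gaussian
#' smoothing, noise addition, and downsampling (re-interpolated so tensor
#' shapes are stable) — plus random cropping to promote weaker features.
#' All enabled operations are applied in random order, freshly randomized
#' each time a sample is accessed.
#'
#' Magnitudes are expressed relative to the sample: slope per full
#' duration and y-shift as fractions of the sample RMS, x-shift as a
#' fraction of the length.
#'
#' @param slope Max |slope| as a fraction of sample RMS per duration.
#' @param shift_x Max |x-shift| as a fraction of the length.
#' @param shift_y Max |y-shift| as a fraction of sample RMS.
#' @param scale_range Amplitude scale factor range.
#' @param window_frac Windowed-op window length as a fraction of the
#'   sample length.
#' @param window_p Per-window application probability.
#' @param noise_sd Added-noise SD for the noise window op, as a fraction
#'   of sample RMS.
#' @param crop_range Crop fraction range (of the sample length).
#' @param enabled Master switch; a disabled policy is the identity.
#' @return An `augmentation_policy`.
#' @export
augmentation_policy <- function(slope = 0.1, shift_x = 0.05, shift_y = 0.1,
                                scale_range = c(0.8, 1.25),
                                window_frac = 0.1, window_p = 0.05,
                                noise_sd = 0.1, crop_range = c(0.7, 1.0),
                                enabled = TRUE) {
  if (window_p < 0 || window_p > 1) abort("`window_p` must lie in [0, 1].")
  if (any(crop_range <= 0) || any(crop_range > 1)) {
    abort("`crop_range` must lie in (0, 1].")
  }
  structure(list(slope = slope, shift_x = shift_x, shift_y = shift_y,
                 scale_range = scale_range, window_frac = window_frac,
                 window_p = window_p, noise_sd = noise_sd,
                 crop_range = sort(crop_range), enabled = isTRUE(enabled)),
            class = "augmentation_policy")
}

as_trace_matrix <- function(sample) {
  if (is.matrix(sample)) list(m = sample, vector = FALSE)
  else list(m = matrix(sample, nrow = 1), vector = TRUE)
}

restore_shape <- function(m, was_vector) if (was_vector) as.numeric(m) else m

#' Apply a whole-sample augmentation operation
#'
#' Deterministic given the magnitude: `"slope"` adds `magnitude * t` with
#' `t` running 0..1 over the sample; `"shift_y"` adds the constant
#' `magnitude`; `"scale"` multiplies by `magnitude`; `"shift_x"`
#' translates by `magnitude` samples with edge replication. Labels are
#' never touched.
#'
#' @param sample Numeric vector or traces-by-length matrix.
#' @param op One of `"slope"`, `"shift_x"`, `"shift_y"`, `"scale"`.
#' @param magnitude Operation magnitude (samples for `shift_x`).
#' @return Augmented sample, same shape.
#' @export
apply_global_op <- function(sample, op, magnitude) {
  s <- as_trace_matrix(sample)
  m <- s$m
  L <- ncol(m)
  out <- switch(op,
    slope = m + rep(magnitude * seq(0, 1, length.out = L), each = nrow(m)),
    shift_y = m + magnitude,
    scale = m * magnitude,
    shift_x = {
      k <- as.integer(round(magnitude))
      if (k == 0) m
      else if (k > 0) cbind(m[, rep(1L, min(k, L)), drop = FALSE],
                            m[, seq_len(max(0L, L - k)), drop = FALSE])
      else cbind(m[, seq.int(min(-k + 1L, L), L), drop = FALSE],
                 m[, rep(L, min(-k, L)), drop = FALSE])
    },
    abort(sprintf("Unknown global augmentation op '%s'.", op))
  )
  restore_shape(out, s$vector)
}

gaussian_kernel <- function(width) {
  half <- max(1L, as.integer(width %/% 2))
  k <- exp(-0.5 * (seq(-half, half) / (half / 2))^2)
  k / sum(k)
}

#' Apply a windowed augmentation operation
#'
#' The sample is tiled with windows of `window` samples; each window is
#' independently drawn with probability `p` and the operation applied to
#' it; untouched regions are bit-identical to the input.
#'
#' @param sample Numeric vector or traces-by-length matrix.
#' @param op One of `"hanging_datapoint"` (hold the window's first value),
#'   `"gaussian_filter"`, `"noise_addition"`, `"downsample"` (factor-2
#'   decimation re-interpolated to the window length).
#' @param window Window length in samples (<= sample length).
#' @param p Per-window probability in \[0, 1\].
#' @param noise_sd SD for `"noise_addition"`.
#' @return Augmented sample, same shape and length.
#' @export
apply_windowed_op <- function(sample, op, window, p, noise_sd = 0.1) {
  s <- as_trace_matrix(sample)
  m <- s$m
  L <- ncol(m)
  window <- check_count(window, "window", min = 2L)
  if (window > L) abort(sprintf("Window (%d) exceeds sample length (%d).",
                                window, L))
  if (!op %in% c("hanging_datapoint", "gaussian_filter", "noise_addition",
                 "downsample")) {
    abort(sprintf("Unknown windowed augmentation op '%s'.", op))
  }
  starts <- seq(1L, L - window + 1L, by = window)
  hit <- runif(length(starts)) < p
  for (w in which(hit)) {
    idx <- starts[w]:(starts[w] + window - 1L)
    seg <- m[, idx, drop = FALSE]
    m[, idx] <- switch(op,
      hanging_datapoint = seg[, rep(1L, window), drop = FALSE],
      gaussian_filter = {
        k <- gaussian_kernel(max(3L, window %/% 4))
        t(apply(seg, 1, function(r) {
          as.numeric(stats::filter(c(rep(r[1], length(k)), r,
                                     rep(r[length(r)], length(k))),
                                   k, sides = 2))[length(k) + seq_along(r)]
        }))
      },
      noise_addition = seg + matrix(rnorm(length(seg), 0, noise_sd),
                                    nrow = nrow(seg)),
      downsample = t(apply(seg, 1, function(r) {
        resample_linear(r[seq(1, length(r), by = 2)], length(r))
      }))
    )
  }
  restore_shape(m, s$vector)
}

#' Randomly crop a sample
#'
#' Keeps a contiguous subsequence whose length is `round(f * n)` with `f`
#' drawn uniformly from `fraction_range` and a uniformly drawn start
#' offset.
#'
#' @param sample Numeric vector or traces-by-length matrix.
#' @param fraction_range Range of the kept fraction, in (0, 1].
#' @param min_length Smallest admissible result (e.g. the classifier's
#'   minimum input length).
#' @return Cropped sample.
#' @export
random_crop <- function(sample, fraction_range = c(0.7, 1.0),
                        min_length = 2L) {
  s <- as_trace_matrix(sample)
  L <- ncol(s$m)
  f <- runif(1, fraction_range[1], fraction_range[2])
  keep <- as.integer(round(f * L))
  if (keep < min_length) {
    abort(sprintf("Crop length %d below the minimum input length %d.",
                  keep, min_length))
  }
  start <- if (keep >= L) 1L else sample.int(L - keep + 1L, 1)
  restore_shape(s$m[, start:(start + keep - 1L), drop = FALSE], s$vector)
}

#' Augment a sample under a policy
#'
#' Draws a fresh random permutation of the enabled whole-sample and
#' windowed operations, applies each with its own magnitude/probability
#' draw, then applies random cropping (re-stretched to the original
#' length so stacked tensors keep their shape). The identity when the
#' policy is disabled. Labels are carried outside the sample and are
#' never modified. The drawn operation order is attached as the
#' `"op_order"` attribute.
#'
#' @param sample Numeric vector or traces-by-length matrix.
#' @param policy An [augmentation_policy()].
#' @return Augmented sample, same shape.
#' @export
augment_traces <- function(sample, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!policy$enabled) return(sample)
  s <- as_trace_matrix(sample)
  m <- s$m
  L <- ncol(m)
  rms <- sqrt(mean(m^2))
  if (rms == 0) rms <- 1
  ops <- base::sample(c("slope", "shift_x", "shift_y", "scale",
                  "hanging_datapoint", "gaussian_filter", "noise_addition",
                  "downsample"))
  window <- max(2L, as.integer(round(policy$window_frac * L)))
  for (op in ops) {
    m <- switch(op,
      slope = apply_global_op(m, "slope",
                              runif(1, -policy$slope, policy$slope) * rms),
      shift_x = apply_global_op(m, "shift_x",
                                runif(1, -policy$shift_x, policy$shift_x) * L),
      shift_y = apply_global_op(m, "shift_y",
                                runif(1, -policy$shift_y, policy$shift_y) * rms),
      scale = apply_global_op(m, "scale",
                              runif(1, policy$scale_range[1],
                                    policy$scale_range[2])),
      apply_windowed_op(m, op, window, policy$window_p,
                        noise_sd = policy$noise_sd * rms)
    )
  }
  cropped <- random_crop(m, policy$crop_range)
  if (ncol(cropped) != L) {
    cropped <- t(apply(cropped, 1, resample_linear, n_out = L))
  }
  out <- restore_shape(cropped, s$vector)
  attr(out, "op_order") <- ops
  out
}
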