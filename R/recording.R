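#' Construct a biopotential recording
#'
#' A recording bundles one or more synchronously sampled biopotential
#' channels (microvolt-scale), the per-channel role (EEG or EMG), the
#' sampling rate, and event annotations (onset, duration, label). It is the
#' common currency of the pipeline: the synthetic generator produces
#' recordings, the preprocessing stage decomposes them into frequency bands,
#' and the feature stage turns them into classifier inputs.
#'
#' @param channels Numeric matrix, one column per channel, or a data frame
#'   of numeric columns. Column names are channel names; unnamed channels
#'   are named after their role.
#' @param channel_roles Character vector, one of `"EEG"`/`"EMG"` per channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param annotations Optional data frame with columns `onset` (s),
#'   `duration` (s) and `label`; intervals must lie inside the record.
#' @param subject Optional subject identifier.
#' @param label Optional class label attached to the whole recording (used
#'   for phoneme samples).
#'
#' @return An object of class `ssi_recording`.
#' @export
#' @examples
#' rec <- new_recording(cbind(eeg = rnorm(1000), emg = rnorm(1000)),
#'                      channel_roles = c("EEG", "EMG"), sampling_rate = 500)
#' rec
new_recording <- function(channels, channel_roles, sampling_rate,
                          annotations = NULL, subject = NA_character_,
                          label = NA_character_) {
  if (is.data.frame(channels)) channels <- as.matrix(channels)
  if (!is.matrix(channels) || !is.numeric(channels)) {
    abort("`channels` must be a numeric matrix (samples x channels).")
  }
  if (nrow(channels) < 1L) abort("A recording needs at least one sample.")
  check_number(sampling_rate, "sampling_rate", min = 0, strict = TRUE)
  channel_roles <- toupper(channel_roles)
  if (length(channel_roles) != ncol(channels)) {
    abort("`channel_roles` must name a role for every channel.")
  }
  if (!all(channel_roles %in% c("EEG", "EMG"))) {
    abort("Channel roles must be 'EEG' or 'EMG'.")
  }
  if (is.null(colnames(channels))) {
    colnames(channels) <- make.unique(tolower(channel_roles), sep = "_")
  }
  duration <- nrow(channels) / sampling_rate
  annotations <- normalize_annotations(annotations, duration)
  structure(
    list(
      channels = channels,
      channel_roles = channel_roles,
      sampling_rate = sampling_rate,
      annotations = annotations,
      subject = as.character(subject),
      label = as.character(label)
    ),
    class = "ssi_recording"
  )
}

normalize_annotations <- function(annotations, duration) {
  if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0L) {
    return(tibble::tibble(onset = numeric(), duration = numeric(),
                          label = character()))
  }
  annotations <- tibble::as_tibble(annotations)
  required <- c("onset", "duration", "label")
  if (!all(required %in% names(annotations))) {
    abort("Annotations need columns `onset`, `duration`, `label`.")
  }
  bad <- annotations$onset < 0 |
    annotations$onset + annotations$duration > duration + 1e-9
  if (any(bad)) {
    abort(sprintf("Annotation interval(s) %s fall outside the record [0, %.3f s].",
                  paste(which(bad), collapse = ", "), duration))
  }
  annotations[order(annotations$onset), c("onset", "duration", "label")]
}

#' @export
print.ssi_recording <- function(x, ...) {
  cat(sprintf("<ssi_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$channels), nrow(x$channels), x$sampling_rate,
              nrow(x$channels) / x$sampling_rate))
  cat("  roles: ", paste(sprintf("%s[%s]", colnames(x$channels),
                                 x$channel_roles), collapse = ", "), "\n")
  if (!is.na(x$label)) cat("  label:", x$label, " subject:", x$subject, "\n")
  if (nrow(x$annotations)) {
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(utils::head(unique(x$annotations$label), 5),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Coerce a recording to a long tibble
#'
#' @param x An `ssi_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `channel`, `role`, `value`.
#' @method as_tibble ssi_recording
#' @export
as_tibble.ssi_recording <- function(x, ...) {
  n <- nrow(x$channels)
  time <- (seq_len(n) - 1) / x$sampling_rate
  tibble::tibble(
    time = rep(time, times = ncol(x$channels)),
    channel = rep(colnames(x$channels), each = n),
    role = rep(x$channel_roles, each = n),
    value = as.vector(x$channels)
  )
}

#' @export
duration.ssi_recording <- function(x, ...) nrow(x$channels) / x$sampling_rate

#' Record duration in seconds
#' @param x An object with a duration.
#' @param ... Passed to methods.
#' @export
duration <- function(x, ...) UseMethod("duration")

# Channel vector for a role (first matching channel).
channel_by_role <- function(recording, role) {
  idx <- which(recording$channel_roles == toupper(role))
  if (length(idx) == 0L) {
    abort(sprintf("Recording has no channel with role '%s'.", role))
  }
  recording$channels[, idx[1]]
}

#' Plot a recording's channels against time
#'
#' Annotated event windows are shaded so movement epochs are visible
#' against the baseline.
#'
#' @param object An `ssi_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssi_recording
#' @export
autoplot.ssi_recording <- function(object, ...) {
  df <- as_tibble.ssi_recording(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)")
  if (nrow(object$annotations)) {
    ann <- object$annotations
    p <- p + ggplot2::annotate("rect",
      xmin = ann$onset, xmax = ann$onset + ann$duration,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}
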