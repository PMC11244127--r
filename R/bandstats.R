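#' Segment a recording into pre/spike epochs
#'
#' Each annotated movement event contributes a "pre" (resting baseline)
#' epoch immediately before its onset and a "spike" (movement) epoch from
#' the onset, matching the protocol of repeated two-to-five-second tongue
#' movements separated by repose.
#'
#' @param recording An `ssi_recording` with at least one annotated event.
#' @param pre_s Pre-epoch length in seconds (default 2, the window in which
#'   movement-locked activity peaks before onset).
#' @param spike_s Spike-epoch length in seconds; `NULL` uses each event's
#'   annotated duration (default 3 s events).
#' @return An `epoch_set` tibble with columns `start`, `end`, `phase`
#'   (`pre`/`spike`) and `repetition`.
#' @export
segment_epochs <- function(recording, pre_s = 2, spike_s = NULL) {
  check_number(pre_s, "pre_s", min = 0, strict = TRUE)
  ann <- recording$annotations
  if (nrow(ann) == 0L) abort("Recording has no annotated events.")
  onsets <- ann$onset
  durations <- if (is.null(spike_s)) ann$duration else rep(spike_s, nrow(ann))
  too_early <- which(onsets - pre_s < -1e-9)
  if (length(too_early)) {
    abort(sprintf("Pre window (%g s) does not fit before event(s) %s.",
                  pre_s, paste(too_early, collapse = ", ")))
  }
  if (nrow(ann) > 1L) {
    gap_bad <- which(onsets[-1] - (onsets[-nrow(ann)] + durations[-nrow(ann)]) <
                       pre_s - 1e-9)
    if (length(gap_bad)) {
      abort(sprintf(
        "Events closer than pre + spike length: pair(s) %s.",
        paste(sprintf("(%d,%d)", gap_bad, gap_bad + 1), collapse = ", ")))
    }
  }
  reps <- seq_len(nrow(ann))
  epochs <- dplyr::bind_rows(
    tibble::tibble(start = onsets - pre_s, end = onsets,
                   phase = "pre", repetition = reps),
    tibble::tibble(start = onsets, end = onsets + durations,
                   phase = "spike", repetition = reps)
  )
  epochs <- dplyr::arrange(epochs, .data$start)
  structure(epochs, class = c("epoch_set", class(epochs)))
}

#' Per-epoch correlation between band envelopes
#'
#' Pearson correlation between two band traces restricted to each epoch,
#' one row per (epoch, band pair). Computed on amplitude envelopes by
#' default, consistent with the moving-window features; epochs in which
#' either trace is constant are flagged (`valid = FALSE`) and excluded
#' from downstream tests.
#'
#' @param bandset A `band_set` from [decompose_bands()].
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @param pairs List of character pairs of band names, e.g.
#'   `list(c("alpha","gamma"))`; default all pairs of the set's bands.
#' @param on `"envelope"` (default) or `"raw"`.
#' @return A `corr_table` tibble with columns `repetition`, `phase`,
#'   `pair`, `r`, `valid`.
#' @export
epoch_band_correlations <- function(bandset, epochs, pairs = NULL,
                                    on = c("envelope", "raw")) {
  on <- match.arg(on)
  nm <- names(bandset$bands)
  if (is.null(pairs)) {
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  if (length(pairs) == 0L) {
    return(structure(tibble::tibble(repetition = integer(), phase = character(),
                                    pair = character(), r = numeric(),
                                    valid = logical()),
                     class = c("corr_table", "tbl_df", "tbl", "data.frame")))
  }
  bad <- purrr::keep(pairs, ~ !all(.x %in% nm))
  if (length(bad)) {
    abort(sprintf("Pair(s) reference unknown bands: %s (have %s).",
                  paste(vapply(bad, paste, character(1), collapse = "~"),
                        collapse = ", "),
                  paste(nm, collapse = ", ")))
  }
  rate <- bandset$sampling_rate
  n <- length(bandset$bands[[1]])
  basis <- if (on == "envelope") {
    lapply(bandset$bands, signal_envelope)
  } else {
    bandset$bands
  }
  rows <- purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    i1 <- max(1L, as.integer(floor(epochs$start[i] * rate)) + 1L)
    i2 <- min(n, as.integer(floor(epochs$end[i] * rate)))
    if (i2 - i1 < 2L) abort(sprintf("Epoch %d lies outside the record.", i))
    purrr::map_dfr(pairs, function(p) {
      x <- basis[[p[1]]][i1:i2]
      y <- basis[[p[2]]][i1:i2]
      valid <- sd(x) > 0 && sd(y) > 0
      tibble::tibble(
        repetition = epochs$repetition[i], phase = epochs$phase[i],
        pair = paste(p, collapse = "~"),
        r = if (valid) cor(x, y) else NA_real_,
        valid = valid)
    })
  })
  structure(rows, class = c("corr_table", class(rows)))
}

#' One-way analysis of variance
#'
#' Classic between-group versus within-group mean-square ratio. The F
#' statistic is the ratio of group variation to within-group variation; a
#' high value indicates group means differ more than chance within-group
#' scatter would produce. Cross-checked against `stats::aov` in the test
#' suite; the explicit sums-of-squares form is kept because the degrees of
#' freedom and the critical-value comparison are part of the reported
#' analysis.
#'
#' @param groups List of numeric vectors, >= 2 groups of >= 2 values each.
#' @param alpha Significance level for the critical value (default 0.05).
#' @return An `anova_result` with `f_value`, `p_value`, `df_between`,
#'   `df_within`, `f_critical`, `ss_between`, `ss_within`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3, 4), c(2, 3, 4, 5)))
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("Need a list of at least two groups.")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    abort(sprintf("Every group needs >= 2 values; group(s) %s too small.",
                  paste(which(sizes < 2L), collapse = ", ")))
  }
  all_values <- unlist(groups, use.names = FALSE)
  if (anyNA(all_values)) abort("Groups must not contain missing values.")
  k <- length(groups)
  N <- length(all_values)
  grand <- mean(all_values)
  ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    f <- 0
    p <- 1
  } else if (ssw == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(f_value = f, p_value = p, df_between = df1, df_within = df2,
                 f_critical = f_critical(alpha, df1, df2), alpha = alpha,
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (F crit at alpha=%g: %.4g)\n",
              x$df_between, x$df_within, x$f_value, x$p_value, x$alpha,
              x$f_critical))
  invisible(x)
}

#' Tidy a one-way ANOVA result
#' @param x An `anova_result`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value, dfs and critical value.
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) {
  tibble::tibble(statistic = x$f_value, p.value = x$p_value,
                 df = x$df_between, df.residual = x$df_within,
                 f.critical = x$f_critical,
                 ss.between = x$ss_between, ss.within = x$ss_within)
}

#' Upper critical value of the F distribution
#'
#' Upper-alpha quantile used as the significance threshold for the band
#' correlation ANOVA; for two groups of four repetitions (df 1, 6) at
#' alpha = 0.05 it equals 5.987.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The critical value.
#' @export
#' @examples
#' f_critical(0.05, 1, 6)  # 5.987
f_critical <- function(alpha, df1, df2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  df1 <- check_count(df1, "df1")
  df2 <- check_count(df2, "df2")
  qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Compare band correlations between pre and spike phases
#'
#' For each band pair, the mean correlation in the resting "pre" phase, the
#' mean during the movement "spike" phase, their difference, and a one-way
#' ANOVA across the two phases. A decline (`delta < 0`) for the alpha-gamma
#' pair is the signature of gamma-band power surging during intentional
#' movement.
#'
#' @param table A `corr_table` from [epoch_band_correlations()] containing
#'   both phases.
#' @param alpha Significance level for the per-pair ANOVA.
#' @param adjust P-value adjustment across pairs (`"none"` default,
#'   or any method of [stats::p.adjust()], e.g. `"bonferroni"`).
#' @return A tibble with one row per pair: `pair`, `mean_pre`,
#'   `mean_spike`, `delta`, `f_value`, `p_value`, `f_critical`,
#'   `significant`.
#' @export
compare_pre_spike <- function(table, alpha = 0.05, adjust = "none") {
  stopifnot(is.data.frame(table))
  table <- dplyr::filter(table, .data$valid)
  phases <- unique(table$phase)
  if (!all(c("pre", "spike") %in% phases)) {
    abort("Correlation table must contain both 'pre' and 'spike' phases.")
  }
  out <- table |>
    dplyr::group_by(.data$pair) |>
    dplyr::group_modify(function(d, key) {
      pre <- d$r[d$phase == "pre"]
      spk <- d$r[d$phase == "spike"]
      an <- one_way_anova(list(pre, spk), alpha = alpha)
      tibble::tibble(mean_pre = mean(pre), mean_spike = mean(spk),
                     delta = mean(spk) - mean(pre),
                     f_value = an$f_value, p_value = an$p_value,
                     f_critical = an$f_critical)
    }) |>
    dplyr::ungroup()
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_value < alpha
  out
}
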