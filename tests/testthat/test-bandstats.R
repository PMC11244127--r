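test_that("epoch segmentation places pre and spike windows around events", {
  rec <- new_recording(cbind(eeg = rnorm(500 * 20)), "EEG", 500,
                       annotations = data.frame(
                         onset = c(10), duration = 3, label = "movement"))
  ep <- segment_epochs(rec, pre_s = 2)
  expect_identical(nrow(ep), 2L)
  pre <- ep[ep$phase == "pre", ]
  spike <- ep[ep$phase == "spike", ]
  expect_equal(c(pre$start, pre$end), c(8, 10))
  expect_equal(c(spike$start, spike$end), c(10, 13))

  # five events yield five pre + five spike epochs with sequential indices
  rec5 <- simulate_recording(synth_config(sampling_rate = 500, duration = 35,
                                          event_times = c(5, 10.5, 16, 21.5, 27),
                                          seed = 2))
  ep5 <- segment_epochs(rec5)
  expect_identical(sum(ep5$phase == "pre"), 5L)
  expect_identical(sum(ep5$phase == "spike"), 5L)
  expect_identical(sort(unique(ep5$repetition)), 1:5)

  # event too early for the pre window
  rec_bad <- new_recording(cbind(eeg = rnorm(5000)), "EEG", 500,
                           annotations = data.frame(onset = 1, duration = 3,
                                                    label = "m"))
  expect_error(segment_epochs(rec_bad, pre_s = 2), "does not fit")
  # events packed closer than pre + spike
  rec_close <- new_recording(cbind(eeg = rnorm(5000)), "EEG", 500,
                             annotations = data.frame(onset = c(3, 6.5),
                                                      duration = 3,
                                                      label = "m"))
  expect_error(segment_epochs(rec_close, pre_s = 2), "closer")
})

test_that("epoch band correlations match brute-force Pearson on slices", {
  rec <- simulate_recording(fast_synth_config(seed = 3))
  bs <- decompose_bands(rec, eeg_bands())
  ep <- segment_epochs(rec)
  tab <- epoch_band_correlations(bs, ep, pairs = list(c("alpha", "gamma")))
  env_a <- signal_envelope(bs$bands$alpha)
  env_g <- signal_envelope(bs$bands$gamma)
  for (i in seq_len(nrow(ep))) {
    i1 <- floor(ep$start[i] * 500) + 1
    i2 <- floor(ep$end[i] * 500)
    expect_equal(tab$r[i], cor(env_a[i1:i2], env_g[i1:i2]),
                 tolerance = 1e-10)
  }
  # self-pair is identically 1; empty pair list gives an empty table
  self <- epoch_band_correlations(bs, ep, pairs = list(c("alpha", "alpha")))
  expect_true(all(abs(self$r - 1) < 1e-12))
  expect_identical(nrow(epoch_band_correlations(bs, ep, pairs = list())), 0L)
  expect_error(epoch_band_correlations(bs, ep, pairs = list(c("alpha", "zeta"))),
               "unknown bands")
})

test_that("one-way ANOVA reproduces closed-form sums of squares and aov", {
  # identical groups: F = 0
  expect_equal(one_way_anova(list(1:4, 1:4))$f_value, 0)
  # hand-computed: SSB = 2, SSW = 10, df (1, 6) -> F = 1.2
  a <- one_way_anova(list(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(a$f_value, 1.2, tolerance = 1e-12)
  expect_equal(a$ss_between, 2)
  expect_equal(a$ss_within, 10)
  expect_identical(c(a$df_between, a$df_within), c(1L, 6L))
  # cross-check against stats::aov on random groups
  set.seed(8)
  g <- list(rnorm(7), rnorm(5, 1), rnorm(6, -0.5))
  ours <- one_way_anova(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(seq_along(g), lengths(g))))
  ref <- summary(stats::aov(y ~ grp, data = df))[[1]]
  expect_equal(ours$f_value, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # F = t^2 for two equal-variance groups
  g2 <- list(rnorm(4), rnorm(4, 0.5))
  tt <- stats::t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(one_way_anova(g2)$f_value, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 5)), "2 values")
  # all values identical across groups: F = 0, p = 1
  flat <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(flat$f_value, 0)
  expect_equal(flat$p_value, 1)
})

test_that("ANOVA is invariant to shifts and common rescaling", {
  set.seed(13)
  g <- list(rnorm(5), rnorm(5, 1))
  f0 <- one_way_anova(g)$f_value
  expect_equal(one_way_anova(lapply(g, `+`, 10))$f_value, f0,
               tolerance = 1e-10)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$f_value, f0,
               tolerance = 1e-10)
})

test_that("F critical values match the F distribution and the ANOVA decision", {
  expect_equal(round(f_critical(0.05, 1, 6), 3), 5.987)
  expect_gt(f_critical(0.01, 1, 6), f_critical(0.05, 1, 6))
  # limit: chi-square/normal equivalence at huge df2
  expect_equal(f_critical(0.05, 1, 1e6), qnorm(0.975)^2, tolerance = 1e-3)
  expect_error(f_critical(1.2, 1, 6), "between 0 and 1")
  expect_error(f_critical(0.05, 0, 6), "integer")
  # consistency: p < alpha iff F > critical
  set.seed(21)
  for (i in 1:20) {
    g <- list(rnorm(4), rnorm(4, runif(1, 0, 2)))
    a <- one_way_anova(g)
    if (abs(a$p_value - 0.05) > 1e-9) {
      expect_identical(a$p_value < 0.05, a$f_value > a$f_critical)
    }
  }
})

test_that("pre/spike comparison reports per-pair deltas and requires both phases", {
  tab <- tibble::tibble(
    repetition = rep(1:4, 2), phase = rep(c("pre", "spike"), each = 4),
    pair = "alpha~gamma", r = c(rep(0.9, 4), rep(0.7, 4)) + rep(c(0, 0.01, -0.01, 0), 2),
    valid = TRUE)
  cmp <- compare_pre_spike(tab)
  expect_equal(cmp$delta, -0.2, tolerance = 1e-12)
  expect_identical(nrow(cmp), 1L)
  one_phase <- tab[tab$phase == "pre", ]
  expect_error(compare_pre_spike(one_phase), "both")
})

test_that("the configured gamma surge drives the alpha-gamma correlation down", {
  n_runs <- 12L
  neg <- 0L
  for (s in seq_len(n_runs)) {
    rec <- simulate_recording(fast_synth_config(seed = 100 + s))
    bs <- decompose_bands(rec, eeg_bands())
    ep <- segment_epochs(rec)
    tab <- epoch_band_correlations(bs, ep, pairs = list(c("alpha", "gamma")))
    cmp <- compare_pre_spike(tab)
    if (cmp$delta < 0) neg <- neg + 1L
  }
  expect_gte(neg, ceiling(0.8 * n_runs))
})
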