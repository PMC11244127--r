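test_that("the analytic-signal envelope recovers tone amplitude and is non-negative", {
  expect_equal(signal_envelope(numeric(0)), numeric(0))
  expect_equal(signal_envelope(rep(0, 100)), rep(0, 100))
  rate <- 500
  t <- seq_len(4 * rate) / rate
  A <- 2.5
  env <- signal_envelope(A * sin(2 * pi * 20 * t))
  interior <- 200:1800
  expect_true(all(abs(env[interior] - A) / A < 0.02))
  set.seed(2)
  expect_true(all(signal_envelope(rnorm(512)) >= 0))
})

test_that("window arithmetic matches the 500 ms / 2000-sample convention", {
  w <- window_spec(500, 4000)
  expect_identical(w$length_samples, 2000L)
  expect_identical(window_spec(500, 500)$length_samples, 250L)
  # trace length formula over a grid of (n, window, stride)
  for (n in c(100, 257, 1000)) {
    for (len in c(20, 50)) {
      for (stride in c(1, 7, 25)) {
        w <- window_spec(len * 2, 500, stride_samples = stride)
        tr <- moving_covariance(rnorm(n), rnorm(n), w)
        expect_length(tr$values,
                      floor((n - w$length_samples) / stride) + 1)
      }
    }
  }
})

test_that("moving covariance and correlation match brute-force loops", {
  w <- window_spec(100, 500, stride_samples = 10)  # 50-sample windows
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(400)
    y <- 0.5 * x + rnorm(400)
    starts <- seq(1, 400 - 50 + 1, by = 10)
    cov_brute <- vapply(starts, function(s) cov(x[s:(s + 49)], y[s:(s + 49)]),
                        numeric(1))
    cor_brute <- vapply(starts, function(s) cor(x[s:(s + 49)], y[s:(s + 49)]),
                        numeric(1))
    expect_equal(moving_covariance(x, y, w)$values, cov_brute,
                 tolerance = 1e-10)
    expect_equal(moving_correlation(x, y, w)$values, cor_brute,
                 tolerance = 1e-10)
  }
})

test_that("windowed statistics honor their identities and bounds", {
  w <- window_spec(100, 500, stride_samples = 25)
  set.seed(3)
  x <- rnorm(300)
  # cov(x, x) is the windowed variance
  vtr <- moving_covariance(x, x, w)
  starts <- seq(1, 300 - 50 + 1, by = 25)
  expect_equal(vtr$values,
               vapply(starts, function(s) var(x[s:(s + 49)]), numeric(1)))
  # constants give zero covariance and flagged zero-variance correlation
  expect_true(all(moving_covariance(rep(2, 100), rep(5, 100),
                                    window_spec(100, 500))$values == 0))
  expect_warning(
    ztr <- moving_correlation(rep(2, 100), rnorm(100), window_spec(100, 500)),
    "zero variance")
  expect_true(all(ztr$values == 0))
  # y = x and y = -x pin correlation at +/-1
  expect_equal(moving_correlation(x, x, w)$values,
               rep(1, length(vtr$values)), tolerance = 1e-12)
  expect_equal(moving_correlation(x, -x, w)$values,
               rep(-1, length(vtr$values)), tolerance = 1e-12)
  expect_error(moving_covariance(rnorm(10), rnorm(10), w), "shorter")
})

test_that("windowed statistics are scale-equivariant and Cauchy-Schwarz bounded", {
  w <- window_spec(80, 500, stride_samples = 20)
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(300); y <- rnorm(300)
    a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3)
    expect_equal(moving_covariance(a * x, b * y, w)$values,
                 a * b * moving_covariance(x, y, w)$values,
                 tolerance = 1e-10)
    expect_equal(moving_correlation(a * x + 1, b * y - 2, w)$values,
                 moving_correlation(x, y, w)$values, tolerance = 1e-10)
    covs <- moving_covariance(x, y, w)$values
    starts <- seq(1, 300 - 40 + 1, by = 20)
    bound <- vapply(starts, function(s) sd(x[s:(s + 39)]) * sd(y[s:(s + 39)]),
                    numeric(1))
    expect_true(all(abs(covs) <= bound + 1e-12))
  }
})

test_that("the phoneme feature stack contains the eight documented traces", {
  cfg <- fast_synth_config()
  rec <- simulate_recording(cfg)
  stack <- phoneme_feature_stack(rec)
  expect_length(stack$band_traces, 4)
  expect_length(stack$corr_traces, 4)
  expect_named(stack$band_traces,
               c("emg_low", "emg_high", "alpha_beta", "gamma"))
  for (tr in stack$corr_traces) {
    expect_true(all(tr$values >= -1 & tr$values <= 1))
  }
  # compositional identity with the primitive operations
  w <- window_spec(500, rec$sampling_rate)
  bs <- decompose_bands(rec)
  env <- lapply(bs$bands, signal_envelope)
  manual <- moving_correlation(env$emg_low, env$emg_high, w)
  expect_equal(stack$corr_traces[[1]]$values, manual$values)
  # missing role errors
  eeg_only <- new_recording(cbind(eeg = rnorm(1000)), "EEG", 500)
  expect_error(phoneme_feature_stack(eeg_only), "EEG and one EMG")
})

test_that("an EMG burst perturbs the EMG-pair correlation trace", {
  # ground-truth event mask from the generator: the 7-1 trace inside the
  # burst should move by > 3 baseline SDs in most seeded runs
  hits <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    cfg <- synth_config(sampling_rate = fast_rate, duration = 12,
                        event_times = 8, event_duration = 2,
                        emg_burst_gain = 6, seed = s)
    rec <- simulate_recording(cfg)
    stack <- phoneme_feature_stack(rec)
    tr <- stack$corr_traces[[1]]
    centers <- (tr$starts - 1 + tr$window$length_samples / 2) / fast_rate
    base <- tr$values[centers < 7]
    inside <- tr$values[centers >= 8 & centers <= 10]
    if (any(abs(inside - mean(base)) > 3 * sd(base))) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_runs)
})

test_that("stack_matrix aligns all eight traces to a common length", {
  rec <- simulate_recording(fast_synth_config())
  stack <- phoneme_feature_stack(rec)
  m <- stack_matrix(stack, length_out = 64)
  expect_identical(dim(m), c(8L, 64L))
  expect_identical(nrow(stack_matrix(stack, length_out = 100)), 8L)
})
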