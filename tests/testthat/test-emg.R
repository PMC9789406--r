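test_that("conditioning removes mains noise and sub-band content", {
  rate <- 10000
  t <- seq(0, 2, by = 1 / rate)
  s60 <- sin(2 * pi * 60 * t)
  out <- condition_signal(emg_channel(s60, rate))
  expect_lt(sd(out$samples) / sd(s60), 0.05)
  s10 <- sin(2 * pi * 10 * t)
  out10 <- condition_signal(emg_channel(s10, rate))
  expect_lt(sd(out10$samples) / sd(s10), 0.5)
  # a 1 kHz passband tone is essentially untouched
  s1k <- sin(2 * pi * 1000 * t)
  out1k <- condition_signal(emg_channel(s1k, rate))
  expect_equal(sd(out1k$samples) / sd(s1k), 1, tolerance = 0.02)
  expect_error(condition_signal(emg_channel(c(1, NA, 3), rate)), "non-finite")
  # cutoff above Nyquist is clipped with a warning, output length preserved
  low_rate <- emg_channel(stats::rnorm(4000), 5000)
  expect_warning(out_lr <- condition_signal(low_rate), "Nyquist")
  expect_length(out_lr$samples, 4000)
})

test_that("conditioning is near-idempotent for in-band signals", {
  set.seed(1)
  rate <- 10000
  bf <- signal::butter(4, c(100, 2000) / (rate / 2), "pass")
  inband <- as.numeric(signal::filtfilt(bf, stats::rnorm(20001)))
  f1 <- condition_signal(emg_channel(inband, rate))
  f2 <- condition_signal(f1)
  expect_lt(abs(sd(f2$samples) - sd(f1$samples)) / sd(f1$samples), 0.01)
})

test_that("burst detection finds sharp-onset bursts within 10 ms at SNR 5", {
  set.seed(2)
  rate <- 10000
  n <- 30001
  x <- stats::rnorm(n, 0, 0.2)
  truth_on <- c(0.5, 1.2, 1.9, 2.5)
  dur <- 0.15
  for (o in truth_on) {
    idx <- (round(o * rate) + 1):(round((o + dur) * rate) + 1)
    x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 1)
  }
  det <- detect_bursts(emg_channel(x, rate))
  expect_equal(nrow(det), length(truth_on))
  for (o in truth_on) expect_lt(min(abs(det$onset_s - o)), 0.010)
})

test_that("burst detection handles generator bursts, baselines and merging", {
  tr <- generate_trial(trial_spec(duration = 3, seed = 9, emg_baseline_sd = 0.2))
  ch <- condition_signal(tr$emg$ax3_L)
  det <- detect_bursts(ch)
  tb <- tr$truth$bursts[tr$truth$bursts$channel == "ax3_L", ]
  expect_equal(nrow(det), nrow(tb))
  # raised-cosine envelopes rise slowly; onsets recovered within 25 ms here
  for (o in tb$onset_s) expect_lt(min(abs(det$onset_s - o)), 0.025)
  # baseline-only signal yields nothing
  base <- emg_channel(stats::rnorm(10000, 0, 0.1), 10000)
  expect_equal(nrow(detect_bursts(base)), 0)
  expect_equal(nrow(detect_bursts(emg_channel(rep(0, 5000), 10000))), 0)
  # two bursts separated by 10 ms merge into one
  x <- rep(0, 10000)
  x[2001:3000] <- 1
  x[3101:4000] <- 1
  merged <- detect_bursts(emg_channel(x, 10000))
  expect_equal(nrow(merged), 1)
})

test_that("duty factor is the burst duration as a share of the cycle", {
  expect_equal(duty_factor(c(0.1, 0.3), c(0, 0.5)), 40)
  expect_equal(duty_factor(c(0, 0.5), c(0, 0.5)), 100)
  expect_equal(duty_factor(c(0, 0.75), c(0, 0.5)), 150)
  expect_error(duty_factor(c(0.3, 0.1), c(0, 0.5)), "offset")
  expect_error(duty_factor(c(0.1, 0.3), c(0.5, 0.5)), "cycle")
})

test_that("theoretical maximum rate is the mean of the top 5% amplitudes", {
  expect_equal(theoretical_max_rate(rep(3.2, 100)), 3.2)
  expect_equal(theoretical_max_rate(1:100), mean(96:100))
  set.seed(5)
  x <- stats::rnorm(500)
  expect_equal(theoretical_max_rate(2 * x), 2 * theoretical_max_rate(x))
  expect_error(theoretical_max_rate(1:10), "at least 20")
  expect_error(theoretical_max_rate(numeric(0)), "empty")
  # pooling a list of channels
  chs <- list(emg_channel(rep(1, 50), 100), emg_channel(rep(3, 50), 100))
  expect_equal(theoretical_max_rate(chs), 3)
})

test_that("RIA normalizes the rectified burst sum exactly", {
  expect_equal(ria(rep(2.5, 400), 2.5), 100)
  expect_equal(ria(rep(0, 400), 2.5), 0)
  expect_equal(ria(rep(1.25, 400), 2.5), 50)
  expect_error(ria(numeric(0), 2.5), "empty")
  expect_error(ria(1:5, 0), "max_rate")
  # gain invariance: scaling the channel cancels through the max rate
  set.seed(6)
  burst <- stats::rnorm(1000)
  pool <- c(burst, stats::rnorm(5000, 0, 0.1))
  r1 <- ria(burst, theoretical_max_rate(pool))
  r2 <- ria(7.3 * burst, theoretical_max_rate(7.3 * pool))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("duty factor is invariant to a common time rescaling", {
  expect_equal(duty_factor(c(0.1, 0.3), c(0, 0.5)),
               duty_factor(10 * c(0.1, 0.3), 10 * c(0, 0.5)))
})

test_that("burst phases follow the tail-stroke convention and flag wrapping", {
  ev <- data.frame(event_type = rep(c("tail_swing_right_start",
                                      "tail_swing_left_start"), 3),
                   time_s = c(0, 0.25, 0.5, 0.75, 1.0, 1.25))
  tseg <- stroke_segmentation("tail", ev)
  b <- data.frame(onset_s = c(0, 0.125, 0.45), offset_s = c(0.1, 0.3, 0.6))
  ph <- burst_phase(b, tseg)
  expect_equal(ph$onset_deg, c(0, 90, 324), tolerance = 1e-9)
  expect_false(ph$wrapped[1])
  expect_true(ph$wrapped[3])           # offset spills into the next cycle
  expect_lt(ph$offset_deg[3], ph$onset_deg[3])
  outside <- data.frame(onset_s = 5, offset_s = 5.1)
  expect_message(ph2 <- burst_phase(outside, tseg), "skipped")
  expect_equal(nrow(ph2), 0)
})

test_that("recovered burst onset phases advance by the generator lag", {
  tr <- clean_trial()
  tseg <- polygait:::trial_tail_segmentation(tr)
  lags <- sapply(paste0("ax", 1:3, "_L"), function(chn) {
    tb <- tr$truth$bursts[tr$truth$bursts$channel == chn, ]
    ph <- suppressMessages(burst_phase(tb[, c("onset_s", "offset_s")], tseg))
    circular_mean_variance(ph$onset_deg)$mean_deg
  })
  expect_lt(abs((lags[2] - lags[1]) %% 360 - 30), 5)
  expect_lt(abs((lags[3] - lags[2]) %% 360 - 30), 5)
})

test_that("co-activation counts interval overlaps against a sweep oracle", {
  a <- data.frame(onset_s = c(0, 1, 2), offset_s = c(0.4, 1.4, 2.4))
  expect_equal(coactivation_count(a, a), list(n_coactive = 3L, n_total = 3L))
  b <- data.frame(onset_s = c(0.5, 1.5, 2.5), offset_s = c(0.9, 1.9, 2.9))
  expect_equal(coactivation_count(a, b)$n_coactive, 0L)
  # exactly one overlapping pair, cross-checked by brute force
  c2 <- data.frame(onset_s = c(0.3, 1.5), offset_s = c(0.6, 1.9))
  brute <- sum(sapply(seq_len(nrow(a)), function(i) {
    any(pmin(a$offset_s[i], c2$offset_s) - pmax(a$onset_s[i], c2$onset_s) > 0)
  }))
  cc <- coactivation_count(a, c2)
  expect_equal(cc$n_coactive, brute)
  expect_equal(cc$n_coactive, 1L)
  expect_equal(coactivation_count(a[0, ], b), list(n_coactive = 0L, n_total = 0L))
})
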