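make_trace <- function(v, fs = 1e5, onsets = numeric(0)) {
  cap_trace((seq_along(v) - 1) / fs, v, fs, onsets)
}

test_that("band-pass rejects line noise and preserves trace geometry", {
  fs <- 1e5
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tr <- make_trace(sin(2 * pi * 60 * t), fs)
  out <- preprocess(tr, band = c(100, 5000), baseline_window = NULL,
                    median_window = NULL)
  # discard filtfilt edge transients before comparing power
  core <- seq(round(0.1 * fs), round(0.9 * fs))
  expect_lt(sqrt(mean(out$v[core]^2)), 0.05 * sqrt(mean(tr$v[core]^2)))
  expect_length(out$v, length(tr$v))
  expect_equal(out$fs, tr$fs)
})

test_that("baseline subtraction removes DC and is idempotent", {
  fs <- 1e4
  v <- rep(3.7, 2 * fs)
  tr <- make_trace(v, fs, onsets = c(0.5, 1.5))
  out <- preprocess(tr, band = NULL, baseline_window = 5e-3,
                    median_window = NULL)
  expect_equal(max(abs(out$v)), 0)
  again <- preprocess(out, band = NULL, baseline_window = 5e-3,
                      median_window = NULL)
  expect_lt(max(abs(again$v - out$v)), 1e-12)
})

test_that("median filter removes single-sample spikes", {
  fs <- 1e5
  v <- numeric(1000)
  v[500] <- 10
  tr <- make_trace(v, fs)
  out <- preprocess(tr, band = NULL, baseline_window = NULL,
                    median_window = 11 / fs)
  expect_lte(out$v[500], stats::median(v[495:505]))
})

test_that("a truncated baseline window warns but still processes", {
  fs <- 1e4
  tr <- make_trace(rep(1, fs), fs, onsets = c(1e-4, 0.5))
  expect_warning(
    preprocess(tr, band = NULL, baseline_window = 5e-3, median_window = NULL),
    "truncated")
})

test_that("epoch extraction averages stimulus-locked sweeps", {
  fs <- 1e4
  epoch <- c(numeric(10), dnorm(seq(-3, 3, length.out = 50)), numeric(40))
  v <- rep(epoch, 5)
  onsets <- (0:4) * length(epoch) / fs
  tr <- make_trace(v, fs, onsets)
  avg <- extract_and_average(tr)
  expect_equal(avg$v, epoch)
  expect_equal(attr(avg, "n_sweeps"), 5)

  tr1 <- make_trace(epoch, fs, 0)
  avg1 <- extract_and_average(tr1)
  expect_equal(avg1$v, epoch)

  expect_error(extract_and_average(make_trace(epoch, fs)), "no stimulus")
})

test_that("averaging suppresses noise by the square-root law", {
  fs <- 1e4
  n_ep <- 100
  len <- 200
  tmpl <- dnorm(seq(-3, 3, length.out = len))
  set.seed(42)
  v <- rep(tmpl, n_ep) + rnorm(n_ep * len, 0, 0.5)
  tr <- make_trace(v, fs, (0:(n_ep - 1)) * len / fs)
  avg <- extract_and_average(tr)
  rms <- sqrt(mean((avg$v - tmpl)^2))
  expect_equal(rms, 0.5 / sqrt(n_ep), tolerance = 0.3)
})

test_that("peak measurement excludes the artifact blanking window", {
  fs <- 1e5
  tau <- seq(0, 10e-3, by = 1 / fs)
  v <- exp(-0.5 * ((tau - 3e-3) / 3e-4)^2)   # 1 mV peak at 3 ms
  m <- measure_cap(data.frame(tau = tau, v = v), artifact_blank = 0.5e-3)
  expect_equal(m$amplitude, 1, tolerance = 1e-9)
  expect_equal(m$latency, 3, tolerance = 1000 / fs * 1000)

  m0 <- measure_cap(data.frame(tau = tau, v = tau * 0))
  expect_equal(m0$amplitude, 0)

  # 5 mV artifact inside the blank window must not win the peak search
  va <- v
  va[tau < 0.3e-3] <- 5
  ma <- measure_cap(data.frame(tau = tau, v = va), artifact_blank = 0.5e-3)
  expect_equal(ma$amplitude, 1, tolerance = 1e-9)
  expect_equal(ma$latency, 3, tolerance = 1000 / fs * 1000)
})

test_that("percent reduction follows the amplitude-ratio definition", {
  expect_equal(cap_reduction(2.0, 1.0), 50)
  expect_equal(cap_reduction(1.6, 1.6), 0)
  expect_equal(cap_reduction(1.6, 0.4), 75)
  for (c0 in c(0.3, 1, 5)) {
    expect_equal(cap_reduction(c0, c0), 0)
    expect_equal(cap_reduction(c0, 0), 100)
  }
  expect_lt(cap_reduction(1, 1.2), 0)   # amplitude increase passes unclamped
  expect_error(cap_reduction(0, 1), "positive")
})

test_that("latency comparison is the pooled two-sample t-test", {
  r <- compare_latencies(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- compare_latencies(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9))
  expect_equal(r2$t, -12.247, tolerance = 1e-4)
  expect_equal(r2$p, 2.552e-4, tolerance = 1e-3)
  r3 <- compare_latencies(c(2, 2), c(2, 2))
  expect_equal(r3$p, 1)
})
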