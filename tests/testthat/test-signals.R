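make_currents <- function(I, comp_neuron) {
  structure(list(time = seq_len(nrow(I)) * 0.1, currents = I,
                 comp_neuron = comp_neuron),
            class = "currents_report")
}

test_that("signal assembly is the weighted current sum", {
  # single compartment: 2 nA x 3e-9 V/nA = 6e-9 V
  cur <- make_currents(matrix(2, 5, 1), 1L)
  tr <- compute_signal(cur, weights_table(3e-9))
  expect_equal(tr$values, rep(6e-9, 5))

  # equal weights + zero-sum per-neuron currents -> identically 0
  I <- cbind(1:5, -(1:5))
  tr0 <- compute_signal(make_currents(I, c(1L, 1L)), weights_table(c(2, 2)))
  expect_equal(tr0$values, rep(0, 5))

  # per-neuron contributions sum to the total
  set.seed(11)
  I <- matrix(rnorm(200), 20)
  cn <- rep(1:2, each = 5)
  tr2 <- compute_signal(make_currents(I, cn), weights_table(runif(10)))
  expect_lt(check_contribution_sum(tr2, tol = 1e-12), 1e-12)
})

test_that("the EEG map is linear in the currents", {
  set.seed(12)
  w <- weights_table(runif(6))
  cn <- rep(1:2, each = 3)
  I1 <- matrix(rnorm(60), 10); I2 <- matrix(rnorm(60), 10)
  a <- 0.7; b <- -1.3
  lhs <- compute_signal(make_currents(a * I1 + b * I2, cn), w)$values
  rhs <- a * compute_signal(make_currents(I1, cn), w)$values +
    b * compute_signal(make_currents(I2, cn), w)$values
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-12)
})

test_that("SEP post-processing extracts, filters and averages correctly", {
  # DC input: the band-pass rejects it entirely in steady state (the 1 Hz
  # high-pass transient needs a record much longer than its time constant)
  fs <- 10000
  x <- rep(5, 10 * fs)
  y <- sepdecomp:::bandpass_zero_phase(x, fs, 1, 500, 2)
  mid <- seq(4 * fs, 6 * fs)
  expect_lt(max(abs(y[mid])), 5 * 1e-3)

  tt <- seq(0, 400, by = 0.1)
  dc <- signal_trace(tt, rep(5, length(tt)))
  out <- postprocess_sep(dc, stimulus_times = c(10, 160),
                         window = c(-10, 100), baseline_correct = FALSE)
  expect_equal(out$time[1], -10)

  # second-response extraction requires two stimuli
  expect_error(postprocess_sep(dc, stimulus_times = 10), "fewer stimuli")

  # invalid bands
  expect_error(postprocess_sep(dc, c(10, 160), filter = c(2, 500, 100)),
               "low >= high")
  expect_error(postprocess_sep(dc, c(10, 160), filter = c(2, 1, 6000)),
               "Nyquist")

  # averaging N copies of one trace reproduces it
  tr <- signal_trace(seq(0, 10, 0.1), sin(seq(0, 10, 0.1)))
  avg <- average_trials(list(tr, tr, tr))
  expect_equal(avg$values, tr$values)

  # two-trial average is the sample-wise mean
  tr2 <- signal_trace(tr$time, cos(tr$time))
  avg2 <- average_trials(list(tr, tr2))
  expect_equal(avg2$values, (tr$values + tr2$values) / 2)
})

test_that("band-pass gains match the analytic Butterworth response", {
  fs <- 10000; low <- 1; high <- 500
  tt <- seq(0, 2, by = 1 / fs)   # seconds
  gain_at <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    y <- sepdecomp:::bandpass_zero_phase(x, fs, low, high, order = 2)
    mid <- seq(round(length(x) * 0.4), round(length(x) * 0.6))
    max(abs(y[mid])) / max(abs(x[mid]))
  }
  # analytic Butterworth band-pass magnitude (order-2 low-pass prototype),
  # squared for the zero-phase forward-backward application, with the
  # bilinear-transform frequency mapping of the digital design
  butter_gain2 <- function(f) {
    warp <- function(fr) 2 * fs * tan(pi * fr / fs)
    w <- warp(f); wl <- warp(low); wh <- warp(high)
    w0 <- sqrt(wl * wh); Q <- w0 / (wh - wl)
    x <- Q * (w / w0 - w0 / w)
    (1 / (1 + x^4))   # |H|^2 with |H|^2 = 1/(1 + x^4) per pass
  }
  expect_equal(gain_at(50), butter_gain2(50), tolerance = 0.01)
  expect_equal(gain_at(2000), butter_gain2(2000), tolerance = 0.05)
  expect_lt(gain_at(2000), 0.01)
})

test_that("filtering preserves the contribution summation invariant", {
  set.seed(13)
  tt <- seq(0, 300, by = 0.1)
  contrib <- matrix(rnorm(length(tt) * 4, sd = 1e-9), ncol = 4)
  raw <- signal_trace(tt, rowSums(contrib), contrib, neuron_ids = 1:4)
  out <- postprocess_sep(raw, stimulus_times = c(10, 160),
                         window = c(-10, 100))
  expect_lt(check_contribution_sum(out, tol = 1e-9), 1e-9)
})

test_that("P1 normalization scales as expected", {
  tt <- seq(-10, 100, 0.1)
  v <- 2e-8 * exp(-(tt - 12)^2 / 8)
  ref <- signal_trace(tt, v)
  self_norm <- normalize_to_p1(ref, ref)
  expect_equal(max(self_norm$values[tt >= 8 & tt <= 16]), 1)

  tr <- signal_trace(tt, 1e-8 * exp(-(tt - 12)^2 / 8))
  out <- normalize_to_p1(tr, ref)
  expect_equal(max(out$values), 0.5, tolerance = 1e-12)

  k <- 3.7
  scaled <- normalize_to_p1(signal_trace(tt, k * tr$values), ref)
  expect_equal(scaled$values, k * out$values)

  neg <- signal_trace(tt, -v)
  expect_error(normalize_to_p1(tr, neg), "positive")
})
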