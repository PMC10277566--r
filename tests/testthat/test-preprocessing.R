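# Band-pass, exponential moving standardization, decimation, epoching.

make_rec <- function(sig, sfreq, events = NULL) {
  if (is.null(events)) events <- data.frame(sample = integer(0),
                                            label = integer(0))
  raw_recording(sig, sfreq, events)
}

test_that("band-pass keeps in-band sinusoids and kills out-of-band ones", {
  sf <- 250
  t <- seq(0, 20, by = 1 / sf)
  amp_after <- function(freq) {
    rec <- make_rec(matrix(sin(2 * pi * freq * t), 1), sf)
    out <- bandpass(rec, 0.5, 40)$signal[1, ]
    mid <- out[(length(out) %/% 4):(3 * length(out) %/% 4)]  # steady state
    max(abs(mid))
  }
  expect_equal(amp_after(10), 1, tolerance = 0.05)
  expect_lt(amp_after(50), 0.1)
  # zero in, zero out (linearity)
  z <- bandpass(make_rec(matrix(0, 2, 1000), sf), 0.5, 40)
  expect_equal(z$signal, matrix(0, 2, 1000))
  expect_error(bandpass(make_rec(matrix(0, 1, 100), sf), 40, 0.5),
               "invalid band")
  expect_error(bandpass(make_rec(matrix(0, 1, 100), sf), 0.5, 200),
               "invalid band")
})

test_that("exponential moving standardization normalizes as specified", {
  sf <- 100
  # constant signal -> 0 after burn-in
  rec <- make_rec(matrix(5, 1, 5000), sf)
  out <- ema_standardize(rec, factor_new = 0.01, eps = 1e-4)$signal[1, ]
  expect_lt(max(abs(out[1000:5000])), 1e-6)
  # long white noise -> unit output variance within 10%
  set.seed(1)
  rec2 <- make_rec(matrix(rnorm(1e5, sd = 7), 1), sf)
  out2 <- ema_standardize(rec2, factor_new = 1e-3)$signal[1, ]
  expect_equal(stats::var(out2[20000:1e5]), 1, tolerance = 0.1)
  # eps above the signal sd: variance floor active, output ~ (x - mean)/eps
  rec3 <- make_rec(matrix(rnorm(5000, sd = 0.001), 1), sf)
  big_eps <- 1
  out3 <- ema_standardize(rec3, factor_new = 1e-3, eps = big_eps)$signal[1, ]
  x <- rec3$signal[1, ]
  a <- 1e-3
  m <- as.numeric(stats::filter(a * x, 1 - a, method = "recursive",
                                init = mean(x[1:1000])))
  expect_equal(out3, (x - m) / big_eps, tolerance = 1e-12)
  expect_error(ema_standardize(rec, factor_new = 2), "factor_new")
})

test_that("decimation preserves in-band content and rescales events", {
  sf <- 1000
  t <- seq(0, 8, by = 1 / sf)
  sig <- matrix(sin(2 * pi * 10 * t), 1)
  rec <- make_rec(sig, sf, data.frame(sample = 4000L, label = 0L))
  dn <- downsample(rec, 250)
  expect_equal(dn$sfreq, 250)
  expect_equal(dn$events$sample, 1000L)
  # spectral peak still at 10 Hz with amplitude within 5%
  mid <- dn$signal[1, 500:1500]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)
  pk <- band_power(dn$signal[1, ], 250, c(9, 11))
  tot <- band_power(dn$signal[1, ], 250, c(0, 125))
  expect_gt(pk / tot, 0.95)
  expect_error(downsample(rec, 333), "integer multiple")
})

test_that("epoching arithmetic and bounds handling are exact", {
  sf <- 250
  sig <- matrix(rnorm(10 * sf * 10), 10)  # 10 channels, 10 s
  ev <- data.frame(sample = c(500L, 1200L), label = c(0L, 1L))
  rec <- make_rec(sig, sf, ev)
  ep <- epoch(rec, -0.5, 4)
  expect_equal(dim(ep$data), c(2, 10, 1125))
  expect_equal(ep$labels, c(0L, 1L))
  # values are the raw samples, window start inclusive
  expect_equal(ep$data[1, 3, 1], sig[3, 500 - 125 + 1])
  # one-sample window
  ep1 <- epoch(rec, 0, 0.004)
  expect_equal(dim(ep1$data)[3], 1)
  # an event whose window exceeds the bounds is dropped with a warning
  rec2 <- make_rec(sig, sf, data.frame(sample = c(10L, 1200L),
                                       label = c(0L, 1L)))
  expect_warning(ep2 <- epoch(rec2, -0.5, 4), "dropped")
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$labels, 1L)
})

test_that("channel-wise operations commute with channel permutation", {
  set.seed(4)
  sig <- matrix(rnorm(4 * 2000), 4)
  rec <- make_rec(sig, 250)
  perm <- c(3, 1, 4, 2)
  f1 <- bandpass(rec, 0.5, 40)$signal[perm, ]
  rec_p <- make_rec(sig[perm, ], 250)
  f2 <- bandpass(rec_p, 0.5, 40)$signal
  expect_equal(f1, f2)
  s1 <- ema_standardize(rec)$signal[perm, ]
  s2 <- ema_standardize(rec_p)$signal
  expect_equal(s1, s2)
})
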