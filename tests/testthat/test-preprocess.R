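sine_rec <- function(freq, dur = 600, fs = 20, amp = 1) {
  sched <- build_schedule(1, 2, seed = 1, sample_rate = fs)
  n <- nirsbci:::n_samples(sched)
  t <- (seq_len(n) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  make_hemo(rbind(x), rbind(-x / 3), sched)
}

test_that("band-pass maps zero to zero and preserves shape", {
  sched <- build_schedule(1, 2, seed = 1)
  z <- matrix(0, 3, nirsbci:::n_samples(sched))
  out <- nirs_bandpass(make_hemo(z, z, sched))
  expect_equal(dim(out$hbo), dim(z))
  expect_true(all(abs(out$hbo) < 1e-14))
})

test_that("stop-band sines are attenuated per the analytic response", {
  spec <- filter_spec()
  for (f in c(1.4, 0.2)) {   # cardiac band, respiration band
    rec <- sine_rec(f)
    out <- nirs_bandpass(rec, spec)
    # amplitude gain of the forward-backward filter is |H(f)|^2
    gain <- central_rms(out$hbo[1, ]) / central_rms(rec$hbo[1, ])
    expected <- analog_bp_gain_fb(f, spec$low, spec$high)
    expect_lt(abs(gain - expected) / expected, 0.05)
    # output RMS / input RMS is at most the squared single-pass magnitude
    expect_lte(gain, expected)
  }
})

test_that("band-center sine passes with near-unit gain", {
  spec <- filter_spec()
  f0 <- sqrt(spec$low * spec$high)   # ~0.0447 Hz
  rec <- sine_rec(f0, dur = 1800)
  out <- nirs_bandpass(rec, spec)
  gain <- central_rms(out$hbo[1, ]) / central_rms(rec$hbo[1, ])
  expect_gte(gain, 0.9 * analog_bp_gain_fb(f0, spec$low, spec$high))
})

test_that("band edges beyond Nyquist are rejected", {
  rec <- sine_rec(0.05)
  expect_error(nirs_bandpass(rec, filter_spec(high = 15)), "Nyquist")
})

test_that("CBSI leaves perfectly anti-correlated channels unchanged", {
  sched <- build_schedule(1, 2, seed = 2)
  set.seed(1)
  x <- matrix(rnorm(2 * nirsbci:::n_samples(sched)), 2)
  out <- cbsi_correct(make_hemo(x, -x, sched))
  expect_equal(out$hbo, x, tolerance = 1e-12)
  expect_equal(out$hbr, -x, tolerance = 1e-12)
})

test_that("CBSI output channels have Pearson correlation exactly -1", {
  sched <- build_schedule(1, 2, seed = 2)
  set.seed(7)
  n <- nirsbci:::n_samples(sched)
  out <- cbsi_correct(make_hemo(matrix(rnorm(3 * n), 3),
                                matrix(rnorm(3 * n, sd = 2), 3), sched))
  for (ch in 1:3) {
    expect_equal(cor(out$hbo[ch, ], out$hbr[ch, ]), -1, tolerance = 1e-8)
  }
})

test_that("CBSI cancels a spike shared by HbO and HbR when alpha = 1", {
  sched <- build_schedule(1, 2, seed = 2)
  n <- nirsbci:::n_samples(sched)
  base <- rep(c(1, -1), length.out = n) * 0.5   # zero-mean carrier
  s <- numeric(n); s[100] <- 4; s[101] <- 4     # spike on a +1/-1 pair
  # cov(base, s) = 0 by construction, so sd(hbo) == sd(hbr) and alpha = 1
  out <- cbsi_correct(make_hemo(rbind(base + s), rbind(-base + s), sched))
  expect_equal(as.numeric(out$hbo), base, tolerance = 1e-10)
})

test_that("CBSI passes zero-variance HbR channels through with a warning", {
  sched <- build_schedule(1, 2, seed = 2)
  n <- nirsbci:::n_samples(sched)
  x <- rbind(sin(seq_len(n) / 50))
  expect_warning(out <- cbsi_correct(make_hemo(x, 0 * x, sched)),
                 "zero-variance")
  expect_equal(out$hbo, x)
})

test_that("baseline correction removes lines, re-zeros the baseline, ignores offsets", {
  sched <- build_schedule(1, 2, seed = 3)
  n <- nirsbci:::n_samples(sched)
  t <- (seq_len(n) - 1) / 20
  # pure line -> identically zero
  out <- baseline_correct(make_hemo(rbind(0.3 * t + 2), rbind(-0.1 * t + 1),
                                    sched))
  expect_lt(max(abs(out$hbo)), 1e-9)
  # random signal: baseline-segment mean is zero afterwards
  set.seed(5)
  x <- rbind(rnorm(n))
  out <- baseline_correct(make_hemo(x, x, sched))
  bidx <- 1:(60 * 20)
  expect_lt(abs(mean(out$hbo[1, bidx])), 1e-10)
  # adding a constant leaves the output unchanged
  out2 <- baseline_correct(make_hemo(x + 5, x + 5, sched))
  expect_equal(out2$hbo, out$hbo, tolerance = 1e-9)
})

test_that("preprocessing pipeline is shape-preserving and deterministic", {
  cfg <- synth_config(seed = 23)
  od <- synth_subject(cfg, 1, 4)
  h <- mbll_convert(od)
  p1 <- preprocess(h)
  p2 <- preprocess(h)
  expect_identical(p1$hbo, p2$hbo)
  expect_equal(dim(p1$hbo), dim(h$hbo))
})
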