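test_that("resampling changes length arithmetically and preserves tone frequency and amplitude", {
  rec <- recording(matrix(rnorm(2500), 1), fs = 2500)
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$signal), 256L)
  expect_equal(out$fs, 256)

  rec2 <- recording(matrix(rnorm(512), 1), fs = 256)
  expect_identical(resample_recording(rec2, 256), rec2)

  # 10 Hz tone at 2500 Hz -> 256 Hz: spectral peak stays at 10 Hz with < 1%
  # amplitude error (FFT oracle, edges trimmed against filter transients)
  t <- seq(0, 20, by = 1 / 2500)[-1]
  tone <- recording(matrix(50 * sin(2 * pi * 10 * t), 1), fs = 2500)
  res <- resample_recording(tone, 256)
  mid <- res$signal[1, (2 * 256 + 1):(18 * 256)]
  sp <- abs(stats::fft(mid)) * 2 / length(mid)
  f <- (seq_along(mid) - 1) * 256 / length(mid)
  pk <- which.max(sp[f <= 128])
  expect_lt(abs(f[pk] - 10), 0.1)
  expect_lt(abs(max(sp) - 50) / 50, 0.01)
})

test_that("resampling carries the validity mask by nearest neighbour", {
  vm <- rep(TRUE, 2560)
  vm[1281:2560] <- FALSE                # second half invalid
  rec <- recording(matrix(rnorm(2560), 1), fs = 512, valid_mask = vm)
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$signal), 1280L)
  expect_true(all(out$valid_mask[1:630]))
  expect_false(any(out$valid_mask[650:1280]))
})

test_that("band-pass and notch filtering meet their attenuation contracts", {
  fs <- 256
  n <- fs * 30
  # DC offset removed
  dc <- recording(matrix(100, 1, n), fs = fs)
  fdc <- filter_eeg(dc)
  expect_lt(abs(mean(fdc$signal)), 0.1)

  # 50 Hz tone attenuated by >= 20 dB
  t <- seq_len(n) / fs
  hum <- recording(matrix(100 * sin(2 * pi * 50 * t), 1), fs = fs)
  fh <- filter_eeg(hum)
  mid <- (5 * fs):(25 * fs)
  atten <- 20 * log10(stats::sd(hum$signal[1, mid]) / stats::sd(fh$signal[1, mid]))
  expect_gte(atten, 20)

  # white noise: out-of-band power fraction < 5% (periodogram oracle)
  set.seed(1)
  wn <- recording(matrix(rnorm(n), 1), fs = fs)
  fw <- filter_eeg(wn)
  x <- fw$signal[1, ]
  inband <- band_power_oracle(x, fs, c(0.5, 100))
  total <- band_power_oracle(x, fs, c(0, 128.01))
  expect_lt(1 - inband / total, 0.05)

  # idempotence up to tolerance: a second pass removes < 1% of the signal
  # power (the residual lives in the filters' finite transition bands)
  f2 <- filter_eeg(fw)
  expect_lt(stats::var(f2$signal[1, mid] - fw$signal[1, mid]) /
              stats::var(fw$signal[1, mid]), 0.01)

  expect_error(filter_eeg(wn, band = c(0, 100)), "pass band")
  expect_error(filter_eeg(wn, band = c(10, 200)), "pass band")
})

test_that("amplitude-threshold artifact rejection marks spike neighbourhoods invalid", {
  fs <- 256
  set.seed(2)
  sig <- matrix(rnorm(fs * 60, sd = 20), 1)
  rec <- recording(sig, fs = fs)
  clean <- reject_artifacts(rec, amp_thresh = 300)
  expect_identical(clean$valid_mask, rec$valid_mask)

  spike_at <- 30 * fs
  sig2 <- sig
  sig2[1, spike_at] <- 500
  rec2 <- reject_artifacts(recording(sig2, fs = fs), amp_thresh = 300,
                           pad_s = 0.25)
  pad <- round(0.25 * fs)
  expect_false(any(rec2$valid_mask[(spike_at - pad):(spike_at + pad)]))
  expect_true(all(rec2$valid_mask[1:(spike_at - pad - 2)]))
})

test_that("rejected fraction tracks the generator's injected artifact duration", {
  sp <- sim_spec(duration = 10 * 3600, n_channels = 1L, artifact_rate = 6,
                 seed = 6)
  ds <- generate_recording(sp)
  truth_frac <- sum(ds$artifact_truth[, 2] - ds$artifact_truth[, 1]) /
    sp$duration
  rec <- reject_artifacts(ds$recording, amp_thresh = 300)
  invalid_frac <- mean(!rec$valid_mask)
  expect_gt(invalid_frac, 0)
  expect_lt(invalid_frac, 2 * truth_frac)
})

test_that("segmentation yields non-overlapping 10-s windows with the validity rule", {
  fs <- 256
  rec <- recording(matrix(0, 1, fs * 3600), fs = fs)
  ws <- segment(rec)
  expect_equal(length(ws$valid), 360L)
  expect_true(all(ws$valid))
  expect_equal(dim(ws$data)[2], 2560L)
  expect_equal(diff(ws$start_times), rep(10, 359))

  expect_equal(length(segment(recording(matrix(0, 1, fs * 25), fs))$valid), 2L)
  expect_equal(length(segment(recording(matrix(0, 1, fs * 9), fs))$valid), 0L)

  vm <- rep(TRUE, fs * 200)
  vm[(95 * fs + 1):(105 * fs)] <- FALSE
  wsv <- segment(recording(matrix(0, 1, fs * 200), fs, valid_mask = vm))
  expect_false(wsv$valid[10])   # window starting at 90 s
  expect_false(wsv$valid[11])   # window starting at 100 s
  expect_true(all(wsv$valid[-c(10, 11)]))
  # relaxed rule: the 50%-invalid windows pass at min_valid_frac = 0.4
  wsr <- segment(recording(matrix(0, 1, fs * 200), fs, valid_mask = vm),
                 min_valid_frac = 0.4)
  expect_true(all(wsr$valid))

  # segmentation preserves the samples it keeps
  sig <- matrix(as.numeric(seq_len(fs * 25)), 1)
  wss <- segment(recording(sig, fs))
  expect_identical(as.vector(wss$data[1, , 2]), as.numeric(sig[1, 2561:5120]))
})

test_that("normalisation statistics and standardization behave algebraically", {
  expect_error(compute_norm_stats(fake_window_set(3, valid = rep(FALSE, 3))),
               "no valid windows")

  zeros <- segment(recording(matrix(0, 2, 2560 * 4), 256))
  st0 <- compute_norm_stats(zeros)
  expect_equal(st0$mean, c(0, 0))
  expect_equal(st0$sd, rep(st0$eps, 2))

  set.seed(3)
  big <- segment(recording(matrix(rnorm(2560 * 1000), 1), 256))
  st <- compute_norm_stats(big)
  expect_lt(abs(st$mean), 0.01)
  expect_lt(abs(st$sd - 1), 0.01)

  # identity stats, constant channel, and inversion round trip
  ws <- segment(recording(matrix(rnorm(2560 * 5, 4, 2), 1), 256))
  ident <- structure(list(mean = 0, sd = 1, eps = 1e-6, n_windows = 5L),
                     class = "norm_stats")
  expect_equal(standardize(ws, ident)$data, ws$data)
  st <- compute_norm_stats(ws)
  const <- segment(recording(matrix(st$mean[1], 1, 2560 * 2), 256))
  expect_true(all(abs(standardize(const, st)$data) < 1e-9))
  z <- standardize(ws, st)
  back <- z$data * st$sd[1] + st$mean[1]
  expect_equal(back, ws$data, tolerance = 1e-12)

  st2 <- structure(list(mean = c(0, 0), sd = c(1, 1), eps = 1e-6,
                        n_windows = 1L), class = "norm_stats")
  expect_error(standardize(ws, st2), "channel count mismatch")

  # own stats applied to the same set give mean 0, sd 1 per channel
  zz <- standardize(big, compute_norm_stats(big))
  expect_lt(abs(mean(zz$data)), 1e-10)
  expect_lt(abs(stats::sd(as.vector(zz$data)) - 1), 1e-3)
})

test_that("standardizing commutes with segmentation", {
  set.seed(4)
  sig <- matrix(rnorm(2560 * 6, 2, 3), 2)
  rec <- recording(sig, 256)
  ws <- segment(rec)
  st <- compute_norm_stats(ws)
  a <- standardize(ws, st)$data
  pre <- rec
  pre$signal <- (sig - st$mean) / st$sd
  b <- segment(pre)$data
  expect_equal(a, b, tolerance = 1e-12)
})
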