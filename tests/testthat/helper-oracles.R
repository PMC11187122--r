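# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths: band power comes
# from a raw FFT periodogram, the firing-power / alarm / adjudication
# oracles are naive loops over definitions.

# total periodogram power of x in [band[1], band[2]) Hz
band_power_oracle <- function(x, fs, band) {
  n <- length(x)
  P <- abs(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(P[f >= band[1] & f < band[2]])
}

rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# naive trailing moving average over the zero-filled nominal grid
fp_oracle <- function(times, o, valid, tau, step = 10) {
  t0 <- times[1]
  n <- round((times[length(times)] - t0) / step) + 1
  og <- numeric(n)
  for (i in seq_along(times)) {
    if (valid[i]) og[round((times[i] - t0) / step) + 1] <- o[i]
  }
  vapply(seq_len(n), function(k) sum(og[max(1, k - tau + 1):k]) / tau, 0)
}

# explicit state machine over the firing-power trace
alarm_oracle <- function(times, fp, warmup, threshold, refractory) {
  out <- numeric()
  below <- TRUE
  ref_until <- -Inf
  for (i in seq_along(fp)) {
    if (fp[i] >= threshold) {
      if (below) {
        if (!warmup[i] && times[i] >= ref_until) {
          out <- c(out, times[i])
          ref_until <- times[i] + refractory
        }
        below <- FALSE
      }
    } else {
      below <- TRUE
    }
  }
  out
}

# pairwise interval check of alarm truth and per-seizure prediction
adjudicate_oracle <- function(alarms, onsets, sph_sec, sop_sec) {
  kind <- rep(FALSE, length(alarms))
  pred <- rep(FALSE, length(onsets))
  for (i in seq_along(alarms)) {
    for (j in seq_along(onsets)) {
      if (onsets[j] >= alarms[i] + sph_sec &&
          onsets[j] <= alarms[i] + sph_sec + sop_sec) {
        kind[i] <- TRUE
        pred[j] <- TRUE
      }
    }
  }
  list(kind = kind, predicted = pred)
}

# exact one-tailed signed-rank p-value by enumerating all sign assignments
wilcoxon_exact_oracle <- function(x, y, alternative = "less") {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vnull <- signs %*% r
  v <- sum(r[d > 0])
  if (alternative == "less") mean(vnull <= v) else mean(vnull >= v)
}

# minimal window_set carrying only timing/label plumbing (1 sample/window)
fake_window_set <- function(n, window_s = 10, valid = rep(TRUE, n)) {
  structure(list(data = array(0, c(1, 2, n)),
                 start_times = (seq_len(n) - 1) * window_s,
                 valid = valid, fs = 256, window_s = window_s,
                 norm_stats = NULL),
            class = "window_set")
}

tiny_dcae_cfg <- function(dropout = 0) {
  dcae_config(enc_filters = c(3L, 4L), kernel = 3L, strides = c(2L, 2L),
              dec_filters = c(3L, NA_integer_), upsample = c(2L, 2L),
              spatial_dropout = dropout)
}

# a small standardized window corpus for optimiser smoke tests
tiny_corpus <- function(n_windows, n_channels = 2L, len = 64L, seed = 1) {
  set.seed(seed)
  t <- seq_len(len) / 64
  data <- array(0, c(n_channels, len, n_windows))
  for (i in seq_len(n_windows)) {
    ph <- runif(n_channels, 0, 2 * pi)
    for (ch in seq_len(n_channels)) {
      data[ch, , i] <- sin(2 * pi * 4 * t + ph[ch]) + 0.3 * rnorm(len)
    }
  }
  structure(list(data = data, start_times = (seq_len(n_windows) - 1) * 10,
                 valid = rep(TRUE, n_windows), fs = 256, window_s = 10,
                 norm_stats = NULL),
            class = "window_set")
}
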