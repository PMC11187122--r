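# Preprocessing: turn raw multichannel recordings into standardized,
# validity-masked 10-second windows at 256 Hz.
#
# Time convention: timestamps are seconds from recording start; intervals
# are half-open [start, end).

#' Construct a recording
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param t0 Absolute start time in seconds (kept at 0 throughout the
#'   pipeline; all downstream timestamps are relative to recording start).
#' @param channel_names Optional channel labels.
#' @param valid_mask Per-sample logical validity mask.
#' @return A `recording` object.
#' @export
recording <- function(signal, fs, t0 = 0, channel_names = NULL,
                      valid_mask = NULL) {
  stopifnot(is.matrix(signal), fs > 0)
  if (is.null(channel_names)) channel_names <- paste0("EEG", seq_len(nrow(signal)))
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(signal))
  stopifnot(length(valid_mask) == ncol(signal),
            length(channel_names) == nrow(signal))
  structure(list(signal = signal, fs = fs, t0 = t0,
                 channel_names = channel_names, valid_mask = valid_mask),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s, %.1f%% valid)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
              100 * mean(x$valid_mask)))
  invisible(x)
}

# best rational approximation p/q to x by continued fractions
rational_approx <- function(x, max_den = 10000L, tol = 1e-9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  if (abs(p1 / q1 - x) > tol) return(NULL)
  c(p = p1, q = q1)
}

# Polyphase rational resampling by L/M with a linear-phase windowed-sinc
# anti-aliasing filter (gain-exact in the passband, unlike
# signal::resample, whose short design filter shows several percent of
# passband gain error). Each of the L phases is one causal FIR pass
# evaluated by overlap-free FFT convolution.
resample_poly <- function(x, L, M, K = 10L) {
  n <- length(x)
  N <- 2L * K * max(L, M) + 1L            # odd, symmetric FIR
  h <- L * signal::fir1(N - 1L, min(1 / L, 1 / M))
  n_out <- round(n * L / M)
  D <- (N - 1L) %/% 2L                    # group delay, upsampled samples
  m <- seq_len(n_out) - 1L
  u <- m * M + D
  r <- u %% L
  s <- (u - r) %/% L                      # 0-based input index of tap 0
  pad <- ceiling(N / L) + 1L
  xp <- c(x, numeric(pad))
  y <- numeric(n_out)
  for (ph in unique(r)) {
    h_ph <- h[seq(ph + 1L, N, by = L)]
    z <- signal::fftfilt(h_ph, xp)
    sel <- r == ph
    y[sel] <- z[s[sel] + 1L]
  }
  y
}

#' Resample a recording
#'
#' Polyphase rational resampling channel by channel; the validity mask is
#' carried over by nearest-neighbour lookup.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate, Hz (e.g. 256).
#' @return The resampled recording with
#'   `round(samples * target_fs / fs)` samples.
#' @export
resample_recording <- function(rec, target_fs = 256) {
  stopifnot(inherits(rec, "recording"), target_fs > 0)
  if (rec$fs == target_fs) return(rec)
  pq <- rational_approx(target_fs / rec$fs)
  if (is.null(pq)) {
    stop("resampling ratio ", target_fs, "/", rec$fs,
         " has no rational approximation within tolerance")
  }
  n_in <- ncol(rec$signal)
  n_out <- round(n_in * target_fs / rec$fs)
  out <- matrix(0, nrow(rec$signal), n_out)
  for (ch in seq_len(nrow(rec$signal))) {
    y <- resample_poly(rec$signal[ch, ], pq[["p"]], pq[["q"]])
    out[ch, ] <- y[seq_len(min(n_out, length(y)))]
  }
  src <- pmin(pmax(floor((seq_len(n_out) - 0.5) * rec$fs / target_fs) + 1L, 1L),
              n_in)
  recording(out, fs = target_fs, t0 = rec$t0,
            channel_names = rec$channel_names,
            valid_mask = rec$valid_mask[src])
}

# zero-phase filtering with odd-reflection end padding so edge transients
# decay inside the padding, not the data
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(flt, xp)
  y[(p + 1):(p + n)]
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase (forward-backward) filtering with odd-reflection end padding:
#' a 2nd-order Butterworth high-pass at `band[1]`, a 4th-order Butterworth
#' low-pass at `band[2]`, and a 2nd-order Butterworth band-stop notch of
#' width `notch_width` centred on `notch`. The cascade is used instead of a
#' single band-pass because a direct Butterworth band-pass with a very low
#' normalized lower edge (0.5 Hz at 256 Hz) is numerically fragile.
#'
#' @param rec A [recording()].
#' @param band `c(low, high)` pass band in Hz; `0 < low < high < fs/2`.
#' @param notch Power-line frequency in Hz (`NULL` to skip).
#' @param notch_width Full stop-band width in Hz.
#' @return The filtered recording (same length, mask untouched).
#' @export
filter_eeg <- function(rec, band = c(0.5, 100), notch = 50, notch_width = 4) {
  stopifnot(inherits(rec, "recording"))
  ny <- rec$fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < ny)) {
    stop("pass band must satisfy 0 < low < high < fs/2 = ", ny)
  }
  hp <- signal::butter(2, band[1] / ny, type = "high")
  lp <- signal::butter(4, band[2] / ny, type = "low")
  bs <- if (!is.null(notch)) {
    signal::butter(2, c(notch - notch_width / 2, notch + notch_width / 2) / ny,
                   type = "stop")
  }
  pad <- round(6 * rec$fs / band[1])   # several settle times of the slowest pole
  out <- rec$signal
  for (ch in seq_len(nrow(out))) {
    x <- filtfilt_padded(hp, out[ch, ], pad)
    x <- filtfilt_padded(lp, x, pad)
    if (!is.null(bs)) x <- filtfilt_padded(bs, x, pad)
    out[ch, ] <- x
  }
  rec$signal <- out
  rec
}

#' Mark high-amplitude artifacts invalid
#'
#' Samples whose absolute amplitude exceeds `amp_thresh` on any channel are
#' marked invalid in the validity mask, together with `pad_s` seconds on
#' each side. Signal values are not altered.
#'
#' @param rec A [recording()].
#' @param amp_thresh Amplitude threshold, microvolts (> 0).
#' @param pad_s Padding around each offending sample, seconds.
#' @return The recording with an updated `valid_mask`.
#' @export
reject_artifacts <- function(rec, amp_thresh = 300, pad_s = 0.25) {
  stopifnot(inherits(rec, "recording"), amp_thresh > 0)
  n <- ncol(rec$signal)
  bad <- colSums(abs(rec$signal) > amp_thresh) > 0
  if (any(bad)) {
    pad <- round(pad_s * rec$fs)
    cs <- cumsum(as.integer(bad))
    hi <- cs[pmin(seq_len(n) + pad, n)]
    lo_idx <- seq_len(n) - pad - 1L
    lo <- ifelse(lo_idx < 1L, 0L, cs[pmax(lo_idx, 1L)])
    rec$valid_mask <- rec$valid_mask & (hi - lo == 0L)
  }
  rec
}

#' Segment a recording into non-overlapping 10-second windows
#'
#' @param rec A [recording()] (the pipeline uses 256 Hz).
#' @param window_s Window length in seconds.
#' @param min_valid_frac A window is valid iff at least this fraction of its
#'   samples is valid (default 1: fully valid). A trailing partial window is
#'   dropped.
#' @return A `window_set`: `data` array `(channels, window samples,
#'   n_windows)`, `start_times` (s, strictly increasing), `valid`, `fs`,
#'   `norm_stats` (absent until [standardize()]).
#' @export
segment <- function(rec, window_s = 10, min_valid_frac = 1) {
  stopifnot(inherits(rec, "recording"))
  wl <- round(window_s * rec$fs)
  nw <- floor(ncol(rec$signal) / wl)
  if (nw == 0L) {
    return(structure(list(data = array(0, c(nrow(rec$signal), wl, 0)),
                          start_times = numeric(), valid = logical(),
                          fs = rec$fs, window_s = window_s,
                          norm_stats = NULL),
                     class = "window_set"))
  }
  used <- seq_len(nw * wl)
  data <- rec$signal[, used, drop = FALSE]
  dim(data) <- c(nrow(rec$signal), wl, nw)
  vm <- matrix(rec$valid_mask[used], wl, nw)
  valid_frac <- colMeans(vm)
  structure(list(data = data,
                 start_times = (seq_len(nw) - 1) * window_s,
                 valid = valid_frac >= min_valid_frac,
                 fs = rec$fs, window_s = window_s, norm_stats = NULL),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d ch @ %g Hz), %d valid%s\n",
              length(x$valid), x$window_s, dim(x$data)[1], x$fs,
              sum(x$valid),
              if (is.null(x$norm_stats)) "" else ", standardized"))
  invisible(x)
}

#' Per-channel normalisation statistics
#'
#' Mean and standard deviation per channel over all samples of valid
#' windows; the sd is floored at `eps` so flat channels cannot blow up the
#' division.
#'
#' @param ws A `window_set`.
#' @param eps Standard-deviation floor (microvolts).
#' @return A `norm_stats` list: `mean`, `sd` (per channel), `eps`,
#'   `n_windows`.
#' @export
compute_norm_stats <- function(ws, eps = 1e-6) {
  stopifnot(inherits(ws, "window_set"))
  if (!any(ws$valid)) stop("no valid windows to compute statistics from")
  x <- ws$data[, , ws$valid, drop = FALSE]
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  m <- rowMeans(x)
  sdv <- sqrt(pmax(rowMeans(x * x) - m * m, 0))
  structure(list(mean = m, sd = pmax(sdv, eps), eps = eps,
                 n_windows = sum(ws$valid)),
            class = "norm_stats")
}

#' Standardize windows with given statistics
#'
#' `(x - mean) / sd` per channel. In the standard training mode the
#' statistics come from the patient's own training windows; in the transfer
#' mode from the source corpus used to pretrain the autoencoder.
#'
#' @param ws A `window_set`.
#' @param stats A `norm_stats` (provenance is recorded in `ws$norm_stats`).
#' @return The standardized window set.
#' @export
standardize <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "norm_stats"))
  if (length(stats$mean) != dim(ws$data)[1]) {
    stop("channel count mismatch: stats have ", length(stats$mean),
         " channels, windows have ", dim(ws$data)[1])
  }
  if (!all(is.finite(stats$mean)) || !all(is.finite(stats$sd)) ||
      any(stats$sd <= 0)) {
    stop("normalisation statistics must be finite with sd > 0")
  }
  d <- dim(ws$data)
  x <- ws$data
  dim(x) <- c(d[1], d[2] * d[3])
  x <- (x - stats$mean) / stats$sd
  dim(x) <- d
  ws$data <- x
  ws$norm_stats <- stats
  ws
}
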