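# Synthetic scalp-EEG simulator.
#
# The background is a sum of four band-limited Gaussian processes (delta,
# theta, alpha, beta) whose amplitudes scale as 1/f of the band centre,
# giving an EEG-like 1/f-weighted spectrum. A controllable preictal
# signature multiplies the alpha-band amplitude by a linear ramp over the
# 40 minutes before each seizure onset, so the preictal state is learnable
# with a tunable effect size. Sparse high-amplitude transients emulate
# artifacts; recording gaps are carried in a per-sample validity mask.

SIM_BANDS <- list(
  delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)
)

#' Simulation specification
#'
#' @param duration Recording length in seconds.
#' @param seizure_onsets Ordered seizure onset times in seconds.
#' @param n_channels Number of EEG channels (10-20 montage default: 19).
#' @param fs Sampling rate in Hz.
#' @param preictal_len Length of the pre-onset span carrying the signature,
#'   seconds (SOP + SPH; 40 min).
#' @param signature_strength Dimensionless effect size `>= 0`: at onset the
#'   signature band's amplitude is multiplied by `1 + signature_strength`.
#' @param signature_band Band carrying the signature (`"alpha"` default).
#' @param gap_spec List of `c(start, end)` second pairs marked invalid.
#' @param artifact_rate High-amplitude transient events per hour.
#' @param seizure_offsets Optional; defaults to onsets + 60 s.
#' @param total_amp_sd Total background standard deviation, microvolts.
#' @param seed Integer RNG seed; identical specs and seeds give
#'   bit-identical recordings (R's default Mersenne-Twister).
#' @return A validated `sim_spec` object.
#' @export
sim_spec <- function(duration, seizure_onsets = numeric(), n_channels = 19L,
                     fs = 256L, preictal_len = 2400, signature_strength = 0,
                     signature_band = "alpha", gap_spec = list(),
                     artifact_rate = 0, seizure_offsets = NULL,
                     total_amp_sd = 20, seed = 1L) {
  onsets <- as.numeric(seizure_onsets)
  if (length(onsets) && any(diff(onsets) <= 0)) {
    stop("seizure onsets must be strictly increasing")
  }
  if (length(onsets) && any(onsets < preictal_len)) {
    stop("seizure onsets must lie at least preictal_len (", preictal_len,
         " s) after the recording start")
  }
  if (length(onsets) && any(onsets > duration)) {
    stop("seizure onsets must lie within [0, duration]")
  }
  if (signature_strength < 0) stop("signature_strength must be >= 0")
  if (!signature_band %in% names(SIM_BANDS)) {
    stop("signature_band must be one of: ",
         paste(names(SIM_BANDS), collapse = ", "))
  }
  if (length(gap_spec)) {
    gm <- do.call(rbind, gap_spec)
    if (any(gm[, 1] >= gm[, 2]) || any(gm < 0) || any(gm > duration)) {
      stop("gaps must be ordered (start < end) and lie within [0, duration]")
    }
    o <- order(gm[, 1])
    if (nrow(gm) > 1 && any(gm[o, 1][-1] < gm[o, 2][-nrow(gm)])) {
      stop("gap intervals must not overlap")
    }
  }
  if (is.null(seizure_offsets)) seizure_offsets <- onsets + 60
  structure(list(duration = duration, seizure_onsets = onsets,
                 seizure_offsets = as.numeric(seizure_offsets),
                 n_channels = as.integer(n_channels), fs = as.integer(fs),
                 preictal_len = preictal_len,
                 signature_strength = signature_strength,
                 signature_band = signature_band, gap_spec = gap_spec,
                 artifact_rate = artifact_rate, total_amp_sd = total_amp_sd,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

band_limited_noise <- function(n, fs, band, sd_target) {
  ny <- fs / 2
  bf <- signal::butter(2, band / ny, type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  x * (sd_target / max(stats::sd(x), 1e-12))
}

#' Generate a synthetic annotated EEG recording
#'
#' Background EEG is the sum of four band-limited Gaussian noise processes
#' with amplitudes proportional to the inverse band-centre frequency. If
#' `spec$signature_strength > 0`, [inject_preictal_signature()] is applied.
#' The generated signature-band component is retained so the signature can
#' be injected multiplicatively afterwards.
#'
#' @param spec A [sim_spec()].
#' @return A `synthetic_dataset`: `recording` (a [recording()]),
#'   `annotations` (a [seizure_annotation()]), `spec`, the stored
#'   `signature_component`, and ground-truth `artifact_truth` intervals.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  fc <- vapply(SIM_BANDS, mean, 0)
  w <- (1 / fc) / sqrt(sum((1 / fc)^2))      # per-band sd weights
  sds <- spec$total_amp_sd * w

  sig <- matrix(0, spec$n_channels, n)
  sig_band <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    acc <- numeric(n)
    for (b in names(SIM_BANDS)) {
      comp <- band_limited_noise(n, spec$fs, SIM_BANDS[[b]], sds[[b]])
      acc <- acc + comp
      if (b == spec$signature_band) sig_band[ch, ] <- comp
    }
    sig[ch, ] <- acc
  }

  artifact_truth <- matrix(numeric(), 0, 2)
  if (spec$artifact_rate > 0) {
    n_art <- stats::rpois(1, spec$artifact_rate * spec$duration / 3600)
    if (n_art > 0) {
      at <- sort(stats::runif(n_art, 0, spec$duration - 1))
      dur <- stats::runif(n_art, 0.5, 1)
      for (i in seq_len(n_art)) {
        i0 <- floor(at[i] * spec$fs) + 1L
        len <- round(dur[i] * spec$fs)
        idx <- i0:min(i0 + len - 1L, n)
        shape <- 400 * sin(pi * seq_along(idx) / length(idx))^2
        chs <- sample(spec$n_channels, max(1L, spec$n_channels %/% 3L))
        for (ch in chs) sig[ch, idx] <- sig[ch, idx] + shape
      }
      artifact_truth <- cbind(at, at + dur)
    }
  }

  valid <- rep(TRUE, n)
  for (g in spec$gap_spec) {
    i0 <- floor(g[1] * spec$fs) + 1L
    i1 <- min(ceiling(g[2] * spec$fs), n)
    valid[i0:i1] <- FALSE
  }

  ds <- structure(list(
    recording = recording(sig, fs = spec$fs, valid_mask = valid),
    annotations = seizure_annotation(spec$seizure_onsets,
                                     spec$seizure_offsets),
    spec = spec,
    signature_component = sig_band,
    artifact_truth = artifact_truth
  ), class = "synthetic_dataset")

  if (spec$signature_strength > 0) {
    ds <- inject_preictal_signature(ds, spec$signature_strength)
  }
  ds
}

#' Inject a preictal signature
#'
#' Over the `preictal_len` seconds before each seizure onset, the stored
#' signature-band component is scaled by a linear ramp so its amplitude is
#' multiplied by `1 + strength * r(t)` with `r` rising from 0 at the span
#' start to 1 at onset. The signal outside those spans is untouched.
#'
#' @param ds A `synthetic_dataset` from [generate_recording()].
#' @param strength Effect size `>= 0`; `0` returns the input unchanged.
#' @return The dataset with the signature applied.
#' @export
inject_preictal_signature <- function(ds, strength) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (strength < 0) stop("strength must be >= 0")
  if (strength == 0) return(ds)
  fs <- ds$spec$fs
  plen <- ds$spec$preictal_len
  for (onset in ds$annotations$onsets) {
    i1 <- round(onset * fs)
    i0 <- i1 - round(plen * fs) + 1L
    if (i0 < 1L) stop("onset at ", onset, " s lacks a full preictal span")
    idx <- i0:i1
    ramp <- seq(0, 1, length.out = length(idx))
    add <- strength * (ds$signature_component[, idx, drop = FALSE] *
                         rep(ramp, each = nrow(ds$signature_component)))
    ds$recording$signal[, idx] <- ds$recording$signal[, idx] + add
  }
  ds$signature_applied <- strength
  ds
}

#' Write a synthetic dataset to disk
#'
#' Produces `<id>.edf` (16-bit EDF) and `<id>_annotations.csv` with columns
#' `patient_id,onset_s,offset_s`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @param id Dataset/patient identifier used in file names.
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(ds, dir, id = "patient01") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf_path <- file.path(dir, paste0(id, ".edf"))
  csv_path <- file.path(dir, paste0(id, "_annotations.csv"))
  write_edf(ds$recording$signal, ds$recording$fs, edf_path,
            channel_names = ds$recording$channel_names, patient_id = id)
  ann <- data.frame(patient_id = rep(id, length(ds$annotations$onsets)),
                    onset_s = ds$annotations$onsets,
                    offset_s = ds$annotations$offsets)
  utils::write.csv(ann, csv_path, row.names = FALSE)
  c(edf = edf_path, annotations = csv_path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param edf_path,csv_path Paths to the EDF file and annotation CSV.
#' @return A list with `recording` and `annotations`.
#' @export
read_dataset <- function(edf_path, csv_path) {
  e <- read_edf(edf_path)
  ann <- utils::read.csv(csv_path)
  list(recording = recording(e$signal, fs = e$fs,
                             channel_names = e$channel_names),
       annotations = seizure_annotation(ann$onset_s, ann$offset_s))
}
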