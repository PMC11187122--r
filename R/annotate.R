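# Seizure-horizon annotation: leading-seizure selection, SOP/SPH window
# labelling, training selections and chronological splits.
#
# SOP (seizure occurrence period, 30 min) is the interval in which a
# predicted seizure is expected to occur; SPH (seizure prediction horizon,
# 10 min) is the minimum warning time. The preictal period is their sum
# (40 min before onset). Window membership in an interval is judged by the
# window START time; intervals are half-open [start, end).

#' Seizure annotation
#'
#' @param onsets Strictly increasing seizure onset times, seconds.
#' @param offsets Seizure offsets (`>= onsets`); default onsets + 60 s.
#' @return A `seizure_annotation`.
#' @export
seizure_annotation <- function(onsets, offsets = NULL) {
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    stop("onsets must be strictly increasing")
  }
  if (is.null(offsets)) offsets <- onsets + 60
  offsets <- as.numeric(offsets)
  if (length(offsets) != length(onsets) || any(offsets < onsets)) {
    stop("each offset must be >= its onset")
  }
  structure(list(onsets = onsets, offsets = offsets),
            class = "seizure_annotation")
}

#' Prediction-horizon configuration
#'
#' @param sop Seizure occurrence period, minutes.
#' @param sph Seizure prediction horizon, minutes.
#' @param train_window Pre-onset span used for training, hours.
#' @param post_ictal_exclusion Post-onset exclusion, minutes.
#' @param min_lead_gap Minimum onset-to-onset gap for a leading seizure,
#'   hours.
#' @return A `horizon_config`. Preictal duration is `sop + sph` minutes.
#' @export
horizon_config <- function(sop = 30, sph = 10, train_window = 4,
                           post_ictal_exclusion = 30, min_lead_gap = 4.5) {
  stopifnot(sop > 0, sph > 0, train_window > 0, post_ictal_exclusion > 0,
            min_lead_gap > 0)
  structure(list(sop = sop, sph = sph, train_window = train_window,
                 post_ictal_exclusion = post_ictal_exclusion,
                 min_lead_gap = min_lead_gap),
            class = "horizon_config")
}

preictal_s <- function(cfg) (cfg$sop + cfg$sph) * 60
sop_s <- function(cfg) cfg$sop * 60
sph_s <- function(cfg) cfg$sph * 60
exclusion_s <- function(cfg) cfg$post_ictal_exclusion * 60

#' Select leading seizures
#'
#' Greedy scan: the first seizure is kept, and every subsequent seizure
#' whose onset lies at least `min_lead_gap` hours after the previous KEPT
#' onset. Onset-to-onset gaps are used since onset is the only
#' clinician-marked time.
#'
#' @param ann A [seizure_annotation()].
#' @param cfg A [horizon_config()].
#' @return The filtered annotation; attribute `conformant` is `FALSE` (with
#'   a warning) when fewer than 3 leading seizures remain.
#' @export
select_leading_seizures <- function(ann, cfg = horizon_config()) {
  stopifnot(inherits(ann, "seizure_annotation"))
  if (!length(ann$onsets)) stop("annotation holds no seizures")
  gap <- cfg$min_lead_gap * 3600
  keep <- 1L
  last <- ann$onsets[1]
  for (i in seq_along(ann$onsets)[-1]) {
    if (ann$onsets[i] - last >= gap) {
      keep <- c(keep, i)
      last <- ann$onsets[i]
    }
  }
  out <- seizure_annotation(ann$onsets[keep], ann$offsets[keep])
  conformant <- length(keep) >= 3L
  if (!conformant) {
    warning("only ", length(keep), " leading seizure(s); ",
            "patient is non-conformant (need >= 3)")
  }
  attr(out, "conformant") <- conformant
  out
}

#' Label windows as interictal / preictal / excluded
#'
#' A window is preictal iff its start lies in `[onset - (sop+sph), onset)`
#' for some seizure; excluded iff it overlaps `[onset, onset +
#' post_ictal_exclusion)`; otherwise interictal. Exclusion takes precedence.
#'
#' @param ws A `window_set`.
#' @param ann A [seizure_annotation()] on the same time base.
#' @param cfg A [horizon_config()].
#' @return A `labeled_windows`: the window set plus a `label` factor.
#' @export
label_windows <- function(ws, ann, cfg = horizon_config()) {
  stopifnot(inherits(ws, "window_set"), inherits(ann, "seizure_annotation"))
  st <- ws$start_times
  en <- st + ws$window_s
  label <- rep("interictal", length(st))
  for (onset in ann$onsets) {
    label[st >= onset - preictal_s(cfg) & st < onset] <- "preictal"
  }
  for (onset in ann$onsets) {
    label[st < onset + exclusion_s(cfg) & en > onset] <- "excluded"
  }
  ws$label <- factor(label, levels = c("interictal", "preictal", "excluded"))
  class(ws) <- c("labeled_windows", class(ws))
  ws
}

#' Build the training selection
#'
#' For each training seizure, interictal windows are drawn from
#' `[onset - train_window, onset - (sop+sph))` (nominally 3 h 20 min) and
#' preictal windows from the SOP span `[onset - (sop+sph), onset - sph)`
#' (nominally 30 min); SPH windows are dropped. Only valid windows carrying
#' the matching label are used; selections of different seizures are
#' unioned.
#'
#' @param lw A `labeled_windows`.
#' @param train_onsets Onsets (seconds) of the training seizures.
#' @param cfg A [horizon_config()].
#' @return List with integer window indices `interictal` and `preictal`.
#' @export
build_training_selection <- function(lw, train_onsets, cfg = horizon_config()) {
  stopifnot(inherits(lw, "labeled_windows"))
  st <- lw$start_times
  inter <- integer()
  pre <- integer()
  for (onset in train_onsets) {
    lo <- onset - cfg$train_window * 3600
    ii <- which(st >= lo & st < onset - preictal_s(cfg) &
                  lw$valid & lw$label == "interictal")
    pp <- which(st >= onset - preictal_s(cfg) & st < onset - sph_s(cfg) &
                  lw$valid & lw$label == "preictal")
    if (!length(pp)) {
      warning("training seizure at ", onset, " s has no preictal windows")
    }
    inter <- union(inter, ii)
    pre <- union(pre, pp)
  }
  list(interictal = sort(inter), preictal = sort(pre))
}

#' Chronological train/test split over seizures
#'
#' The first `ceiling(train_frac * n)` leading seizures go to training, the
#' rest to test. Each test seizure's segment runs from
#' `post_ictal_exclusion` after the previous onset up to its own onset.
#' Training windows get a label-stratified random 80/20 train/validation
#' holdout.
#'
#' @param lw A `labeled_windows`.
#' @param ann Leading-seizure [seizure_annotation()].
#' @param cfg A [horizon_config()].
#' @param train_frac Fraction of seizures used for training.
#' @param val_frac Fraction of training windows held out for validation.
#' @param seed RNG seed for the holdout.
#' @return A `split_plan`: `train_seizures`, `test_seizures` (indices),
#'   `train_idx`, `val_idx` (window indices), `test_segments` (matrix of
#'   start/end seconds per test seizure).
#' @export
chronological_split <- function(lw, ann, cfg = horizon_config(),
                                train_frac = 0.6, val_frac = 0.2, seed = 1L) {
  n <- length(ann$onsets)
  if (n < 3L) stop("need at least 3 leading seizures, have ", n)
  n_train <- ceiling(train_frac * n)
  train_seizures <- seq_len(n_train)
  test_seizures <- seq(n_train + 1L, n)

  sel <- build_training_selection(lw, ann$onsets[train_seizures], cfg)
  set.seed(seed)
  hold <- function(idx) {
    if (!length(idx)) return(list(train = integer(), val = integer()))
    nv <- max(1L, round(val_frac * length(idx)))
    val <- sort(idx[sample.int(length(idx), nv)])
    list(train = setdiff(idx, val), val = val)
  }
  hi <- hold(sel$interictal)
  hp <- hold(sel$preictal)

  segs <- cbind(start = ann$onsets[test_seizures - 1L] + exclusion_s(cfg),
                end = ann$onsets[test_seizures])
  structure(list(
    train_seizures = train_seizures, test_seizures = test_seizures,
    train_idx = list(interictal = hi$train, preictal = hp$train),
    val_idx = list(interictal = hi$val, preictal = hp$val),
    test_segments = segs, seed = seed
  ), class = "split_plan")
}
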