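# Firing-power alarm generation.
#
# Classifier outputs o[k] in [0,1] arrive on a nominal 10-second grid. The
# firing power at grid step n is the mean of o over the trailing SOP-length
# moving window (tau = SOP / 10 s = 180 steps under defaults). Steps missing
# from the grid (preprocessing gaps, invalid windows) contribute o = 0 while
# still occupying their calendar slot, so a sustained gap drives the firing
# power to zero.

#' Prediction series
#'
#' @param times Window start times in seconds (multiples of `step_s` on a
#'   common grid), strictly increasing.
#' @param o Classifier preictal probability per window, in `[0, 1]`.
#' @param valid Logical per window; invalid windows carry no usable output.
#' @param step_s Grid step, seconds (window length).
#' @return A `prediction_series`.
#' @export
prediction_series <- function(times, o, valid = rep(TRUE, length(o)),
                              step_s = 10) {
  stopifnot(length(times) == length(o), length(valid) == length(o))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(o[valid] < 0 | o[valid] > 1)) stop("o must lie in [0, 1]")
  structure(list(times = as.numeric(times), o = as.numeric(o),
                 valid = valid, step_s = step_s),
            class = "prediction_series")
}

#' Gap-aware firing power
#'
#' Materialises the nominal `step_s` grid spanning the series, zero-fills
#' missing or invalid steps, and computes the trailing moving average over
#' `tau = sop * 60 / step_s` slots. Steps closer than `tau` slots to the
#' grid start are flagged `warmup` (computed over the available slots, with
#' missing leading slots counted as zero, but alarms are suppressed there).
#'
#' @param ps A [prediction_series()].
#' @param cfg A [horizon_config()]; only `sop` is used.
#' @return A `firing_power_series`: `times`, `fp` in `[0, 1]`, `tau`,
#'   `warmup`.
#' @export
firing_power <- function(ps, cfg = horizon_config()) {
  stopifnot(inherits(ps, "prediction_series"))
  tau <- round(sop_s(cfg) / ps$step_s)
  if (!length(ps$times)) {
    return(structure(list(times = numeric(), fp = numeric(), tau = tau,
                          warmup = logical(), step_s = ps$step_s),
                     class = "firing_power_series"))
  }
  t0 <- ps$times[1]
  n <- round((ps$times[length(ps$times)] - t0) / ps$step_s) + 1L
  o <- numeric(n)
  slot <- round((ps$times - t0) / ps$step_s) + 1L
  use <- ps$valid
  o[slot[use]] <- ps$o[use]
  cs <- c(0, cumsum(o))
  lo <- pmax(seq_len(n) - tau, 0L)
  fp <- (cs[seq_len(n) + 1L] - cs[lo + 1L]) / tau
  structure(list(times = t0 + (seq_len(n) - 1L) * ps$step_s, fp = fp,
                 tau = tau, warmup = seq_len(n) < tau, step_s = ps$step_s),
            class = "firing_power_series")
}

#' Trigger alarms from a firing-power series
#'
#' An alarm fires on an upward crossing: the firing power reaches
#' `threshold` from below at a step outside warm-up and outside the
#' refractory period (`sop + sph`, 40 min, after each alarm). Crossings
#' occurring during warm-up or refractory are consumed — after the
#' refractory period a fresh crossing is required, so a sustained plateau
#' cannot re-alarm indefinitely.
#'
#' @param fps A `firing_power_series` from [firing_power()].
#' @param threshold Alarm threshold in `(0, 1)`.
#' @param cfg A [horizon_config()].
#' @return Numeric vector of alarm times (seconds), spaced at least
#'   `sop + sph` minutes apart.
#' @export
trigger_alarms <- function(fps, threshold = 0.5, cfg = horizon_config()) {
  stopifnot(inherits(fps, "firing_power_series"),
            threshold > 0, threshold < 1)
  refractory <- preictal_s(cfg)
  alarms <- numeric()
  armed <- TRUE
  ref_until <- -Inf
  for (i in seq_along(fps$fp)) {
    if (fps$fp[i] >= threshold) {
      if (armed) {
        armed <- FALSE
        if (!fps$warmup[i] && fps$times[i] >= ref_until) {
          alarms <- c(alarms, fps$times[i])
          ref_until <- fps$times[i] + refractory
        }
      }
    } else {
      armed <- TRUE
    }
  }
  alarms
}
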