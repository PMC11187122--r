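# Evaluation: alarm adjudication, seizure sensitivity (SS), false
# prediction rate per hour (FPR/h) with refractory correction, surrogate
# chance-level analysis, and paired comparison of training approaches.

#' Adjudicate alarms against seizure onsets
#'
#' An alarm at time `t` is TRUE iff some onset falls in
#' `[t + sph, t + sph + sop]`: the SPH is the minimum warning time and the
#' SOP the window in which the predicted seizure must occur. A seizure is
#' predicted iff at least one true alarm maps to it.
#'
#' @param alarm_times Alarm times, seconds.
#' @param onsets Test-seizure onset times, seconds.
#' @param cfg A [horizon_config()].
#' @return List: `alarms` data frame (`time`, `kind` in true/false) and
#'   logical `predicted` per seizure.
#' @export
adjudicate_alarms <- function(alarm_times, onsets, cfg = horizon_config()) {
  lo <- sph_s(cfg)
  hi <- sph_s(cfg) + sop_s(cfg)
  kind <- vapply(alarm_times, function(t) {
    any(onsets >= t + lo & onsets <= t + hi)
  }, logical(1))
  predicted <- vapply(onsets, function(on) {
    any(on >= alarm_times + lo & on <= alarm_times + hi)
  }, logical(1))
  list(alarms = data.frame(time = as.numeric(alarm_times),
                           kind = ifelse(kind, "true", "false")),
       predicted = predicted)
}

#' Seizure sensitivity
#'
#' Fraction of test seizures preceded by at least one correctly timed alarm.
#'
#' @param predicted Logical vector, one entry per test seizure.
#' @return SS in `[0, 1]`.
#' @export
seizure_sensitivity <- function(predicted) {
  if (!length(predicted)) stop("seizure sensitivity undefined without test seizures")
  mean(predicted)
}

#' False prediction rate per hour
#'
#' `FPR/h = n_false / (interictal_hours - n_false * refractory_hours)`:
#' false alarms per hour of interictal time, after removing the refractory
#' time the false alarms themselves consume.
#'
#' @param n_false Number of false alarms.
#' @param interictal_hours Interictal duration in hours, measured on valid
#'   recorded time (gaps excluded) with preictal spans removed.
#' @param cfg A [horizon_config()]; the refractory period is `sop + sph`.
#' @return FPR/h (`>= 0`).
#' @export
fpr_per_hour <- function(n_false, interictal_hours, cfg = horizon_config()) {
  refractory_h <- (cfg$sop + cfg$sph) / 60
  denom <- interictal_hours - n_false * refractory_h
  if (denom <= 0) {
    stop("interictal time (", signif(interictal_hours, 4),
         " h) does not exceed the refractory time consumed by ", n_false,
         " false alarm(s); FPR/h undefined")
  }
  n_false / denom
}

#' Interictal hours of the test segments
#'
#' Valid window time inside the test segments minus the preictal spans of
#' the test seizures.
#'
#' @param lw A `labeled_windows` covering the recording.
#' @param segments Matrix with `start`/`end` columns (one row per test
#'   seizure).
#' @param cfg A [horizon_config()].
#' @return Hours of valid interictal test time.
#' @export
interictal_hours <- function(lw, segments, cfg = horizon_config()) {
  st <- lw$start_times
  total <- 0
  for (r in seq_len(nrow(segments))) {
    inseg <- st >= segments[r, 1] & st < segments[r, 2]
    onset <- segments[r, 2]
    pre <- st >= onset - preictal_s(cfg) & st < onset
    total <- total + sum(lw$valid & inseg & !pre) * lw$window_s
  }
  total / 3600
}

#' Surrogate configuration
#'
#' @param n_surrogates Number of surrogate repetitions (`>= 2`).
#' @param alpha One-tailed significance level.
#' @param seed RNG seed for the onset redraws.
#' @return A `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 30L, alpha = 0.05, seed = 1L) {
  stopifnot(n_surrogates >= 2, alpha > 0, alpha < 1)
  structure(list(n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Surrogate chance-level analysis
#'
#' Holds the alarms fixed and redraws each test-seizure onset uniformly
#' within its test segment (at least `sop + sph` after the segment start),
#' recomputing SS against the same alarms for each of `n_surrogates`
#' repetitions. The observed (mean) SS is compared with the surrogate SS
#' distribution by the one-tailed Monte-Carlo rank p-value
#' `p = (1 + #\{surr >= obs\}) / (n_surrogates + 1)`, which is exactly valid
#' under exchangeability of the observed and surrogate seizure times (ties
#' count against the observation, so discreteness of SS can only make the
#' test conservative). The procedure is a pure function of alarms and
#' segments — it never touches the model.
#'
#' @param alarms Alarm times (seconds), or a list of alarm-time vectors
#'   (one per training repeat; SS values are averaged per surrogate draw).
#' @param segments Test-segment matrix (`start`, `end`; the seizure onset is
#'   the segment end).
#' @param scfg A [surrogate_config()].
#' @param cfg A [horizon_config()].
#' @return List: `observed_ss`, `surrogate_ss` (vector), `p_value`,
#'   `above_chance`.
#' @export
surrogate_analysis <- function(alarms, segments, scfg = surrogate_config(),
                               cfg = horizon_config()) {
  if (!is.list(alarms)) alarms <- list(alarms)
  n_seiz <- nrow(segments)
  if (!n_seiz) stop("surrogate analysis needs at least one test seizure")
  min_off <- preictal_s(cfg)
  usable <- segments[, 2] - segments[, 1] >= min_off
  if (!all(usable)) {
    warning(sum(!usable), " test segment(s) too short to place a surrogate",
            " onset; dropped")
    segments <- segments[usable, , drop = FALSE]
    if (!nrow(segments)) stop("no usable test segments remain")
  }
  ss_for <- function(onsets) {
    mean(vapply(alarms, function(a) {
      seizure_sensitivity(adjudicate_alarms(a, onsets, cfg)$predicted)
    }, numeric(1)))
  }
  observed <- ss_for(segments[, 2])
  set.seed(scfg$seed)
  surr <- vapply(seq_len(scfg$n_surrogates), function(s) {
    onsets <- stats::runif(nrow(segments),
                           segments[, 1] + min_off, segments[, 2])
    ss_for(onsets)
  }, numeric(1))
  p <- (1 + sum(surr >= observed - 1e-12)) / (length(surr) + 1)
  list(observed_ss = observed, surrogate_ss = surr, p_value = p,
       above_chance = p < scfg$alpha)
}

#' Paired one-tailed Wilcoxon comparison of approaches
#'
#' Wilcoxon signed-rank test on per-patient means, one-tailed in the stated
#' direction (e.g. transfer FPR/h lower than standard, or SS greater).
#'
#' @param standard,transfer Paired per-patient metric vectors.
#' @param alternative `"less"` tests transfer < standard; `"greater"` tests
#'   transfer > standard.
#' @return List with `p_value` and `statistic`.
#' @export
compare_approaches <- function(standard, transfer,
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(standard) == length(transfer))
  if (length(standard) < 5) warning("fewer than 5 pairs; test is weak")
  d <- transfer - standard
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(transfer, standard, paired = TRUE,
                       alternative = alternative)
  )
  list(p_value = wt$p.value, statistic = unname(wt$statistic))
}
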