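# End-to-end experiment orchestration: simulate -> preprocess -> annotate ->
# pretrain -> fit (standard / transfer) -> alarms -> evaluate -> compare.

#' Experiment configuration
#'
#' Bundles every stage's configuration so a saved configuration reruns the
#' experiment identically for its deterministic stages.
#'
#' @param source_spec [sim_spec()] for the source corpus the autoencoder is
#'   pretrained on.
#' @param patient_specs List of [sim_spec()], one per synthetic patient.
#' @param horizon A [horizon_config()].
#' @param dcae A [dcae_config()].
#' @param bilstm_units BiLSTM hidden units per direction.
#' @param proto_dcae,proto_pred [train_protocol()] objects for pretraining
#'   and predictor fits.
#' @param scfg A [surrogate_config()].
#' @param modes Training modes to run.
#' @param threshold Firing-power alarm threshold.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param seed Base seed for split holdouts.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(source_spec, patient_specs,
                              horizon = horizon_config(),
                              dcae = dcae_config(), bilstm_units = 64L,
                              proto_dcae = train_protocol("dcae"),
                              proto_pred = train_protocol("standard"),
                              scfg = surrogate_config(),
                              modes = c("standard", "transfer"),
                              threshold = 0.5, out_dir = NULL, seed = 1L) {
  structure(list(source_spec = source_spec, patient_specs = patient_specs,
                 horizon = horizon, dcae = dcae,
                 bilstm_units = as.integer(bilstm_units),
                 proto_dcae = proto_dcae, proto_pred = proto_pred,
                 scfg = scfg, modes = modes, threshold = threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Desk-scale experiment profile
#'
#' A reduced problem size for a single workstation CPU: 4 channels, a small
#' encoder (4-4-8-8-16-16 filters), a compressed inter-seizure timeline
#' (leading gap 1.2 h instead of 4.5 h), few epochs, and a learning rate of
#' 3e-3 instead of the full protocol's 3e-4 (the published rate is
#' calibrated for thousands of optimiser steps per epoch; at desk scale an
#' epoch is ~30 steps, so the rate scales up to keep optimisation feasible
#' within the reduced epoch budget). Every structural property of the full
#' protocol (10-s windows at 256 Hz, SOP 30 / SPH 10 min, 4-h training
#' span, chronological 60/40 split, balanced batches, firing power with
#' 40-min refractory) is retained.
#'
#' @param n_patients Number of synthetic patients.
#' @param signature_strength Preictal effect size given to every patient.
#' @param n_repeats Predictor fits per patient and mode.
#' @param seed Base seed; patient `i` simulates with `seed + i`.
#' @param out_dir Optional output directory.
#' @return An `experiment_config`.
#' @export
desk_profile <- function(n_patients = 1L, signature_strength = 2,
                         n_repeats = 3L, seed = 1L, out_dir = NULL) {
  onsets <- c(6000, 11000, 16000, 30000)
  patient_specs <- lapply(seq_len(n_patients), function(i) {
    sim_spec(duration = 30060, seizure_onsets = onsets, n_channels = 4L,
             signature_strength = signature_strength, artifact_rate = 2,
             seed = seed + i)
  })
  experiment_config(
    source_spec = sim_spec(duration = 1800, n_channels = 4L,
                           artifact_rate = 2, seed = seed + 1000L),
    patient_specs = patient_specs,
    horizon = horizon_config(min_lead_gap = 1.2),
    dcae = dcae_config(enc_filters = c(4L, 4L, 8L, 8L, 16L, 16L),
                       dec_filters = c(8L, 8L, NA_integer_)),
    bilstm_units = 8L,
    proto_dcae = train_protocol("dcae", batch_size = 32L, max_epochs = 12L,
                                patience = 11L, lr = 3e-3, seed = seed),
    proto_pred = train_protocol("standard", max_epochs = 15L, patience = 14L,
                                lr = 3e-3, n_repeats = n_repeats, seed = seed),
    scfg = surrogate_config(seed = seed),
    threshold = 0.5, out_dir = out_dir, seed = seed
  )
}

preprocess_dataset <- function(ds, amp_thresh = 300) {
  rec <- ds$recording
  if (rec$fs != 256) rec <- resample_recording(rec, 256)
  rec <- filter_eeg(rec)
  rec <- reject_artifacts(rec, amp_thresh = amp_thresh)
  segment(rec)
}

# predictions + alarms + metrics for one fitted repeat
evaluate_repeat <- function(model, lw, split, cfg, threshold) {
  segs <- split$test_segments
  alarms <- numeric()
  for (r in seq_len(nrow(segs))) {
    idx <- which(lw$start_times >= segs[r, 1] & lw$start_times < segs[r, 2] &
                   lw$valid)
    if (!length(idx)) next
    probs <- predict_windows(model, lw$data[, , idx, drop = FALSE])
    ps <- prediction_series(lw$start_times[idx], probs[, "preictal"],
                            step_s = lw$window_s)
    alarms <- c(alarms, trigger_alarms(firing_power(ps, cfg), threshold, cfg))
  }
  adj <- adjudicate_alarms(alarms, segs[, 2], cfg)
  n_false <- sum(adj$alarms$kind == "false")
  ih <- interictal_hours(lw, segs, cfg)
  fpr <- tryCatch(fpr_per_hour(n_false, ih, cfg), error = function(e) {
    warning("FPR/h undefined for one repeat: ", conditionMessage(e))
    NA_real_
  })
  list(alarms = alarms, adjudicated = adj,
       ss = seizure_sensitivity(adj$predicted),
       n_false = n_false, interictal_hours = ih, fpr_h = fpr)
}

fit_patient_mode <- function(lw, split, mode, cfg, ecfg, source_stats,
                             bundle) {
  stats <- if (mode == "transfer") {
    source_stats
  } else {
    sub <- lw
    keep <- sort(c(split$train_idx$interictal, split$train_idx$preictal))
    sub$data <- lw$data[, , keep, drop = FALSE]
    sub$valid <- lw$valid[keep]
    sub$start_times <- lw$start_times[keep]
    compute_norm_stats(sub)
  }
  lws <- standardize(lw, stats)
  take <- function(idx_list) {
    idx <- c(idx_list$interictal, idx_list$preictal)
    y <- rep(1:2, c(length(idx_list$interictal), length(idx_list$preictal)))
    list(x = lws$data[, , idx, drop = FALSE], y = y)
  }
  tr <- take(split$train_idx)
  va <- take(split$val_idx)
  pcfg <- predictor_config(ecfg$dcae, bilstm_units = ecfg$bilstm_units,
                           encoder_frozen = (mode == "transfer"))
  proto <- ecfg$proto_pred
  proto$mode <- mode
  fits <- train_predictor(tr$x, tr$y, va$x, va$y, mode = mode, proto = proto,
                          pcfg = pcfg,
                          bundle = if (mode == "transfer") bundle)
  reps <- lapply(fits, function(f) {
    evaluate_repeat(f$model, lws, split, cfg, ecfg$threshold)
  })
  sur <- surrogate_analysis(lapply(reps, `[[`, "alarms"),
                            split$test_segments, ecfg$scfg, cfg)
  list(fits = fits, repeats = reps,
       mean_ss = mean(vapply(reps, `[[`, 0, "ss")),
       mean_fpr_h = mean(vapply(reps, `[[`, 0, "fpr_h")),
       surrogate = sur)
}

#' Run a full experiment
#'
#' Pretrains the autoencoder on the simulated source corpus, then per
#' patient: simulates, preprocesses, labels, splits chronologically, fits
#' each training mode `n_repeats` times, converts test-segment predictions
#' into firing-power alarms, and evaluates SS, FPR/h and surrogate
#' chance-level validation. When both modes run on at least two patients,
#' approaches are compared with one-tailed Wilcoxon signed-rank tests
#' (transfer SS greater; transfer FPR/h lower).
#'
#' @param ecfg An [experiment_config()].
#' @return An `experiment_report`: `patients` (per patient x mode metrics),
#'   `comparison` data frame, `wilcoxon`, `dcae_fit`, `bundle`,
#'   `config_hash`. If `ecfg$out_dir` is set, writes `report.json`,
#'   `comparison.csv`, per-fit loss curves (CSV) and the encoder
#'   `weight_bundle`.
#' @export
run_experiment <- function(ecfg) {
  stopifnot(inherits(ecfg, "experiment_config"))
  chash <- config_hash(ecfg[setdiff(names(ecfg), "out_dir")])
  stage <- "pretrain"
  res <- tryCatch({
    src <- generate_recording(ecfg$source_spec)
    ws_src <- preprocess_dataset(src)
    source_stats <- compute_norm_stats(ws_src)
    ws_src <- standardize(ws_src, source_stats)
    dcae_fit <- train_dcae(ws_src, ecfg$proto_dcae, ecfg$dcae)
    bundle <- weight_bundle(dcae_fit$model,
                            provenance = list(dataset = "synthetic-source",
                                              run = chash))
    patients <- list()
    for (p in seq_along(ecfg$patient_specs)) {
      stage <- paste0("patient", p)
      ds <- generate_recording(ecfg$patient_specs[[p]])
      ws <- preprocess_dataset(ds)
      lead <- select_leading_seizures(ds$annotations, ecfg$horizon)
      lw <- label_windows(ws, lead, ecfg$horizon)
      split <- chronological_split(lw, lead, ecfg$horizon,
                                   seed = ecfg$seed + p)
      modes <- list()
      for (m in ecfg$modes) {
        stage <- paste0("patient", p, ":", m)
        modes[[m]] <- fit_patient_mode(lw, split, m, ecfg$horizon, ecfg,
                                       source_stats, bundle)
      }
      patients[[p]] <- list(split = split, modes = modes)
    }
    list(dcae_fit = dcae_fit, bundle = bundle, patients = patients,
         source_stats = source_stats)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  comparison <- do.call(rbind, lapply(ecfg$modes, function(m) {
    ss <- vapply(res$patients, function(p) p$modes[[m]]$mean_ss, 0)
    fpr <- vapply(res$patients, function(p) p$modes[[m]]$mean_fpr_h, 0)
    ac <- vapply(res$patients, function(p) p$modes[[m]]$surrogate$above_chance,
                 logical(1))
    data.frame(approach = m, mean_ss = mean(ss), sd_ss = stats::sd(ss),
               mean_fpr_h = mean(fpr, na.rm = TRUE),
               sd_fpr_h = stats::sd(fpr, na.rm = TRUE),
               above_chance = sum(ac), n_patients = length(ss))
  }))

  wilcox <- NULL
  if (all(c("standard", "transfer") %in% ecfg$modes) &&
      length(res$patients) >= 2) {
    g <- function(m, f) vapply(res$patients, function(p) p$modes[[m]][[f]], 0)
    wilcox <- list(
      ss = compare_approaches(g("standard", "mean_ss"),
                              g("transfer", "mean_ss"), "greater"),
      fpr_h = compare_approaches(g("standard", "mean_fpr_h"),
                                 g("transfer", "mean_fpr_h"), "less")
    )
  }

  report <- structure(list(patients = res$patients, comparison = comparison,
                           wilcoxon = wilcox, dcae_fit = res$dcae_fit,
                           bundle = res$bundle, config_hash = chash),
                      class = "experiment_report")
  if (!is.null(ecfg$out_dir)) write_report(report, ecfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  comp <- report$comparison
  comp$config_hash <- report$config_hash
  utils::write.csv(comp, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  per_patient <- lapply(seq_along(report$patients), function(p) {
    pm <- report$patients[[p]]$modes
    lapply(pm, function(m) list(
      mean_ss = m$mean_ss, mean_fpr_h = m$mean_fpr_h,
      repeat_ss = vapply(m$repeats, `[[`, 0, "ss"),
      repeat_fpr_h = vapply(m$repeats, `[[`, 0, "fpr_h"),
      repeat_seeds = vapply(m$fits, `[[`, 0L, "seed"),
      surrogate_p = m$surrogate$p_value,
      above_chance = m$surrogate$above_chance
    ))
  })
  jsonlite::write_json(
    list(config_hash = report$config_hash, patients = per_patient,
         wilcoxon = report$wilcoxon),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  save_weight_bundle(report$bundle, file.path(out_dir, "dcae_encoder.bundle"))
  curves <- data.frame(epoch = seq_along(report$dcae_fit$train_loss),
                       train_loss = report$dcae_fit$train_loss,
                       val_loss = report$dcae_fit$val_loss,
                       config_hash = report$config_hash)
  utils::write.csv(curves, file.path(out_dir, "dcae_loss_curves.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> config", x$config_hash, "\n")
  print(x$comparison, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat(sprintf("Wilcoxon (one-tailed): SS p = %.3f; FPR/h p = %.3f\n",
                x$wilcoxon$ss$p_value, x$wilcoxon$fpr_h$p_value))
  }
  invisible(x)
}
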