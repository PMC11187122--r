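test_that("generated recordings have the requested geometry and are seed-deterministic", {
  sp <- sim_spec(duration = 3600, n_channels = 19L, seed = 1)
  ds <- generate_recording(sp)
  expect_identical(dim(ds$recording$signal), c(19L, 921600L))
  expect_equal(ds$annotations$onsets, numeric(0))

  a <- generate_recording(sim_spec(duration = 600, n_channels = 2L, seed = 9))
  b <- generate_recording(sim_spec(duration = 600, n_channels = 2L, seed = 9))
  expect_identical(a$recording$signal, b$recording$signal)
  c <- generate_recording(sim_spec(duration = 600, n_channels = 2L, seed = 10))
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("invalid simulation specs are rejected", {
  expect_error(sim_spec(3600, seizure_onsets = c(3000, 2500)), "increasing")
  expect_error(sim_spec(3600, seizure_onsets = 1000), "preictal_len")
  expect_error(sim_spec(3600, seizure_onsets = 2500, signature_strength = -1),
               ">= 0")
  expect_error(sim_spec(3600, gap_spec = list(c(100, 50))), "ordered")
  expect_error(sim_spec(3600, gap_spec = list(c(100, 300), c(200, 400))),
               "overlap")
  expect_error(sim_spec(3600, gap_spec = list(c(3500, 3700))), "within")
})

test_that("gaps are reflected in the validity mask", {
  sp <- sim_spec(duration = 300, n_channels = 1L,
                 gap_spec = list(c(50, 60), c(200, 210)), seed = 2)
  ds <- generate_recording(sp)
  vm <- ds$recording$valid_mask
  expect_false(any(vm[(50 * 256 + 1):(60 * 256)]))
  expect_true(all(vm[1:(50 * 256)]))
  expect_true(all(vm[(211 * 256):(300 * 256)]))
})

test_that("zero signature strength leaves the recording untouched and undetectable", {
  sp <- sim_spec(duration = 900, seizure_onsets = 600, n_channels = 1L,
                 preictal_len = 300, signature_strength = 0, seed = 3)
  ds <- generate_recording(sp)
  expect_identical(inject_preictal_signature(ds, 0), ds)
  expect_error(inject_preictal_signature(ds, -0.5), ">= 0")

  # preictal vs interictal alpha power indistinguishable: t-test p-values
  # uniform over repeated seeds
  pv <- vapply(1:60, function(s) {
    d <- generate_recording(sim_spec(duration = 900, seizure_onsets = 600,
                                     n_channels = 1L, preictal_len = 300,
                                     signature_strength = 0, seed = s))
    ws <- segment(d$recording)
    ap <- apply(ws$data[1, , ], 2, band_power_oracle, fs = 256, band = c(8, 13))
    pre <- ws$start_times >= 300 & ws$start_times < 600
    inter <- ws$start_times < 300
    stats::t.test(ap[pre], ap[inter])$p.value
  }, 0)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("the preictal signature ramps the alpha band up toward onset", {
  sp <- sim_spec(duration = 3600, seizure_onsets = 3000, n_channels = 2L,
                 signature_strength = 2, seed = 7)
  ds <- generate_recording(sp)
  base <- generate_recording(sim_spec(duration = 3600, seizure_onsets = 3000,
                                      n_channels = 2L, signature_strength = 0,
                                      seed = 7))
  # signature confined to the 40-min pre-onset span
  pre_idx <- (600 * 256 + 1):(3000 * 256)
  expect_identical(ds$recording$signal[, -pre_idx],
                   base$recording$signal[, -pre_idx])
  expect_false(identical(ds$recording$signal[, pre_idx],
                         base$recording$signal[, pre_idx]))

  ws <- segment(ds$recording)
  lw <- label_windows(ws, ds$annotations)
  ap <- apply(ws$data[1, , ], 2, band_power_oracle, fs = 256, band = c(8, 13))
  inter <- ap[lw$label == "interictal"]
  last5 <- ap[ws$start_times >= 2700 & ws$start_times < 3000]
  first5 <- ap[ws$start_times >= 600 & ws$start_times < 900]
  expect_gt(mean(last5) / mean(inter), 1)
  expect_gt(mean(last5), mean(first5))
})

test_that("both of two distant onsets receive non-overlapping ramps", {
  on <- c(3000, 20000)
  sp <- sim_spec(duration = 21000, seizure_onsets = on, n_channels = 1L,
                 signature_strength = 2, seed = 11)
  ds <- generate_recording(sp)
  base <- generate_recording(sim_spec(duration = 21000, seizure_onsets = on,
                                      n_channels = 1L, signature_strength = 0,
                                      seed = 11))
  delta <- abs(ds$recording$signal - base$recording$signal)
  changed <- which(delta[1, ] > 1e-9) / 256
  expect_true(all((changed > on[1] - 2400 & changed <= on[1]) |
                    (changed > on[2] - 2400 & changed <= on[2])))
  expect_true(any(changed <= on[1]) && any(changed > on[2] - 2400))
})

test_that("a strength-2 signature is recoverable by a band-power classifier (AUC > 0.8)", {
  sp <- sim_spec(duration = 3600, seizure_onsets = 3000, n_channels = 2L,
                 signature_strength = 2, seed = 7)
  ds <- generate_recording(sp)
  ws <- segment(ds$recording)
  lw <- label_windows(ws, ds$annotations)
  ap <- apply(ws$data[1, , ], 2, band_power_oracle, fs = 256, band = c(8, 13))
  auc <- rank_auc(ap[lw$label == "preictal"], ap[lw$label == "interictal"])
  expect_gt(auc, 0.8)
})

test_that("datasets round-trip through EDF + annotation CSV", {
  sp <- sim_spec(duration = 60, seizure_onsets = c(25, 50),
                 preictal_len = 20, n_channels = 3L, seed = 4)
  ds <- generate_recording(sp)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, id = "p01")
  back <- read_dataset(paths[["edf"]], paths[["annotations"]])

  qstep <- apply(ds$recording$signal, 1, function(x) {
    r <- range(x)
    (r[2] - r[1]) / 65535
  })
  dev <- abs(back$recording$signal - ds$recording$signal)
  expect_true(all(dev <= qstep + 1e-12))
  expect_equal(back$recording$fs, 256)

  ann <- utils::read.csv(paths[["annotations"]])
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$onset_s, c(25, 50))

  # degenerate: no seizures still yields a valid EDF and empty table
  empty <- generate_recording(sim_spec(duration = 30, n_channels = 1L, seed = 5))
  p2 <- write_dataset(empty, dir, id = "p02")
  expect_equal(nrow(utils::read.csv(p2[["annotations"]])), 0L)
  expect_equal(ncol(read_edf(p2[["edf"]])$signal), 30 * 256)

  blocker <- file.path(dir, "blocker")
  file.create(blocker)
  expect_error(suppressWarnings(write_dataset(ds, file.path(blocker, "sub"))))
})
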