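test_that("scheduling respects seizure count, spacing and feasibility", {
  cfg <- sim_config(n_seizures = 4, record_days = 5, seed = 7)
  sch <- simulate_schedule(cfg)
  expect_length(sch$onsets_s, 4)
  expect_true(all(diff(sch$onsets_s) >= 270 * 60))
  expect_true(sch$onsets_s[1] >= cfg$true_preictal_min * 60)
  expect_true(max(sch$ictal_end_s) <= sch$record_s)

  # blocks partition the pre-onset timeline per seizure
  expect_equal(sch$blocks$end, sch$onsets_s)
  expect_equal(sch$blocks$start[-1], sch$ictal_end_s[-4])

  cfg_bad <- sim_config(n_seizures = 6, record_days = 0.5, seed = 1)
  expect_error(simulate_schedule(cfg_bad), class = "sz_schedule_error")

  expect_error(sim_config(n_seizures = 2), "at least 4")
})

test_that("identical config and seed reproduce the record bit-for-bit", {
  cfg <- sim_config(n_seizures = 1, record_days = 0.02, n_channels = 2,
                    min_separation_min = 5, true_preictal_min = 5,
                    effect_size = 2, artifact_rate = 10, seed = 99,
                    allow_few = TRUE)
  a <- simulate_patient(cfg)
  b <- simulate_patient(cfg)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$annotations$onset, b$annotations$onset)
  other <- simulate_patient(sim_config(
    n_seizures = 1, record_days = 0.02, n_channels = 2,
    min_separation_min = 5, true_preictal_min = 5, effect_size = 2,
    artifact_rate = 10, seed = 100, allow_few = TRUE))
  expect_false(identical(a$record$signal, other$record$signal))
})

test_that("preictal effect injection reaches the configured power ratio", {
  p <- simulate_patient(recovery_config(seed = 5, effect_size = 3))
  fm <- extract_features(p$record, features = c("relpower", "total_power"))
  st <- window_states(p$truth, fm$window_start_s)
  tot <- fm$values[, "Fp1/total_power"]
  eff_rel <- rowSums(fm$values[, paste0("Fp1/relpow_",
                                        p$truth$effect_bands)])
  eff_abs <- eff_rel * tot
  pre <- st$state == "preictal"
  int <- st$state == "interictal"
  expect_gt(sum(pre), 500)
  ratio <- mean(eff_abs[pre]) / mean(eff_abs[int])
  expect_gt(ratio, 3 * 0.9)
  expect_lt(ratio, 3 * 1.1)
})

test_that("effect_size = 1 gives indistinguishable preictal windows and homogeneous variance", {
  p <- simulate_patient(recovery_config(seed = 21, effect_size = 1))
  fm <- extract_features(p$record, features = c("relpower", "moments"))
  st <- window_states(p$truth, fm$window_start_s)
  g <- rowSums(fm$values[, paste0("Fp1/relpow_gamma", 1:4)])
  pre <- which(st$state == "preictal")
  int <- which(st$state == "interictal")
  set.seed(1)
  pv <- wilcox.test(g[sample(pre, 200)], g[sample(int, 200)])$p.value
  expect_gt(pv, 0.01)

  # stationarity control: windowed variance homogeneous over time
  v <- fm$values[int, "Fp1/variance"]
  grp <- cut(seq_along(v), 6)
  expect_gt(fligner.test(v, grp)$p.value, 0.01)
})

test_that("preictal signature is detectable at effect_size 3", {
  p <- simulate_patient(recovery_config(seed = 8, effect_size = 3))
  fm <- extract_features(p$record, features = "relpower")
  st <- window_states(p$truth, fm$window_start_s)
  g <- rowSums(fm$values[, paste0("Fp1/relpow_gamma", 1:4)])
  pre <- which(st$state == "preictal")
  int <- which(st$state == "interictal")
  set.seed(2)
  pv <- wilcox.test(g[sample(pre, 200)], g[sample(int, 200)],
                    alternative = "greater")$p.value
  expect_lt(pv, 0.001)
})

test_that("ground-truth states partition the window grid as configured", {
  p <- simulate_patient(recovery_config(seed = 3))
  grid_s <- seq(0, p$truth$record_s - 5, by = 5)
  st <- window_states(p$truth, grid_s)
  expect_false(anyNA(st$state))
  on_s <- as.numeric(p$annotations$onset) - as.numeric(p$record$start_time)
  # preictal spans exactly true_preictal_min before each onset; the one
  # window straddling an unaligned onset counts as ictal by precedence
  n_pre_expected <- length(on_s) * p$truth$true_preictal_min * 60 / 5
  straddle <- sum(on_s %% 5 != 0)
  expect_equal(sum(st$state == "preictal"), n_pre_expected - straddle)
  # ictal covers each onset window
  i_on <- findInterval(on_s, grid_s)
  expect_true(all(st$state[i_on] == "ictal"))
})

test_that("sleep schedule and artifacts are reflected in the ground truth", {
  cfg <- sim_config(n_seizures = 1, record_days = 0.5, n_channels = 1,
                    min_separation_min = 30, artifact_rate = 2,
                    sleep_schedule = list(c(23, 7)), seed = 12,
                    allow_few = TRUE)
  p <- simulate_patient(cfg)
  grid_s <- seq(0, p$truth$record_s - 5, by = 5)
  st <- window_states(p$truth, grid_s)
  # record starts at midnight -> asleep until 07:00
  expect_true(all(st$asleep[grid_s < 7 * 3600]))
  expect_false(any(st$asleep[grid_s > 7 * 3600 & grid_s < 12 * 3600]))
  expect_gt(sum(st$artifact), 0)
  # sleep boosts delta power
  fm <- extract_features(p$record, features = "relpower")
  d <- fm$values[, "Fp1/relpow_delta"]
  stw <- window_states(p$truth, fm$window_start_s)
  ok <- stw$state == "interictal" & !stw$artifact
  expect_gt(mean(d[ok & stw$asleep]), mean(d[ok & !stw$asleep]))
})

test_that("annotation CSV round-trips, handles empty files and validates", {
  tmp <- tempfile(fileext = ".csv")
  t0 <- as.POSIXct("2024-03-01 10:00:00", tz = "UTC")
  ann <- seizure_annotation(t0 + c(0, 3600, 7200), t0 + c(60, 3660, 7260))
  write_annotations(ann, tmp)
  back <- read_annotations(tmp)
  expect_equal(as.numeric(back$onset), as.numeric(ann$onset))
  expect_equal(as.numeric(back$offset), as.numeric(ann$offset))

  writeLines("onset_iso8601", tmp)
  empty <- read_annotations(tmp)
  expect_s3_class(empty, "seizure_annotation")
  expect_length(empty, 0)

  expect_error(seizure_annotation(t0 + c(3600, 0)), "strictly increasing")
  expect_error(seizure_annotation(t0 + c(0, 0)), "strictly increasing")

  rec <- eeg_record(matrix(rnorm(2560), ncol = 2), fs = 256,
                    channel_names = c("C3", "C4"), start_time = t0)
  expect_error(validate_annotations(seizure_annotation(t0 - 10), rec),
               "before record start")
})

test_that("record container round-trips through float32 + JSON sidecar", {
  t0 <- as.POSIXct("2024-03-02 08:30:00", tz = "UTC")
  rec <- eeg_record(matrix(rnorm(256 * 10 * 2), ncol = 2), fs = 256,
                    channel_names = c("O1", "O2"), start_time = t0)
  path <- tempfile()
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$fs, 256)
  expect_equal(back$channel_names, c("O1", "O2"))
  expect_equal(as.numeric(back$start_time), as.numeric(t0))
  expect_equal(back$signal, rec$signal, tolerance = 1e-6)  # float32
})
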