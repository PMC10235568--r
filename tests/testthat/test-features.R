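t0 <- as.POSIXct("2024-03-01", tz = "UTC")

test_that("windowing follows the floor rule and rejects short records", {
  mk <- function(secs) eeg_record(matrix(rnorm(secs * 256)), 256, "Cz", t0)
  g60 <- segment_windows(mk(60))
  expect_equal(g60$n_windows, 12)
  expect_equal(g60$samples_per_window, 1280)
  expect_equal(segment_windows(mk(61))$n_windows, 12)  # 1 s dropped
  expect_error(segment_windows(mk(4)), "shorter than one window")
})

test_that("every feature matches its independent direct-formula oracle", {
  set.seed(101)
  n_reps <- 100
  for (r in seq_len(n_reps)) {
    # mixture of noise and tones so all bands are exercised
    t_s <- (0:1279) / 256
    x <- rnorm(1280) * runif(1, 0.5, 3) +
      runif(1, 0, 3) * sin(2 * pi * runif(1, 1, 120) * t_s) +
      runif(1, -5, 5)
    mo <- statistical_moments(x)
    expect_equal(unclass(mo), oracle_moments(x), tolerance = 1e-9,
                 ignore_attr = TRUE)
    hj <- hjorth(x)
    expect_equal(unclass(hj), oracle_hjorth(x), tolerance = 1e-9,
                 ignore_attr = TRUE)
    dc <- decorrelation_time(x, 256)
    expect_equal(as.numeric(dc), oracle_decorr(x, 256), tolerance = 1e-12)
    if (r <= 25) {  # O(n^2) DFT oracle kept to a subset for speed
      bp <- relative_band_powers(x, 256)
      expect_equal(as.numeric(bp), oracle_band_powers(x, 256),
                   tolerance = 1e-6)
      se <- spectral_edge(x, 256, 0.5)
      oe <- oracle_sef(x, 256, 0.5)
      expect_equal(se$edge_hz, oe$edge_hz, tolerance = 1e-6)
      expect_equal(se$cum_power, oe$cum_power, tolerance = 1e-6)
    }
  }
})

test_that("band powers concentrate on tones and spread for white noise", {
  t_s <- (0:1279) / 256
  s10 <- sin(2 * pi * 10 * t_s)
  p <- relative_band_powers(s10, 256)
  expect_gte(p[["band_8_13"]], 0.99)
  expect_true(all(p[setdiff(names(p), "band_8_13")] <= 0.01))
  expect_lte(sum(p), 1)  # notch gaps excluded from the bands

  set.seed(7)
  fr <- rowMeans(replicate(40, relative_band_powers(rnorm(1280), 256)))
  expect_equal(fr[["delta"]], 17 / 638, tolerance = 0.15)
  expect_equal(fr[["gamma2"]], 110 / 638, tolerance = 0.15)

  se <- spectral_edge(rnorm(1280), 256, 0.5)
  expect_lt(abs(se$edge_hz - 64.25), 5)
  se99 <- spectral_edge(rnorm(1280), 256, 0.99)
  expect_gt(se99$edge_hz, 120)
})

test_that("band ratios: count, symmetry and zero-denominator guard", {
  p <- setNames(rep(2, 8), eeg_bands()$name)
  r <- band_ratios(p)
  expect_length(r, 28)
  expect_true(all(abs(r - 1) < 1e-9))
  p0 <- c(a = 1, b = 0)
  expect_true(is.finite(band_ratios(p0)[[1]]))
})

test_that("moments and Hjorth transform as theory requires", {
  set.seed(3)
  x <- rnorm(1280)
  # skewness is odd under reflection
  expect_equal(statistical_moments(-x)[["skewness"]],
               -statistical_moments(x)[["skewness"]])
  # Gaussian kurtosis near 3 (Pearson convention)
  k <- mean(replicate(30, statistical_moments(rnorm(1280))[["kurtosis"]]))
  expect_lt(abs(k - 3), 0.4)
  # amplitude scaling: activity x a^2, mobility/complexity invariant
  h1 <- hjorth(x); h3 <- hjorth(3 * x)
  expect_equal(h3[["activity"]], 9 * h1[["activity"]])
  expect_equal(h3[["mobility"]], h1[["mobility"]])
  expect_equal(h3[["complexity"]], h1[["complexity"]])
})

test_that("decorrelation time matches the first-zero law for tones and noise", {
  t_s <- (0:1279) / 256
  for (f in c(4, 10, 25)) {
    dt <- decorrelation_time(sin(2 * pi * f * t_s), 256)
    expect_lt(abs(dt - 1 / (4 * f)), 1 / 256 + 1e-12)
  }
  set.seed(11)
  dts <- replicate(20, decorrelation_time(rnorm(1280), 256))
  # delta-correlated noise: first crossing within a couple of lags
  expect_lte(median(dts), 2 / 256)
  expect_true(all(dts <= 6 / 256 + 1e-12))
  # a ramp's raw autocorrelation stays positive -> saturation
  ramp <- decorrelation_time(seq(1, 2, length.out = 1280), 256)
  expect_true(attr(ramp, "saturated"))
  expect_equal(as.numeric(ramp), 5)
})

test_that("wavelet energies: conservation, band mapping and reference values", {
  expect_equal(unname(wavelet_energies(rep(0, 1280))), rep(0, 8))
  set.seed(5)
  x <- rnorm(1280)
  E <- wavelet_energies(matrix(x, ncol = 1))  # includes approximation
  expect_equal(sum(E), sum(x^2), tolerance = 1e-6)
  # 96 Hz tone lives in D1 (64-128 Hz scale band)
  tone <- sin(2 * pi * 96 * (0:1279) / 256)
  Et <- wavelet_energies(tone)
  expect_gt(Et[["E_D1"]], 0.8 * sum(Et))
  # frozen cross-check against an independent DWT implementation
  # (PyWavelets db4, periodization mode) on a seeded window
  set.seed(42)
  y <- rnorm(256)
  Ey <- wavelet_energies(y, levels = 4)
  expect_equal(unname(Ey),
               c(127.048414497880, 58.053928672185,
                 32.287312055099, 13.499036040849),
               tolerance = 1e-9)
  expect_error(wavelet_energies(rnorm(100)), "shorter")
})

test_that("degenerate windows yield flagged, finite sentinels", {
  const <- rep(2.5, 1280)
  mo <- statistical_moments(const)
  expect_equal(unname(unclass(mo)), c(2.5, 0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(mo, "degenerate"))
  hj <- hjorth(const)
  expect_equal(unname(unclass(hj)), c(0, 0, 0), ignore_attr = TRUE)
  bp <- relative_band_powers(const, 256)
  expect_true(all(bp == 0))
  expect_true(attr(bp, "degenerate"))
  r <- extract_features(eeg_record(matrix(const), 256, "Cz", t0))
  expect_true(all(is.finite(r$values)))
  expect_true(all(r$degenerate))
})

test_that("extract_features produces 54 named features per channel and labels windows", {
  cfg <- sim_config(n_seizures = 1, record_days = 0.045, n_channels = 2,
                    min_separation_min = 10, true_preictal_min = 30,
                    onset_hours = 0.75,  # grid-aligned onset
                    seed = 4, allow_few = TRUE)
  p <- simulate_patient(cfg)
  fm <- extract_features(p$record, p$annotations, preictal_min = 30)
  expect_equal(ncol(fm$values), 2 * 54)
  expect_false(any(duplicated(fm$feature_names)))
  expect_true(all(grepl("^(Fp1|Fp2)/", fm$feature_names)))
  expect_true(all(is.finite(fm$values)))
  # 30 min of 5-s windows fully recorded -> 360 preictal labels
  expect_equal(sum(fm$labels == "preictal", na.rm = TRUE), 360)
  # excluded windows overlap the ictal span and carry NA labels
  expect_true(all(is.na(fm$labels[fm$excluded])))
  grid <- segment_windows(p$record)
  expect_equal(nrow(fm$values), grid$n_windows)
  # row subsetting keeps the object consistent
  sub <- fm_subset(fm, 1:100)
  expect_equal(nrow(sub$values), 100)
  expect_length(sub$labels, 100)
})

test_that("feature CSV serialization round-trips values and labels", {
  m <- matrix(rnorm(40), 10, 4)
  fm <- make_fm(m)
  fm$labels <- factor(rep(c("interictal", "preictal"), 5),
                      levels = c("interictal", "preictal"))
  tmp <- tempfile(fileext = ".csv")
  write_features(fm, tmp)
  back <- read.csv(tmp, check.names = FALSE)
  expect_equal(nrow(back), 10)
  expect_equal(unname(as.matrix(back[, 4:7])), unname(m), tolerance = 1e-12)
  expect_true(file.exists(paste0(tmp, ".meta.json")))
})
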