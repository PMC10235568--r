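#' Standard 10-20 scalp electrode labels
#'
#' @return Character vector of the 19 standard 10-20 electrode names.
#' @export
eeg_1020_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Simulation configuration for a synthetic long-term EEG patient
#'
#' Defines the study conditions under which a synthetic patient is
#' generated: recording length, number and minimum spacing of seizures,
#' the length and strength of the preictal spectral signature, circadian
#' and sleep-wake modulation, and an optional muscle-artifact process.
#' The defaults emulate long-term presurgical scalp monitoring: 256 Hz,
#' 10-20 montage, at least four seizures separated by at least 4 h 30 min.
#'
#' The preictal signature is a multiplicative power ramp on the configured
#' `effect_bands`: band power is scaled by a factor rising linearly from 1
#' at the start of the preictal span to `effect_size` at seizure onset.
#' Circadian modulation multiplies broadband amplitude sinusoidally with a
#' 24-h period (acrophase 18:00). Sleep intervals boost delta-band power
#' and suppress the posterior alpha rhythm. Artifacts are 0.5-2 s
#' broadband 20-100 Hz bursts on a Poisson schedule.
#'
#' @param n_seizures Number of seizures to place (the study inclusion
#'   criterion requires at least 4; smaller values must be explicitly
#'   allowed with `allow_few = TRUE`).
#' @param record_days Total recording length in days (may be fractional).
#' @param fs Sampling frequency in Hz.
#' @param n_channels Number of channels (first `n_channels` 10-20 labels).
#' @param channel_names Channel labels; overrides `n_channels`.
#' @param true_preictal_min True preictal duration in minutes.
#' @param effect_size Multiplicative band-power factor during the
#'   preictal span (1 = no preictal signature).
#' @param preictal_profile Shape of the preictal signature:
#'   `"constant"` scales the effect bands' power by `effect_size` over
#'   the whole span (the mean preictal/interictal power ratio then equals
#'   `effect_size`); `"ramp"` rises linearly from 1 to `effect_size`
#'   across the span, emulating a gradual transitional stage.
#' @param effect_bands Names of the spectral bands carrying the preictal
#'   signature (see [eeg_bands()]).
#' @param circadian_amplitude Relative amplitude of the 24-h broadband
#'   modulation (0 disables it).
#' @param sleep_schedule List of `c(start_hour, end_hour)` times-of-day
#'   (intervals may wrap past midnight); empty list disables sleep
#'   modulation.
#' @param sleep_delta_boost Multiplicative delta-power factor during sleep.
#' @param artifact_rate Expected muscle-artifact bursts per hour.
#' @param min_separation_min Minimum inter-onset spacing in minutes.
#' @param ictal_s Ictal duration in seconds appended after each onset.
#' @param onset_hours Optional explicit onset times (hours from record
#'   start); when given they override random scheduling but are still
#'   validated against spacing and record length.
#' @param start_time Absolute start time of the recording (`POSIXct`, UTC).
#' @param seed Integer master seed; fixes the full record bit-for-bit.
#' @param allow_few Allow fewer than 4 seizures (for small examples).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_seizures = 4,
                       record_days = 2,
                       fs = 256,
                       n_channels = 19,
                       channel_names = NULL,
                       true_preictal_min = 40,
                       effect_size = 1,
                       preictal_profile = c("constant", "ramp"),
                       effect_bands = c("band_13_30", "gamma1", "gamma2",
                                        "gamma3", "gamma4"),
                       circadian_amplitude = 0.2,
                       sleep_schedule = list(c(23, 7)),
                       sleep_delta_boost = 2,
                       artifact_rate = 0,
                       min_separation_min = 270,
                       ictal_s = 60,
                       onset_hours = NULL,
                       start_time = as.POSIXct("2024-03-01 00:00:00",
                                               tz = "UTC"),
                       seed = 1L,
                       allow_few = FALSE) {
  if (is.null(channel_names)) {
    stopifnot(n_channels >= 1, n_channels <= 19)
    channel_names <- eeg_1020_channels()[seq_len(n_channels)]
  }
  stopifnot(fs > 0, record_days > 0, true_preictal_min > 0,
            effect_size >= 0, circadian_amplitude >= 0,
            sleep_delta_boost > 0, artifact_rate >= 0,
            min_separation_min > 0, ictal_s > 0)
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  known <- eeg_bands()$name
  if (!all(effect_bands %in% known)) {
    stop("unknown effect band(s): ",
         paste(setdiff(effect_bands, known), collapse = ", "))
  }
  if (n_seizures < 4 && !allow_few) {
    stop("the inclusion criterion requires at least 4 seizures; ",
         "pass allow_few = TRUE to override")
  }
  structure(list(
    n_seizures = as.integer(n_seizures), record_days = record_days,
    fs = fs, channel_names = channel_names,
    true_preictal_min = true_preictal_min, effect_size = effect_size,
    preictal_profile = match.arg(preictal_profile),
    effect_bands = effect_bands,
    circadian_amplitude = circadian_amplitude,
    sleep_schedule = sleep_schedule,
    sleep_delta_boost = sleep_delta_boost,
    artifact_rate = artifact_rate,
    min_separation_min = min_separation_min, ictal_s = ictal_s,
    onset_hours = onset_hours, start_time = start_time,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# sleep schedule (hours of day, possibly wrapping) -> absolute second
# intervals over [0, record_s)
sleep_intervals_s <- function(schedule, start_time, record_s) {
  if (length(schedule) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  tod0 <- as.numeric(start_time) %% 86400  # seconds past midnight at t = 0
  out <- list()
  n_days <- ceiling(record_s / 86400) + 1
  for (iv in schedule) {
    a <- iv[1] * 3600; b <- iv[2] * 3600
    if (b <= a) b <- b + 86400  # wraps past midnight
    for (d in -1:n_days) {
      s <- d * 86400 + a - tod0
      e <- d * 86400 + b - tod0
      if (e > 0 && s < record_s) {
        out[[length(out) + 1]] <- c(max(0, s), min(record_s, e))
      }
    }
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

#' Schedule seizure onsets for a synthetic patient
#'
#' Places `n_seizures` onsets in the record so that all inter-onset gaps
#' are at least `min_separation_min`, the first onset leaves room for the
#' preictal span, and the last ictal segment ends before the record does.
#' Jitter is drawn from the seeded scheduling substream.
#'
#' @param config A [sim_config()] object.
#' @return A list with `onsets_s` (onset times in seconds from record
#'   start), `ictal_end_s`, `blocks` (per-seizure contiguous pre-onset data
#'   spans used e.g. for surrogate onset relocation) and `record_s`.
#' @export
simulate_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  record_s <- config$record_days * 86400
  n <- config$n_seizures
  min_sep <- config$min_separation_min * 60
  lead <- config$true_preictal_min * 60 + 900
  tail_s <- config$ictal_s + 300
  if (!is.null(config$onset_hours)) {
    onsets <- sort(config$onset_hours) * 3600
    if (length(onsets) != n) stop("onset_hours length must equal n_seizures")
    if (onsets[1] < lead || onsets[n] + tail_s > record_s ||
        (n > 1 && any(diff(onsets) < min_sep))) {
      stop_sz("explicit onsets violate the scheduling constraints",
              "sz_schedule_error")
    }
  } else {
    span_needed <- lead + (n - 1) * min_sep + tail_s
    slack <- record_s - span_needed
    if (slack < 0) {
      stop_sz(sprintf(
        "infeasible schedule: %d seizures with %.0f min spacing need %.2f h but the record is %.2f h",
        n, config$min_separation_min, span_needed / 3600, record_s / 3600),
        "sz_schedule_error")
    }
    jitter <- withr::with_seed(derive_seed(config$seed, 1),
                               sort(runif(n, 0, slack)))
    onsets <- lead + (seq_len(n) - 1) * min_sep + jitter
  }
  ictal_end <- onsets + config$ictal_s
  blocks <- data.frame(
    start = c(0, ictal_end[-n]),
    end = onsets,
    seizure = seq_len(n)
  )
  list(onsets_s = onsets, ictal_end_s = ictal_end, blocks = blocks,
       record_s = record_s)
}

#' Generate a synthetic long-term EEG patient
#'
#' Produces a continuous multichannel recording with annotated seizures
#' and a ground-truth state timeline. The background per channel is
#' 1/f-coloured noise plus a 10-Hz posterior alpha rhythm while awake;
#' during each preictal span the configured bands' power ramps linearly up
#' to `effect_size`; circadian modulation scales broadband amplitude with a
#' 24-h period; sleep boosts delta power; muscle-artifact bursts are
#' injected on a Poisson schedule; each onset is followed by `ictal_s`
#' seconds of large-amplitude 4-Hz oscillation. Identical configurations
#' (including the seed) reproduce the output bit-for-bit.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `record` ([eeg_record]), `annotations`
#'   ([seizure_annotation]) and `truth` (ground-truth spans, class
#'   `sz_ground_truth`).
#' @export
simulate_patient <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sch <- simulate_schedule(config)
  fs <- config$fs
  n_samp <- round(sch$record_s * fs)
  n_ch <- length(config$channel_names)
  bands <- eeg_bands()

  sleep <- sleep_intervals_s(config$sleep_schedule, config$start_time,
                             sch$record_s)
  pre <- data.frame(
    start = sch$onsets_s - config$true_preictal_min * 60,
    end = sch$onsets_s, seizure = seq_along(sch$onsets_s))
  ict <- data.frame(start = sch$onsets_s, end = sch$ictal_end_s,
                    seizure = seq_along(sch$onsets_s))

  # artifact schedule (shared across channels; bursts differ per channel)
  arts <- data.frame(time = numeric(0), duration = numeric(0))
  if (config$artifact_rate > 0) {
    arts <- withr::with_seed(derive_seed(config$seed, 5), {
      n_ev <- rpois(1, config$artifact_rate * sch$record_s / 3600)
      data.frame(time = sort(runif(n_ev, 0, sch$record_s - 2)),
                 duration = runif(n_ev, 0.5, 2))
    })
  }

  # frequency-domain masks are built per block; blocks are multiples of
  # the 5-s window so block seams never fall inside an analysis window
  block_len <- min(n_samp, 163840L)          # 640 s at 256 Hz
  eff <- bands[bands$name %in% config$effect_bands, ]
  tod0 <- as.numeric(config$start_time) %% 86400

  signal <- matrix(0, nrow = n_samp, ncol = n_ch)
  posterior <- config$channel_names %in% c("T5", "P3", "Pz", "P4", "T6",
                                           "O1", "O2")
  alpha_phase <- withr::with_seed(derive_seed(config$seed, 7),
                                  runif(n_ch, 0, 2 * pi))

  n_blocks <- ceiling(n_samp / block_len)
  spec_cache <- NULL
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1) * block_len + 1L
    i1 <- min(n_samp, b * block_len)
    L <- i1 - i0 + 1L
    t_s <- (seq.int(i0, i1) - 1) / fs

    # per-sample gain profiles for this block
    g_pre <- rep(1, L)
    for (k in seq_len(nrow(pre))) {
      sel <- t_s >= pre$start[k] & t_s < pre$end[k]
      if (any(sel)) {
        if (config$preictal_profile == "ramp") {
          frac <- (t_s[sel] - pre$start[k]) / (pre$end[k] - pre$start[k])
          g_pre[sel] <- 1 + (config$effect_size - 1) * frac
        } else {
          g_pre[sel] <- config$effect_size
        }
      }
    }
    asleep <- point_in_intervals(t_s, sleep$start, sleep$end)
    g_delta <- ifelse(asleep, config$sleep_delta_boost, 1)
    circ <- 1 + config$circadian_amplitude *
      sin(2 * pi * ((t_s + tod0) / 86400 - 0.25))  # acrophase 18:00

    if (is.null(spec_cache) || spec_cache$L != L) {
      freqs <- c(0, seq_len(L - 1)) * fs / L
      freqs <- pmin(freqs, fs - freqs)           # two-sided frequency axis
      amp <- ifelse(freqs >= 0.5, 1 / sqrt(freqs), 0)  # 1/f power spectrum
      use_eff <- config$effect_size != 1
      use_del <- config$sleep_delta_boost != 1 && nrow(sleep) > 0
      m_eff <- if (use_eff) {
        point_in_intervals(freqs, eff$f_low, eff$f_high)
      } else rep(FALSE, L)
      m_del <- if (use_del) freqs >= 0.5 & freqs < 4 else rep(FALSE, L)
      half <- L %/% 2L
      spec_cache <- list(
        L = L, use_eff = use_eff, use_del = use_del, half = half,
        amp_pair = amp * ((amp > 0 & !m_eff & !m_del) + 1i * m_eff) *
          sqrt(L / 2),
        amp_del = amp * m_del * sqrt(L / 2),
        mirror = L - seq.int(2L, half + 1L) + 2L)  # conjugate bins
    }
    use_eff <- spec_cache$use_eff; use_del <- spec_cache$use_del
    half <- spec_cache$half; mirror <- spec_cache$mirror

    for (ch in seq_len(n_ch)) {
      # draw the noise directly as a conjugate-symmetric random spectrum
      # (a circular stationary Gaussian process with the 1/f spectrum);
      # disjoint band masks of one spectrum are independent components
      wn <- withr::with_seed(derive_seed(config$seed, 100L + b * 37L + ch),
                             rnorm(L))
      Fz <- complex(length.out = L)
      Fz[seq.int(2L, half + 1L)] <-
        complex(real = wn[seq_len(half)],
                imaginary = c(wn[seq.int(half + 1L, L - 1L)], 0))
      Fz[mirror] <- Conj(Fz[seq.int(2L, half + 1L)])
      Fz[half + 1L] <- complex(real = sqrt(2) * Re(Fz[half + 1L]))
      # pack the rest and effect components into one inverse transform
      z <- fft(Fz * spec_cache$amp_pair, inverse = TRUE) / L
      comp_rest <- Re(z)
      comp_eff <- if (use_eff) Im(z) else 0
      comp_del <- if (use_del) {
        Re(fft(Fz * spec_cache$amp_del, inverse = TRUE)) / L
      } else 0
      alpha_amp <- 6 * (0.3 + 0.7 * posterior[ch]) * as.numeric(!asleep)
      x <- comp_rest + sqrt(g_pre) * comp_eff + sqrt(g_delta) * comp_del
      signal[i0:i1, ch] <- 30 * circ *
        (x + alpha_amp * sin(2 * pi * 10 * t_s + alpha_phase[ch]))
    }
  }

  # ictal overwrite: large-amplitude 4 Hz oscillation
  for (k in seq_len(nrow(ict))) {
    j0 <- floor(ict$start[k] * fs) + 1L
    j1 <- min(n_samp, ceiling(ict$end[k] * fs))
    t_s <- (seq.int(j0, j1) - 1) / fs
    for (ch in seq_len(n_ch)) {
      ns <- withr::with_seed(derive_seed(config$seed, 9000L + k * 31L + ch),
                             rnorm(length(t_s)))
      signal[j0:j1, ch] <- 150 * sin(2 * pi * 4 * t_s) + 15 * ns
    }
  }

  # muscle-artifact bursts: tapered 20-100 Hz noise
  if (nrow(arts) > 0) {
    for (k in seq_len(nrow(arts))) {
      j0 <- floor(arts$time[k] * fs) + 1L
      L <- round(arts$duration[k] * fs)
      j1 <- min(n_samp, j0 + L - 1L)
      L <- j1 - j0 + 1L
      if (L < 8) next
      taper <- sin(pi * (seq_len(L) - 0.5) / L)^2
      freqs <- c(0, seq_len(L - 1)) * fs / L
      freqs <- pmin(freqs, fs - freqs)
      mask <- freqs >= 20 & freqs <= 100
      for (ch in seq_len(n_ch)) {
        wn <- withr::with_seed(derive_seed(config$seed, 5e5 + k * 53L + ch),
                               rnorm(L))
        burst <- Re(fft(fft(wn) * mask, inverse = TRUE)) / L
        burst <- burst / max(sd(burst), 1e-12) * 60
        signal[j0:j1, ch] <- signal[j0:j1, ch] + taper * burst
      }
    }
  }

  record <- eeg_record(signal, fs = fs,
                       channel_names = config$channel_names,
                       start_time = config$start_time)
  ann <- seizure_annotation(
    onset = config$start_time + sch$onsets_s,
    offset = config$start_time + sch$ictal_end_s)
  truth <- structure(list(
    preictal = pre, ictal = ict, sleep = sleep, artifacts = arts,
    blocks = sch$blocks, record_s = sch$record_s,
    true_preictal_min = config$true_preictal_min,
    effect_bands = config$effect_bands, effect_size = config$effect_size
  ), class = "sz_ground_truth")
  list(record = record, annotations = ann, truth = truth)
}

#' Per-window ground-truth states
#'
#' Maps the continuous ground-truth spans of a simulated patient onto a
#' window grid. A window is `ictal` if it overlaps an ictal span,
#' otherwise `preictal` if its start falls inside a true preictal span,
#' otherwise `interictal`. Sleep state is read at the window start;
#' the artifact flag marks windows overlapping any artifact burst.
#'
#' @param truth A `sz_ground_truth` object from [simulate_patient()].
#' @param window_start_s Window start times in seconds from record start.
#' @param window_s Window length in seconds.
#' @return A data frame with columns `state` (factor
#'   interictal/preictal/ictal), `asleep` and `artifact`.
#' @export
window_states <- function(truth, window_start_s, window_s = 5) {
  stopifnot(inherits(truth, "sz_ground_truth"))
  w0 <- window_start_s
  w1 <- window_start_s + window_s
  state <- rep("interictal", length(w0))
  for (k in seq_len(nrow(truth$preictal))) {
    state[w0 >= truth$preictal$start[k] & w0 < truth$preictal$end[k]] <-
      "preictal"
  }
  for (k in seq_len(nrow(truth$ictal))) {
    state[w1 > truth$ictal$start[k] & w0 < truth$ictal$end[k]] <- "ictal"
  }
  asleep <- point_in_intervals(w0, truth$sleep$start, truth$sleep$end)
  artifact <- rep(FALSE, length(w0))
  if (nrow(truth$artifacts) > 0) {
    artifact <- point_in_intervals(
      w0, truth$artifacts$time - window_s,
      truth$artifacts$time + truth$artifacts$duration)
  }
  data.frame(
    state = factor(state, levels = c("interictal", "preictal", "ictal")),
    asleep = asleep, artifact = artifact)
}
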