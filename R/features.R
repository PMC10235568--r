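#' Spectral band table
#'
#' The eight analysis bands used for relative spectral power, with notch
#' gaps at 47-53 Hz and 97-103 Hz between the gamma bands. Band names are
#' frequency-range based for the 8-13 Hz and 13-30 Hz bands:
#' conventionally these ranges are called alpha and beta respectively,
#' and the `conventional_label` column records that mapping, so no
#' clinical label is attached silently.
#'
#' @return A data frame with columns `name`, `f_low`, `f_high`,
#'   `conventional_label`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "band_8_13", "band_13_30",
             "gamma1", "gamma2", "gamma3", "gamma4"),
    f_low = c(0.5, 4, 8, 13, 30, 53, 75, 103),
    f_high = c(4, 8, 13, 30, 47, 75, 97, 128),
    conventional_label = c("delta", "theta", "alpha", "beta",
                           "gamma1", "gamma2", "gamma3", "gamma4"),
    stringsAsFactors = FALSE)
}

feature_groups_all <- function() {
  c("relpower", "ratios", "sef", "moments", "hjorth", "decorr", "wavelet")
}

#' Segment a recording into fixed non-overlapping windows
#'
#' Defines the 5-second (default) non-overlapping window grid used by all
#' downstream stages; trailing samples that do not fill a whole window are
#' dropped.
#'
#' @param record An [eeg_record].
#' @param window_s Window length in seconds (must give an integer number
#'   of samples).
#' @return An object of class `window_grid` with fields `n_windows`,
#'   `samples_per_window`, `window_s`, `fs`, `window_start_s` and
#'   `start_time`.
#' @export
segment_windows <- function(record, window_s = 5) {
  stopifnot(inherits(record, "eeg_record"))
  ns <- window_s * record$fs
  if (abs(ns - round(ns)) > 1e-9) {
    stop("window_s * fs must be an integer sample count")
  }
  ns <- as.integer(round(ns))
  nw <- floor(nrow(record$signal) / ns)
  if (nw < 1) stop("record shorter than one window")
  structure(list(
    n_windows = nw, samples_per_window = ns, window_s = window_s,
    fs = record$fs, window_start_s = (seq_len(nw) - 1) * window_s,
    start_time = record$start_time), class = "window_grid")
}

# samples-by-windows matrix for one channel over a window index range
window_matrix <- function(record, grid, channel, idx) {
  ns <- grid$samples_per_window
  if (length(idx) > 1 && all(diff(idx) == 1L)) {
    rows <- seq.int((idx[1] - 1L) * ns + 1L, idx[length(idx)] * ns)
  } else {
    offs <- as.integer(idx - 1L) * ns
    rows <- rep(offs, each = ns) + seq_len(ns)
  }
  W <- record$signal[rows, channel]
  dim(W) <- c(ns, length(idx))
  W
}

column_var <- function(M) {
  mu <- colMeans(M)
  colSums((M - rep(mu, each = nrow(M)))^2) / (nrow(M) - 1)
}

# Vectorised per-window feature bank. W: samples x windows matrix of one
# channel. Returns list(values = windows x p, names, degenerate, saturated).
compute_window_features <- function(W, fs, features = feature_groups_all(),
                                    bands = eeg_bands(),
                                    sef_fractions = 0.5,
                                    ratio_eps = 1e-12,
                                    wavelet_levels = 8) {
  n <- nrow(W); m <- ncol(W)
  mu <- colMeans(W)
  Xd <- W - rep(mu, each = n)
  m2 <- colSums(Xd^2) / n
  degen <- m2 <= 1e-20
  vals <- list(); nms <- character(0)
  sat <- rep(FALSE, m)

  need_psd <- any(c("relpower", "ratios", "sef", "total_power") %in% features)
  if (need_psd) {
    # single-taper (Hann) periodogram of the mean-detrended window
    h <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    Fm <- mvfft(Xd * h)
    nb <- n %/% 2 + 1L
    scale <- c(1, rep(2, nb - 2), 1) / (fs * sum(h^2))
    Fh <- Fm[seq_len(nb), , drop = FALSE]
    psd <- (Re(Fh)^2 + Im(Fh)^2) * scale
    f_hz <- (seq_len(nb) - 1) * fs / n
    df <- fs / n
    f_top <- min(128, fs / 2)
    in_total <- f_hz >= 0.5 & f_hz <= f_top
    # single-pass aggregation: each bin belongs to one band (or to the
    # notch gaps, group nrow + 1, which count toward the total only)
    grp <- rep(0L, nb)
    for (b in seq_len(nrow(bands))) {
      mk <- f_hz >= bands$f_low[b] &
        (f_hz < bands$f_high[b] |
           (bands$f_high[b] >= fs / 2 & f_hz <= fs / 2))
      grp[mk] <- b
    }
    grp[in_total & grp == 0L] <- nrow(bands) + 1L
    keep <- grp > 0L
    agg <- rowsum(psd[keep, , drop = FALSE], grp[keep]) * df
    present <- as.integer(rownames(agg))
    bp <- matrix(0, nrow(bands), m)
    bp[present[present <= nrow(bands)], ] <-
      agg[present <= nrow(bands), , drop = FALSE]
    total <- colSums(agg)
    relp <- bp / rep(pmax(total, 1e-300), each = nrow(bands))
    relp[, degen] <- 0

    if ("relpower" %in% features) {
      vals <- c(vals, lapply(seq_len(nrow(bands)), function(b) relp[b, ]))
      nms <- c(nms, paste0("relpow_", bands$name))
    }
    if ("ratios" %in% features) {
      for (i in seq_len(nrow(bands) - 1)) {
        for (j in seq.int(i + 1, nrow(bands))) {
          vals <- c(vals, list(relp[i, ] / (relp[j, ] + ratio_eps)))
          nms <- c(nms, paste0("ratio_", bands$name[i], "_", bands$name[j]))
        }
      }
    }
    if ("sef" %in% features) {
      Pin <- psd[in_total, , drop = FALSE]
      f_in <- f_hz[in_total]
      cs <- apply(Pin, 2, cumsum)
      if (!is.matrix(cs)) cs <- matrix(cs, ncol = m)
      for (fr in sef_fractions) {
        target <- fr * cs[nrow(cs), ]
        idx <- colSums(cs < rep(target, each = nrow(cs))) + 1L
        idx <- pmin(idx, nrow(cs))
        edge <- f_in[idx]
        cpow <- cs[cbind(idx, seq_len(m))] * df
        edge[degen] <- 0; cpow[degen] <- 0
        vals <- c(vals, list(edge), list(cpow))
        tag <- sprintf("sef%02d", round(100 * fr))
        nms <- c(nms, tag, paste0(tag, "_power"))
      }
    }
    if ("total_power" %in% features) {
      vals <- c(vals, list(total))
      nms <- c(nms, "total_power")
    }
  }

  if ("moments" %in% features) {
    m3 <- colSums(Xd^3) / n
    m4 <- colSums(Xd^4) / n
    skew <- ifelse(degen, 0, m3 / pmax(m2, 1e-300)^1.5)
    kurt <- ifelse(degen, 0, m4 / pmax(m2, 1e-300)^2)  # Pearson: Gaussian -> 3
    vals <- c(vals, list(mu), list(colSums(Xd^2) / (n - 1)), list(skew),
              list(kurt))
    nms <- c(nms, "mean", "variance", "skewness", "kurtosis")
  }

  if ("hjorth" %in% features) {
    v0 <- column_var(Xd)
    D1 <- Xd[-1, , drop = FALSE] - Xd[-n, , drop = FALSE]
    D2 <- D1[-1, , drop = FALSE] - D1[-(n - 1), , drop = FALSE]
    v1 <- column_var(D1); v2 <- column_var(D2)
    mob <- ifelse(degen, 0, sqrt(v1 / pmax(v0, 1e-300)))
    mobd <- ifelse(degen | v1 <= 1e-300, 0, sqrt(v2 / pmax(v1, 1e-300)))
    comp <- ifelse(degen | mob <= 0, 0, mobd / pmax(mob, 1e-300))
    act <- ifelse(degen, 0, v0)
    vals <- c(vals, list(act), list(mob), list(comp))
    nms <- c(nms, "hjorth_activity", "hjorth_mobility", "hjorth_complexity")
  }

  if ("decorr" %in% features) {
    # biased autocorrelation of the raw window (no detrending: removing
    # the mean would force a zero crossing at some lag for every window,
    # making the saturation case unreachable) via zero-padded FFT
    Y <- mvfft(rbind(W, matrix(0, n, m)))
    r <- Re(mvfft(Mod(Y)^2, inverse = TRUE))[seq_len(n), , drop = FALSE] /
      (2 * n)
    r0 <- r[1, ]
    neg <- r[-1, , drop = FALSE] <= 0
    hit <- colSums(neg) > 0
    first <- max.col(t(neg) * 1, ties.method = "first")
    k <- ifelse(hit, first, NA_integer_)
    dt <- ifelse(hit, k / fs, n / fs)
    sat <- sat | (!hit & !degen)
    dt[degen] <- 0
    vals <- c(vals, list(dt))
    nms <- c(nms, "decorr_time")
  }

  if ("wavelet" %in% features) {
    if (n < 2^wavelet_levels) stop("window shorter than 2^levels samples")
    n_use <- 2^wavelet_levels * (n %/% 2^wavelet_levels)
    E <- wavelet_energies(Xd[seq_len(n_use), , drop = FALSE],
                          levels = wavelet_levels)
    for (j in seq_len(wavelet_levels)) vals <- c(vals, list(E[, j]))
    nms <- c(nms, paste0("wavelet_d", seq_len(wavelet_levels)))
  }

  out <- do.call(cbind, vals)
  colnames(out) <- nms
  if (any(!is.finite(out))) stop("internal error: non-finite feature value")
  list(values = out, names = nms, degenerate = degen, saturated = sat)
}

#' Relative spectral band powers of one window
#'
#' Estimates the power spectral density of the mean-detrended window with
#' a single Hann-tapered periodogram, integrates it over each band, and
#' normalises by the total power in 0.5-128 Hz (so the eight band
#' fractions sum to at most 1; the notch gaps count toward the total but
#' toward no band).
#'
#' @param window Numeric vector of samples.
#' @param fs Sampling frequency in Hz.
#' @param bands Band table as from [eeg_bands()].
#' @return Named vector of band-power fractions in `[0, 1]`, with
#'   attribute `degenerate` set for a (near-)constant window (all-zero
#'   powers).
#' @export
relative_band_powers <- function(window, fs, bands = eeg_bands()) {
  r <- compute_window_features(matrix(window, ncol = 1), fs,
                               features = "relpower", bands = bands)
  out <- setNames(as.numeric(r$values[1, ]), bands$name)
  attr(out, "degenerate") <- r$degenerate[1]
  out
}

#' Pairwise band-power ratios
#'
#' For every unordered band pair (i < j in the band-table order), the
#' ratio `p_i / (p_j + eps)`; 28 ratios for 8 bands. The epsilon guard
#' keeps ratios finite when a band power is zero.
#'
#' @param powers Named band-power vector (as from
#'   [relative_band_powers()]).
#' @param eps Guard added to the denominator.
#' @return Named vector of `choose(n, 2)` ratios.
#' @export
band_ratios <- function(powers, eps = 1e-12) {
  nb <- length(powers)
  nm <- names(powers) %||% paste0("b", seq_len(nb))
  out <- numeric(0)
  for (i in seq_len(nb - 1)) {
    for (j in seq.int(i + 1, nb)) {
      out <- c(out, setNames(powers[[i]] / (powers[[j]] + eps),
                             paste0("ratio_", nm[i], "_", nm[j])))
    }
  }
  out
}

#' Spectral edge frequency
#'
#' The smallest frequency f such that the cumulative power of the window
#' over 0.5 Hz..f reaches `fraction` of the total power (0.5-128 Hz), on
#' the periodogram bin grid; also returns the absolute cumulative power
#' at that edge.
#'
#' @param window Numeric vector of samples.
#' @param fs Sampling frequency in Hz.
#' @param fraction Power fraction in (0, 1).
#' @return A list with `edge_hz`, `cum_power` and `degenerate`.
#' @export
spectral_edge <- function(window, fs, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  r <- compute_window_features(matrix(window, ncol = 1), fs,
                               features = "sef", sef_fractions = fraction)
  list(edge_hz = as.numeric(r$values[1, 1]),
       cum_power = as.numeric(r$values[1, 2]),
       degenerate = r$degenerate[1])
}

#' Four statistical moments of a window
#'
#' Sample mean, sample variance (n-1 denominator), skewness and kurtosis.
#' Kurtosis follows the Pearson (non-excess) convention: a Gaussian
#' window gives values near 3. A zero-variance window yields
#' `(mean, 0, 0, 0)` with the degenerate attribute set.
#'
#' @param window Numeric vector of samples.
#' @return Named vector `(mean, variance, skewness, kurtosis)`.
#' @export
statistical_moments <- function(window) {
  r <- compute_window_features(matrix(window, ncol = 1), fs = 1,
                               features = "moments")
  out <- setNames(as.numeric(r$values[1, ]),
                  c("mean", "variance", "skewness", "kurtosis"))
  attr(out, "degenerate") <- r$degenerate[1]
  out
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (ratio of the standard deviation of the
#' first difference to that of the signal) and complexity (mobility of
#' the first difference divided by the mobility of the signal).
#'
#' @param window Numeric vector of samples (length at least 3).
#' @return Named vector `(activity, mobility, complexity)`; zeros with
#'   the degenerate attribute for a constant window.
#' @export
hjorth <- function(window) {
  stopifnot(length(window) >= 3)
  r <- compute_window_features(matrix(window, ncol = 1), fs = 1,
                               features = "hjorth")
  out <- setNames(as.numeric(r$values[1, ]),
                  c("activity", "mobility", "complexity"))
  attr(out, "degenerate") <- r$degenerate[1]
  out
}

#' Decorrelation time
#'
#' Lag, in seconds, of the first zero crossing of the biased sample
#' autocorrelation of the mean-detrended window. If the autocorrelation
#' never crosses zero within the window, the window length is returned
#' with the `saturated` attribute set.
#'
#' @param window Numeric vector of samples.
#' @param fs Sampling frequency in Hz.
#' @return Decorrelation time in seconds, with attributes `saturated`
#'   and `degenerate`.
#' @export
decorrelation_time <- function(window, fs) {
  r <- compute_window_features(matrix(window, ncol = 1), fs,
                               features = "decorr")
  out <- as.numeric(r$values[1, 1])
  attr(out, "saturated") <- r$saturated[1]
  attr(out, "degenerate") <- r$degenerate[1]
  out
}

#' Extract the univariate linear feature bank of a recording
#'
#' Segments the recording into non-overlapping windows and computes, per
#' channel, the full univariate linear feature set: 8 relative spectral
#' band powers, their 28 pairwise ratios, the 50% spectral edge frequency
#' and the cumulative power at that edge, the four statistical moments,
#' the three Hjorth parameters, the decorrelation time and the 8 db4
#' wavelet detail energies (54 features per channel by default). When
#' annotations and a preictal duration are given, windows are labelled
#' preictal/interictal and windows overlapping ictal spans are excluded
#' from the labelled set.
#'
#' @param record An [eeg_record].
#' @param annotations Optional [seizure_annotation] for labelling.
#' @param preictal_min Optional preictal duration (minutes) for
#'   labelling.
#' @param window_s Window length in seconds (default 5).
#' @param features Character vector of feature groups, a subset of
#'   `relpower, ratios, sef, moments, hjorth, decorr, wavelet,
#'   total_power`.
#' @param channels Channel names to use (default: all).
#' @param sef_fractions Spectral-edge fractions to emit (default 0.5;
#'   e.g. `c(0.5, 0.9)` adds SEF90).
#' @param chunk Number of windows processed per block (memory knob).
#' @return An object of class `feature_matrix`: windows-by-features
#'   values, `channel/feature` column names, window start times, labels,
#'   exclusion and degeneracy flags and a metadata list.
#' @export
extract_features <- function(record, annotations = NULL,
                             preictal_min = NULL, window_s = 5,
                             features = feature_groups_all(),
                             channels = NULL, sef_fractions = 0.5,
                             chunk = 4096L) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.null(annotations)) validate_annotations(annotations, record)
  channels <- channels %||% record$channel_names
  stopifnot(all(channels %in% record$channel_names))
  grid <- segment_windows(record, window_s)
  nw <- grid$n_windows

  blocks <- split(seq_len(nw), ceiling(seq_len(nw) / chunk))
  per_ch <- vector("list", length(channels))
  degen <- matrix(FALSE, nw, length(channels),
                  dimnames = list(NULL, channels))
  feat_names_1 <- NULL
  for (ci in seq_along(channels)) {
    parts <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      W <- window_matrix(record, grid, channels[ci], blocks[[bi]])
      r <- compute_window_features(W, grid$fs, features = features,
                                   sef_fractions = sef_fractions)
      parts[[bi]] <- r$values
      degen[blocks[[bi]], ci] <- r$degenerate
      feat_names_1 <- r$names
    }
    per_ch[[ci]] <- do.call(rbind, parts)
  }
  values <- do.call(cbind, per_ch)
  feature_names <- as.vector(vapply(
    channels, function(ch) paste0(ch, "/", feat_names_1),
    character(length(feat_names_1))))
  colnames(values) <- feature_names

  fm <- structure(list(
    values = values, feature_names = feature_names,
    window_start = grid$start_time + grid$window_start_s,
    window_start_s = grid$window_start_s, window_s = window_s,
    fs = grid$fs, start_time = grid$start_time,
    labels = factor(rep(NA_character_, nw),
                    levels = c("interictal", "preictal")),
    excluded = rep(FALSE, nw), degenerate = degen,
    meta = list(kurtosis = "Pearson (non-excess; Gaussian -> 3)",
                psd = "Hann single-taper periodogram, mean-detrended",
                bands = eeg_bands(), features = features,
                sef_fractions = sef_fractions)
  ), class = "feature_matrix")
  if (!is.null(annotations) && !is.null(preictal_min)) {
    fm <- label_windows(fm, annotations, preictal_min)
  }
  fm
}

#' Label feature-matrix windows for a candidate preictal duration
#'
#' A window is `preictal` when its start falls in the `preictal_min`
#' minutes before a seizure onset, `interictal` otherwise. Windows
#' overlapping an ictal span (onset to offset, or onset + `ictal_s` when
#' offsets are absent) are excluded from the labelled set. Relabelling is
#' cheap, which is what the preictal grid search exploits.
#'
#' @param fm A `feature_matrix`.
#' @param annotations A [seizure_annotation].
#' @param preictal_min Preictal duration in minutes.
#' @param ictal_s Assumed ictal duration when annotations carry no
#'   offsets.
#' @return The feature matrix with `labels` and `excluded` updated.
#' @export
label_windows <- function(fm, annotations, preictal_min, ictal_s = 60) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(annotations, "seizure_annotation"),
            preictal_min > 0)
  t0 <- as.numeric(fm$start_time)
  on_s <- as.numeric(annotations$onset) - t0
  off_s <- if (!is.null(annotations$offset)) {
    as.numeric(annotations$offset) - t0
  } else on_s + ictal_s
  if (any(on_s < 0)) stop("seizure onset before record start")
  w0 <- fm$window_start_s
  w1 <- w0 + fm$window_s
  lab <- rep("interictal", length(w0))
  lab[point_in_intervals(w0, on_s - preictal_min * 60, on_s)] <- "preictal"
  excl <- rep(FALSE, length(w0))
  for (k in seq_along(on_s)) {
    excl <- excl | (w1 > on_s[k] & w0 < off_s[k])
  }
  lab[excl] <- NA
  fm$labels <- factor(lab, levels = c("interictal", "preictal"))
  fm$excluded <- excl
  fm$preictal_min <- preictal_min
  fm
}

#' Row subset of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param idx Integer or logical window index.
#' @return A `feature_matrix` restricted to those windows.
#' @export
fm_subset <- function(fm, idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$values <- fm$values[idx, , drop = FALSE]
  fm$window_start <- fm$window_start[idx]
  fm$window_start_s <- fm$window_start_s[idx]
  fm$labels <- fm$labels[idx]
  fm$excluded <- fm$excluded[idx]
  fm$degenerate <- fm$degenerate[idx, , drop = FALSE]
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%.1f-s windows)\n",
              nrow(x$values), ncol(x$values), x$window_s))
  if (!all(is.na(x$labels))) {
    tb <- table(x$labels, useNA = "ifany")
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a feature matrix to CSV (+ JSON sidecar)
#'
#' Writes the window-by-feature values with timestamps and labels to a
#' CSV file and the extraction conventions (band table, kurtosis and PSD
#' conventions, feature groups) to a JSON sidecar.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path; the sidecar is `<path>.meta.json`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(window_start = format_iso8601(fm$window_start),
                   label = as.character(fm$labels),
                   excluded = fm$excluded, check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fm$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
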